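.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_plasbhr("need at least 2 groups")
  if (any(lengths(groups) == 0L))
    stop_plasbhr("every group needs at least one observation")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (k - 1 degrees
#' of freedom), or an exact-style permutation p-value obtained by
#' re-labelling observations (`p_method = "permutation"`). The chi-square
#' route delegates to [stats::kruskal.test()].
#'
#' @param groups named list of numeric vectors, one per group.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm number of label permutations.
#' @return list: `h_statistic`, `kw_p`, `df`, `n_per_group`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000L) {
  groups <- .check_groups(groups)
  p_method <- match.arg(p_method)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- suppressWarnings(stats::kruskal.test(x, g))
  h <- unname(kt$statistic)
  if (is.nan(h)) h <- 0  # all observations tied: no evidence of difference
  p <- unname(kt$p.value)
  if (is.nan(p)) p <- 1
  if (p_method == "permutation") {
    hs <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      hb <- suppressWarnings(
        stats::kruskal.test(x, g[sample.int(length(g))])$statistic)
      hs[b] <- if (is.nan(hb)) 0 else hb
    }
    p <- (1 + sum(hs >= h - 1e-12)) / (n_perm + 1)
  }
  list(h_statistic = h, kw_p = p, df = length(groups) - 1L,
       n_per_group = lengths(groups), method = p_method)
}

#' Dunn's multiple-comparison post hoc test
#'
#' For every group pair,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` on pooled midranks with the tie correction, with a
#' two-sided standard-normal p-value adjusted over the k(k-1)/2 comparisons
#' (Bonferroni by default, capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust_method any method of [stats::p.adjust()]; the classical
#'   choice is `"bonferroni"`, `"holm"` is the usual alternative.
#' @return data.frame: `group_i`, `group_j`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, p_adjust_method = "bonferroni") {
  groups <- .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)  # midranks
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  nm <- names(groups)
  k <- length(nm)
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- nm[pairs[1, c]]; j <- nm[pairs[2, c]]
    se <- sqrt(v0 * (1 / n[[i]] + 1 / n[[j]]))
    z[c] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  data.frame(group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
             z = z, p_unadjusted = p,
             p_adjusted = pmin(1, stats::p.adjust(p, p_adjust_method)),
             stringsAsFactors = FALSE)
}

.split_set <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) v[nzchar(v)])
}

#' Cohort summary tables and group comparisons
#'
#' Joins mobility calls, feature profiles and plasmid statistics and
#' produces the cohort-level summaries: per-mobility-class counts and
#' length/GC medians, Kruskal-Wallis + Dunn comparisons of length, GC
#' content and ARG presence (0/1) across the mobility classes, per-ARG
#' occurrence counts with the fraction of carriers that are conjugative or
#' mobilizable, per-antibiotic-class counts, and Inc/MOB/MPF frequency
#' tables. Comparisons are skipped with a notice when fewer than two
#' classes are present.
#'
#' @param profiles table from [profile_table()].
#' @param calls table from [mobility_table()].
#' @param plasmids table from [plasmid_records()] (column `sequence`
#'   optional).
#' @param p_adjust_method passed to [dunn_posthoc()].
#' @return object of class `plasbhr_summary`: a list of tables, test
#'   results and notices.
#' @export
summarize_cohort <- function(profiles, calls, plasmids,
                             p_adjust_method = "bonferroni") {
  stopifnot(setequal(calls$plasmid_id, profiles$plasmid_id),
            all(calls$plasmid_id %in% plasmids$id))
  m <- merge(merge(calls, profiles, by = "plasmid_id"),
             plasmids[, c("id", "length", "gc_content")],
             by.x = "plasmid_id", by.y = "id")
  classes <- c("conjugative", "mobilizable", "non_mobilizable")
  m$mobility <- factor(m$mobility, levels = classes)
  present <- classes[classes %in% m$mobility]
  notices <- character(0)

  class_summary <- do.call(rbind, lapply(present, function(cl) {
    sub <- m[m$mobility == cl, ]
    data.frame(mobility = cl, n = nrow(sub),
               median_length_nt = stats::median(sub$length),
               median_gc = stats::median(sub$gc_content),
               n_with_arg = sum(nzchar(sub$args)),
               n_bhr = sum(sub$bhr_candidate), stringsAsFactors = FALSE)
  }))

  run_test <- function(values, label) {
    if (length(present) < 2L) {
      notices <<- c(notices, sprintf(
        "%s comparison skipped: only %d mobility class(es) present",
        label, length(present)))
      return(NULL)
    }
    groups <- split(values, droplevels(m$mobility))
    list(kw = kruskal_wallis(groups),
         dunn = dunn_posthoc(groups, p_adjust_method))
  }
  tests <- list(
    length = run_test(m$length, "length"),
    gc = run_test(m$gc_content, "GC"),
    arg_presence = run_test(as.numeric(nzchar(m$args)), "ARG presence"))

  # per-ARG occurrence and mobile fraction (conjugative or mobilizable)
  arg_sets <- .split_set(m$args)
  all_args <- sort(unique(unlist(arg_sets)))
  arg_table <- do.call(rbind, lapply(all_args, function(a) {
    carrier <- vapply(arg_sets, function(s) a %in% s, logical(1))
    n <- sum(carrier)
    n_mobile <- sum(carrier & m$mobility %in% c("conjugative", "mobilizable"))
    data.frame(arg = a, n_plasmids = n, n_mobile = n_mobile,
               pct_mobile = round(100 * n_mobile / n, 1),
               stringsAsFactors = FALSE)
  }))
  class_sets <- .split_set(m$arg_classes)
  all_classes <- sort(unique(unlist(class_sets)))
  arg_class_table <- do.call(rbind, lapply(all_classes, function(a) {
    n <- sum(vapply(class_sets, function(s) a %in% s, logical(1)))
    data.frame(arg_class = a, n_plasmids = n, stringsAsFactors = FALSE)
  }))

  freq <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (!length(x)) return(NULL)
    as.data.frame(table(value = x), stringsAsFactors = FALSE)
  }
  inc_table <- freq(unlist(.split_set(m$inc_types)))
  mob_table <- freq(m$mob_type)
  mpf_table <- freq(m$mpf_type)

  structure(list(class_summary = class_summary, tests = tests,
                 arg_table = arg_table, arg_class_table = arg_class_table,
                 inc_table = inc_table, mob_table = mob_table,
                 mpf_table = mpf_table, notices = notices),
            class = "plasbhr_summary")
}

#' @export
print.plasbhr_summary <- function(x, ...) {
  cat("Plasmid cohort summary\n")
  print(x$class_summary, row.names = FALSE)
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (is.null(t)) next
    cat(sprintf("\n%s ~ mobility: Kruskal-Wallis H = %.4g, p = %.3g\n",
                nm, t$kw$h_statistic, t$kw$kw_p))
    print(t$dunn, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$arg_table) && nrow(x$arg_table)) {
    cat("\nARG occurrence (pct_mobile = % of carriers conjugative or",
        "mobilizable):\n")
    print(utils::head(x$arg_table[order(-x$arg_table$n_plasmids), ], 10),
          row.names = FALSE)
  }
  for (n in x$notices) cat("note:", n, "\n")
  invisible(x)
}

#' Write the machine-readable stats and summary tables
#'
#' @param summary object from [summarize_cohort()].
#' @param json_path path for `stats.json`.
#' @param tsv_path path for `summary.tsv` (the class summary).
#' @return invisibly, the paths.
#' @export
write_stats <- function(summary, json_path, tsv_path) {
  ser <- function(x) {
    if (is.numeric(x)) return(signif(x, 6))
    if (is.data.frame(x)) { x[] <- lapply(x, ser); return(x) }
    if (is.list(x)) return(lapply(x, ser))
    x
  }
  jsonlite::write_json(ser(unclass(summary)), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  write.table(summary$class_summary, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
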