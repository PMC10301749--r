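#' Run configuration for the characterization pipeline
#'
#' Collects the run-wide constants: per-category hit thresholds, the ORF
#' caller floor, topology, ANI fragment size / threshold / linkage, the
#' broad-host-range minimum feature count, the mobilizable rule, the T-AT
#' pair mode and output handling. Every value can also come from a YAML
#' file via [read_run_config()]; explicit arguments win.
#'
#' @param plasmids path to the plasmid FASTA, or a table from
#'   [plasmid_records()].
#' @param refs_dir directory with `panel_<category>.fasta` files, or a
#'   reference table from [load_reference_sets()].
#' @param out_dir output directory (`NULL` = return results only).
#' @param thresholds named per-category threshold list.
#' @param min_orf_nt minimum ORF length (nt).
#' @param topology `"linear"` or `"circular"`.
#' @param ani run ANI clustering on the BHR candidates.
#' @param ani_fragment_nt,ani_threshold_pct,ani_linkage ANI parameters.
#' @param bhr_min_features candidate threshold (default 3 of 5).
#' @param mobilizable_rule `"strict_paper"` or `"relaxase_or_orit"`.
#' @param tat_pair_required complete cognate pair required for the T-AT
#'   feature.
#' @param t4ss_min_genes,require_atpase T4SS machinery rule knobs.
#' @param seed seed for any stochastic step (none in the default path; kept
#'   for reproducibility of optional permutation p-values).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return list of class `plasbhr_config`.
#' @export
plasbhr_config <- function(plasmids = NULL, refs_dir = NULL, out_dir = NULL,
                           thresholds = default_thresholds(),
                           min_orf_nt = 90L, topology = "linear",
                           ani = TRUE, ani_fragment_nt = 1000L,
                           ani_threshold_pct = 95,
                           ani_linkage = c("single", "complete"),
                           bhr_min_features = 3L,
                           mobilizable_rule = c("strict_paper",
                                                "relaxase_or_orit"),
                           tat_pair_required = TRUE,
                           t4ss_min_genes = 3L, require_atpase = TRUE,
                           seed = 1L,
                           log_level = c("info", "quiet", "debug")) {
  structure(list(
    plasmids = plasmids, refs_dir = refs_dir, out_dir = out_dir,
    thresholds = thresholds, min_orf_nt = as.integer(min_orf_nt),
    topology = topology, ani = isTRUE(ani),
    ani_fragment_nt = as.integer(ani_fragment_nt),
    ani_threshold_pct = ani_threshold_pct,
    ani_linkage = match.arg(ani_linkage),
    bhr_min_features = as.integer(bhr_min_features),
    mobilizable_rule = match.arg(mobilizable_rule),
    tat_pair_required = isTRUE(tat_pair_required),
    t4ss_min_genes = as.integer(t4ss_min_genes),
    require_atpase = isTRUE(require_atpase),
    seed = as.integer(seed), log_level = match.arg(log_level)),
    class = "plasbhr_config")
}

#' Read a YAML run configuration
#'
#' Field names mirror [plasbhr_config()] arguments; `overrides` (e.g. CLI
#' flags) replace YAML values.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a `plasbhr_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  known <- names(formals(plasbhr_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_plasbhr("unknown config field(s): %s",
                 paste(unknown, collapse = ", "))
  do.call(plasbhr_config, y)
}

.log <- function(cfg, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[cfg$log_level]] >= levels[[level]])
    message(sprintf("[plasbhr] %s", sprintf(fmt, ...)))
}

.resolve_refs <- function(refs_dir) {
  if (is.data.frame(refs_dir)) return(refs_dir)
  files <- list.files(refs_dir, pattern = "^panel_.*\\.fasta$",
                      full.names = TRUE)
  if (!length(files))
    stop_plasbhr("no panel_<category>.fasta files in %s", refs_dir)
  cats <- toupper(sub("^panel_(.*)\\.fasta$", "\\1", basename(files)))
  bad <- setdiff(cats, PLASBHR_CATEGORIES)
  if (length(bad))
    stop_plasbhr("unrecognized reference category file(s): %s",
                 paste(bad, collapse = ", "))
  load_reference_sets(stats::setNames(as.list(files), cats))
}

.resolve_plasmids <- function(plasmids, topology) {
  if (is.data.frame(plasmids)) {
    if (!"length" %in% names(plasmids))
      plasmids <- plasmid_records(plasmids, topology = topology)
    return(plasmids)
  }
  plasmid_records(read_fasta(plasmids, "nucleotide"), topology = topology)
}

#' Run the full plasmid characterization pipeline
#'
#' Composes the pipeline end to end: sequence loading, ORF calling,
#' per-category homology search, mobility classification and typing,
#' feature profiling with the BHR rule, optional ANI clustering of the BHR
#' candidates, and cohort statistics. With `out_dir` set, writes
#' `plasmids.tsv`, `orfs.gff3`, `orfs.faa`, `hits.tsv`, `mobility.tsv`,
#' `features.tsv`, `ani.tsv`, `clusters.tsv`, the joined `profile.tsv`,
#' `stats.json`, `summary.tsv` and a `manifest.json` with a config hash
#' and file checksums. The run is deterministic given its inputs and
#' configuration.
#'
#' @param config a [plasbhr_config()]; `plasmids`/`refs_dir` may also be
#'   passed directly.
#' @param plasmids,refs_dir,out_dir optional overrides of the config.
#' @return object of class `plasbhr_run`: plasmids, orfs, hits, mobility,
#'   features, ani, clusters, profile, stats, config.
#' @export
run_characterize <- function(config = plasbhr_config(), plasmids = NULL,
                             refs_dir = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "plasbhr_config"))
  if (!is.null(plasmids)) config$plasmids <- plasmids
  if (!is.null(refs_dir)) config$refs_dir <- refs_dir
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$plasmids) || is.null(config$refs_dir))
    stop_plasbhr("run_characterize needs plasmids and refs_dir")

  plasmids <- .resolve_plasmids(config$plasmids, config$topology)
  refs <- .resolve_refs(config$refs_dir)
  .log(config, "info", "loaded %d plasmids, %d reference entries",
       nrow(plasmids), nrow(refs))

  orfs <- find_orfs_cohort(plasmids, min_length_nt = config$min_orf_nt)
  .log(config, "info", "called %d ORFs", nrow(orfs))

  hits <- search_all_categories(refs, orfs, plasmids, config$thresholds)
  .log(config, "info", "%d hits passed category thresholds", nrow(hits))

  calls <- mobility_table(hits, plasmids$id,
                          mobilizable_rule = config$mobilizable_rule,
                          t4ss_min_genes = config$t4ss_min_genes,
                          require_atpase = config$require_atpase)
  features <- profile_table(hits, plasmids$id,
                            bhr_min_features = config$bhr_min_features,
                            tat_pair_required = config$tat_pair_required)

  ani <- NULL
  clusters <- NULL
  cand <- features$plasmid_id[features$bhr_candidate]
  if (config$ani && length(cand) >= 2L) {
    sub <- plasmids[match(cand, plasmids$id), , drop = FALSE]
    frag <- min(config$ani_fragment_nt, min(sub$length))
    if (frag < config$ani_fragment_nt)
      .log(config, "info",
           "ANI fragment size lowered to %d nt (shortest candidate)", frag)
    ani <- ani_matrix(sub, fragment_nt = frag)
    clusters <- cluster_at_threshold(ani, cand,
                                     threshold_pct = config$ani_threshold_pct,
                                     linkage = config$ani_linkage)
    .log(config, "info", "clustered %d BHR candidates into %d plasmid types",
         length(cand), max(clusters$cluster_id))
  } else if (config$ani) {
    .log(config, "info",
         "ANI step skipped: %d BHR candidate(s)", length(cand))
  }

  stats <- summarize_cohort(features, calls, plasmids)

  profile <- merge(calls, features, by = "plasmid_id")
  if (!is.null(clusters)) {
    profile <- merge(profile,
                     clusters[, c("plasmid_id", "cluster_id",
                                  "cluster_size")],
                     by = "plasmid_id", all.x = TRUE)
  } else {
    profile$cluster_id <- NA_integer_
    profile$cluster_size <- NA_integer_
  }
  profile <- profile[order(profile$plasmid_id), , drop = FALSE]
  rownames(profile) <- NULL

  run <- structure(list(plasmids = plasmids, orfs = orfs, hits = hits,
                        mobility = calls, features = features, ani = ani,
                        clusters = clusters, profile = profile,
                        stats = stats, config = config),
                   class = "plasbhr_run")
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

.write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_plasmids_tsv(run$plasmids, p("plasmids.tsv"))
  write_orfs_gff3(run$orfs, p("orfs.gff3"))
  write_orfs_faa(run$orfs, p("orfs.faa"))
  write_hits_tsv(run$hits, p("hits.tsv"))
  write_mobility_tsv(run$mobility, p("mobility.tsv"))
  write_features_tsv(run$features, p("features.tsv"))
  if (!is.null(run$ani))
    write_ani_tsv(run$ani, run$clusters, p("ani.tsv"), p("clusters.tsv"))
  prof <- run$profile
  num <- vapply(prof, is.numeric, logical(1))
  prof[num] <- lapply(prof[num], function(x)
    ifelse(is.na(x), x, signif(x, 6)))
  write.table(prof, p("profile.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_stats(run$stats, p("stats.json"), p("summary.tsv"))
  files <- setdiff(list.files(dir), "manifest.json")
  cfg <- unclass(run$config)
  cfg$plasmids <- if (is.character(cfg$plasmids)) cfg$plasmids else
    "<in-memory>"
  cfg$refs_dir <- if (is.character(cfg$refs_dir)) cfg$refs_dir else
    "<in-memory>"
  manifest <- list(
    config = cfg,
    config_hash = unname(tools::md5sum(
      textConnection_md5(jsonlite::toJSON(cfg, auto_unbox = TRUE)))),
    checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(as.character(x), tf)
  tf
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [simulate_cohort()] + [write_cohort()].
#'
#' @param config a [sim_config()] (or a YAML path of its fields).
#' @param out_dir output directory.
#' @return the `plasbhr_sim` object, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  if (is.character(config)) config <- do.call(sim_config,
                                              yaml::read_yaml(config))
  sim <- simulate_cohort(config)
  write_cohort(sim, out_dir)
  invisible(sim)
}

#' @export
print.plasbhr_run <- function(x, ...) {
  tab <- table(factor(x$mobility$mobility,
                      levels = c("conjugative", "mobilizable",
                                 "non_mobilizable")))
  cat(sprintf("plasbhr run: %d plasmids, %d ORFs, %d hits\n",
              nrow(x$plasmids), nrow(x$orfs), nrow(x$hits)))
  cat(sprintf("  mobility: %d conjugative, %d mobilizable, %d non-mobilizable\n",
              tab[["conjugative"]], tab[["mobilizable"]],
              tab[["non_mobilizable"]]))
  cat(sprintf("  BHR candidates (>= %d of 5 features): %d\n",
              x$config$bhr_min_features, sum(x$features$bhr_candidate)))
  if (!is.null(x$clusters))
    cat(sprintf("  candidate plasmid types at %.0f%% ANI: %d\n",
                x$config$ani_threshold_pct, max(x$clusters$cluster_id)))
  invisible(x)
}

#' @export
summary.plasbhr_run <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$stats)
  invisible(object$stats)
}
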