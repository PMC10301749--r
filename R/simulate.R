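#' Deterministic synthetic reference panel
#'
#' Builds a small, seeded reference panel standing in for curated
#' replication / relaxase / T4SS / stability / resistance / virulence
#' reference sets: two Inc replicon families, MOBF/MOBP relaxases, two
#' complete five-gene MPF sets (each with one `*_ATPase` member), three
#' cognate toxin-antitoxin pairs (one with an RNA antitoxin), partitioning
#' (sopB, parA), SOS-inhibition (psiB, psiA), mating-pair stabilization
#' (traN, traG), two methyltransferases, three ARGs with antibiotic
#' classes, two virulence factors, one oriT and one RNA antitoxin. Protein
#' sequences are random draws of 120-350 aa; the same seed always yields a
#' byte-identical panel. All entries are synthetic sequences, not curated
#' database records.
#'
#' @param seed integer seed.
#' @return reference table in [load_reference_sets()] layout.
#' @export
make_reference_panel <- function(seed = 1L) {
  with_seed(derive_seed(seed, 0L), {
    rows <- list()
    add <- function(id, category, family, molecule, len,
                    cognate = NA_character_, arg_class = NA_character_) {
      seqv <- if (molecule == "protein") random_protein(len) else
        random_dna(len)
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, category = category, family = family, molecule = molecule,
        sequence = seqv, cognate_partner = cognate, arg_class = arg_class,
        stringsAsFactors = FALSE)
    }
    plen <- function() sample(120:350, 1L)
    add("RepF_1", "REP", "IncF", "protein", plen())
    add("RepX_1", "REP", "IncX", "protein", plen())
    add("MOBF_1", "RELAXASE", "MOBF", "protein", plen())
    add("MOBP_1", "RELAXASE", "MOBP", "protein", plen())
    for (fam in c("MPFF", "MPFT"))
      for (gene in c("traC_ATPase", "traE", "traK", "traB", "traV"))
        add(paste0(fam, "_", gene), "T4SS", fam, "protein", plen())
    add("ccdB_1", "TOXIN", "ccdB", "protein", plen(), cognate = "ccdA")
    add("vapC_1", "TOXIN", "vapC", "protein", plen(), cognate = "vapB")
    add("hok_1", "TOXIN", "hok", "protein", plen(), cognate = "sok")
    add("ccdA_1", "ANTITOXIN", "ccdA", "protein", plen(), cognate = "ccdB")
    add("vapB_1", "ANTITOXIN", "vapB", "protein", plen(), cognate = "vapC")
    add("sopB_1", "PAR", "sopB", "protein", plen())
    add("parA_1", "PAR", "parA", "protein", plen())
    add("psiB_1", "PSI", "psiB", "protein", plen())
    add("psiA_1", "PSI", "psiA", "protein", plen())
    add("traN_1", "MPS", "traN", "protein", plen())
    add("traG_1", "MPS", "traG", "protein", plen())
    add("mtaseA_1", "MTASE", "mtaseA", "protein", plen())
    add("mtaseB_1", "MTASE", "mtaseB", "protein", plen())
    add("TEM-1_1", "ARG", "TEM-1", "protein", plen(),
        arg_class = "beta_lactam")
    add("sul1_1", "ARG", "sul1", "protein", plen(),
        arg_class = "sulfonamide")
    add("aph3_1", "ARG", "aph3", "protein", plen(),
        arg_class = "aminoglycoside")
    add("espX_1", "VF", "espX", "protein", plen())
    add("vgrG_1", "VF", "vgrG", "protein", plen())
    add("oriT_F_1", "ORIT", "oriT_F", "nucleotide", 150L)
    add("sok_1", "RNA_ANTITOXIN", "sok", "nucleotide", 80L)
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    panel
  })
}

#' Write a reference panel as per-category FASTA files
#'
#' Files are named `panel_<category>.fasta` (lower-case category) with
#' `id|family[|partner_or_class]` headers, the layout
#' [load_reference_sets()] reads back.
#'
#' @param panel reference table (see [make_reference_panel()]).
#' @param dir output directory (created if needed).
#' @return named character vector of paths (by category), invisibly.
#' @export
write_reference_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cats <- unique(panel$category)
  paths <- stats::setNames(
    file.path(dir, sprintf("panel_%s.fasta", tolower(cats))), cats)
  for (cat in cats) {
    sub <- panel[panel$category == cat, , drop = FALSE]
    third <- ifelse(!is.na(sub$cognate_partner), sub$cognate_partner,
                    ifelse(!is.na(sub$arg_class), sub$arg_class, NA))
    hdr <- ifelse(is.na(third), paste(sub$id, sub$family, sep = "|"),
                  paste(sub$id, sub$family, third, sep = "|"))
    write_fasta(data.frame(id = hdr, sequence = sub$sequence,
                           header = hdr), paths[[cat]])
  }
  invisible(paths)
}

# substitute round(divergence * length) residues, uniform over the 19
# alternatives at each chosen position
.mutate_protein <- function(protein, divergence) {
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n_sub <- round(divergence * length(ch))
  if (n_sub > 0) {
    pos <- sample(length(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(aa20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

.mutate_dna <- function(sequence, rate, positions = NULL) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- seq_along(ch)
  n_sub <- min(round(rate * length(ch)), length(positions))
  if (n_sub > 0) {
    pos <- if (length(positions) == 1L) positions else
      sample(positions, n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# uniform synonymous-codon reverse translation (table 11, stops excluded)
.reverse_translate <- function(protein) {
  gc11 <- .plasbhr$gencode11
  by_aa <- split(names(gc11), gc11)
  by_aa[["*"]] <- NULL
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop_plasbhr("cannot reverse-translate residue '%s'", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

# overwrite a window of `sequence` with `cassette` at a position whose span
# does not overlap any interval in `occupied` (1-based inclusive matrix)
.place_cassette <- function(sequence, cassette, occupied, max_try = 500L) {
  L <- nchar(sequence)
  lc <- nchar(cassette)
  if (lc > L) stop_plasbhr("cassette (%d nt) longer than backbone (%d nt)",
                           lc, L)
  for (k in seq_len(max_try)) {
    start <- sample.int(L - lc + 1L, 1L)
    end <- start + lc - 1L
    clash <- nrow(occupied) > 0 &&
      any(start <= occupied[, 2] & end >= occupied[, 1])
    if (!clash) {
      seqv <- paste0(substr(sequence, 1L, start - 1L), cassette,
                     substr(sequence, end + 1L, L))
      return(list(sequence = seqv, start = start, end = end))
    }
  }
  stop_plasbhr(
    "no non-overlapping slot for a %d nt cassette; use a longer backbone", lc)
}

#' Plant a diverged protein cassette into a DNA backbone
#'
#' The protein is mutated at `round(divergence * length)` positions,
#' reverse-translated with uniform synonymous codon choice, framed as
#' `ATG + codons + TAA` with an additional in-frame leading stop codon so
#' the planted ORF is recovered exactly by [find_orfs()], and written over
#' a random window of the backbone (replicon length is preserved). The
#' reported span is the ORF itself, 0-based half-open.
#'
#' @param backbone DNA string, long enough for the cassette.
#' @param protein amino-acid string to plant.
#' @param divergence substitution fraction in \[0, 0.6\].
#' @param strand `"+"` or `"-"`.
#' @return list: `sequence` (modified backbone), `span` (`c(start, end)`),
#'   `strand`, `planted_protein` (the mutated protein, leading M included).
#' @export
plant_cassette <- function(backbone, protein, divergence = 0,
                           strand = "+") {
  stopifnot(divergence >= 0, divergence <= 0.6, strand %in% c("+", "-"))
  mut <- .mutate_protein(protein, divergence)
  orf_nt <- paste0("ATG", .reverse_translate(mut), "TAA")
  cassette <- paste0("TAA", orf_nt)              # leading in-frame guard stop
  if (strand == "-") cassette <- revcomp(cassette)
  pl <- .place_cassette(backbone, cassette, occupied = matrix(numeric(0), 0, 2))
  lc <- nchar(cassette)
  span <- if (strand == "+") c(pl$start - 1L + 3L, pl$start - 1L + lc) else
    c(pl$start - 1L, pl$start - 1L + lc - 3L)
  list(sequence = pl$sequence, span = span, strand = strand,
       planted_protein = paste0("M", mut))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the qualitative structure of real clinical plasmid
#' cohorts at desk scale: conjugative plasmids are longer and GC-richer
#' than mobilizable ones, which exceed non-mobilizable ones; ARGs are
#' enriched on mobile plasmids; a few near-identical plasmid groups mimic
#' strain-shared replicons for ANI clustering.
#'
#' @param seed RNG seed for the whole cohort.
#' @param n_plasmids cohort size (cluster copies included).
#' @param class_mix named fractions over
#'   conjugative/mobilizable/non_mobilizable, summing to 1.
#' @param length_meanlog,length_sdlog per-class log-normal parameters of
#'   backbone length (nt).
#' @param gc_per_class per-class backbone GC fraction.
#' @param cassette_divergence amino-acid substitution rate applied to
#'   planted proteins (nucleotide rate for planted oriT/RNA elements), in
#'   \[0, 0.6\].
#' @param feature_prob per-class probability of planting each of the five
#'   host-range feature categories.
#' @param lone_toxin_prob probability of a toxin without its antitoxin when
#'   the T-AT feature was not drawn.
#' @param arg_prob_per_class per-class probability of carrying ARGs.
#' @param vf_prob probability of a virulence factor.
#' @param relaxase_in_mob_prob probability a mobilizable plasmid also
#'   carries a relaxase.
#' @param n_clusters number of planted near-identical groups.
#' @param cluster_copies extra copies per cluster seed.
#' @param within_cluster_subst substitution rate applied to cluster copies
#'   (outside planted cassettes, so planted truth is conserved).
#' @param min_length_nt floor on backbone length.
#' @return validated config list of class `plasbhr_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_plasmids = 60L,
                       class_mix = c(conjugative = 0.47,
                                     mobilizable = 0.29,
                                     non_mobilizable = 0.24),
                       length_meanlog = c(conjugative = log(12000),
                                          mobilizable = log(6000),
                                          non_mobilizable = log(2500)),
                       length_sdlog = c(conjugative = 0.25,
                                        mobilizable = 0.30,
                                        non_mobilizable = 0.35),
                       gc_per_class = c(conjugative = 0.55,
                                        mobilizable = 0.50,
                                        non_mobilizable = 0.45),
                       cassette_divergence = 0.05,
                       feature_prob = c(conjugative = 0.45,
                                        mobilizable = 0.35,
                                        non_mobilizable = 0.10),
                       lone_toxin_prob = 0.15,
                       arg_prob_per_class = c(conjugative = 0.70,
                                              mobilizable = 0.60,
                                              non_mobilizable = 0.15),
                       vf_prob = 0.15,
                       relaxase_in_mob_prob = 0.5,
                       n_clusters = 3L,
                       cluster_copies = 2L,
                       within_cluster_subst = 0.02,
                       min_length_nt = 1000L) {
  classes <- c("conjugative", "mobilizable", "non_mobilizable")
  cfg <- list(seed = as.integer(seed), n_plasmids = as.integer(n_plasmids),
              class_mix = class_mix, length_meanlog = length_meanlog,
              length_sdlog = length_sdlog, gc_per_class = gc_per_class,
              cassette_divergence = cassette_divergence,
              feature_prob = feature_prob,
              lone_toxin_prob = lone_toxin_prob,
              arg_prob_per_class = arg_prob_per_class, vf_prob = vf_prob,
              relaxase_in_mob_prob = relaxase_in_mob_prob,
              n_clusters = as.integer(n_clusters),
              cluster_copies = as.integer(cluster_copies),
              within_cluster_subst = within_cluster_subst,
              min_length_nt = as.integer(min_length_nt))
  for (nm in c("class_mix", "length_meanlog", "length_sdlog",
               "gc_per_class", "feature_prob", "arg_prob_per_class")) {
    if (!all(classes %in% names(cfg[[nm]])))
      stop_plasbhr("%s must be named with all of: %s", nm,
                   paste(classes, collapse = ", "))
    cfg[[nm]] <- cfg[[nm]][classes]
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    stop_plasbhr("class_mix must sum to 1 (got %.6f)", sum(cfg$class_mix))
  probs <- c(cfg$class_mix, cfg$gc_per_class, cfg$feature_prob,
             cfg$arg_prob_per_class, cfg$lone_toxin_prob, cfg$vf_prob,
             cfg$relaxase_in_mob_prob, cfg$within_cluster_subst)
  if (any(probs < 0 | probs > 1))
    stop_plasbhr("all probabilities must lie in [0, 1]")
  if (cfg$cassette_divergence < 0 || cfg$cassette_divergence > 0.6)
    stop_plasbhr("cassette_divergence must lie in [0, 0.6]")
  if (cfg$n_plasmids < cfg$n_clusters * (cfg$cluster_copies + 1L))
    stop_plasbhr("n_plasmids too small for %d clusters of %d copies",
                 cfg$n_clusters, cfg$cluster_copies + 1L)
  if (cfg$min_length_nt < 1000L)
    stop_plasbhr("min_length_nt must be at least 1000")
  structure(cfg, class = "plasbhr_sim_config")
}

# generate one base plasmid; returns plasmid row + truth row
.simulate_plasmid <- function(i, cfg, panel, force_bhr = FALSE) {
  with_seed(derive_seed(cfg$seed, i), {
    id <- sprintf("P%03d", i)
    cls <- sample(names(cfg$class_mix), 1L, prob = cfg$class_mix)
    pick <- function(category, family = NULL) {
      sub <- panel[panel$category == category, , drop = FALSE]
      if (!is.null(family)) sub <- sub[sub$family %in% family, , drop = FALSE]
      sub[sample.int(nrow(sub), 1L), , drop = FALSE]
    }
    plan <- list(pick("REP"))
    if (cls == "conjugative") {
      plan <- c(plan, list(pick("RELAXASE")))
      mpf <- sample(c("MPFF", "MPFT"), 1L)
      t4 <- panel[panel$category == "T4SS" & panel$family == mpf, ,
                  drop = FALSE]
      plan <- c(plan, lapply(seq_len(nrow(t4)),
                             function(r) t4[r, , drop = FALSE]))
      plan <- c(plan, list(pick("ORIT")))
    } else if (cls == "mobilizable") {
      plan <- c(plan, list(pick("ORIT")))
      if (runif(1) < cfg$relaxase_in_mob_prob)
        plan <- c(plan, list(pick("RELAXASE")))
    }
    p_feat <- cfg$feature_prob[[cls]]
    feats <- stats::runif(5) < p_feat
    names(feats) <- c("tat", "par", "psi", "mps", "mtase")
    if (force_bhr) feats[sample(5L, 4L)] <- TRUE
    if (feats["tat"]) {
      tox <- pick("TOXIN")
      plan <- c(plan, list(tox))
      anti_cat <- if (tox$family == "hok") "RNA_ANTITOXIN" else "ANTITOXIN"
      plan <- c(plan, list(pick(anti_cat, family = tox$cognate_partner)))
    } else if (runif(1) < cfg$lone_toxin_prob) {
      plan <- c(plan, list(pick("TOXIN")))
    }
    if (feats["par"]) plan <- c(plan, list(pick("PAR")))
    if (feats["psi"]) plan <- c(plan, list(pick("PSI")))
    if (feats["mps"]) plan <- c(plan, list(pick("MPS")))
    if (feats["mtase"]) plan <- c(plan, list(pick("MTASE")))
    if (runif(1) < cfg$arg_prob_per_class[[cls]]) {
      n_arg <- sample(1:2, 1L)
      args <- panel[panel$category == "ARG", , drop = FALSE]
      sel <- sample.int(nrow(args), n_arg)
      plan <- c(plan, lapply(sel, function(r) args[r, , drop = FALSE]))
    }
    if (runif(1) < cfg$vf_prob) plan <- c(plan, list(pick("VF")))
    plan <- do.call(rbind, plan)

    cass_len <- ifelse(plan$molecule == "protein",
                       3L * nchar(plan$sequence) + 9L, nchar(plan$sequence))
    need <- ceiling(1.6 * sum(cass_len)) + 300L
    L <- max(round(rlnorm(1, cfg$length_meanlog[[cls]],
                          cfg$length_sdlog[[cls]])),
             need, cfg$min_length_nt)
    seqv <- random_dna(L, cfg$gc_per_class[[cls]])

    # build every cassette, then place them by a randomized partition of the
    # free backbone (always feasible, spans never overlap)
    n_cass <- nrow(plan)
    strands <- sample(c("+", "-"), n_cass, replace = TRUE)
    cassettes <- character(n_cass)
    for (r in seq_len(n_cass)) {
      if (plan$molecule[r] == "protein") {
        mut <- .mutate_protein(plan$sequence[r], cfg$cassette_divergence)
        cassettes[r] <- paste0("TAA", "ATG", .reverse_translate(mut), "TAA")
      } else {
        cassettes[r] <- .mutate_dna(plan$sequence[r], cfg$cassette_divergence)
      }
      if (strands[r] == "-") cassettes[r] <- revcomp(cassettes[r])
    }
    lc <- nchar(cassettes)
    free <- L - sum(lc)
    gaps <- as.vector(stats::rmultinom(1, free, rep(1, n_cass + 1L)))
    ord <- sample.int(n_cass)            # genomic order of the cassettes
    starts <- integer(n_cass)            # 1-based start per cassette
    pos <- 0L
    for (j in seq_len(n_cass)) {
      pos <- pos + gaps[j]
      starts[ord[j]] <- pos + 1L
      pos <- pos + lc[ord[j]]
    }
    occupied <- cbind(starts, starts + lc - 1L)
    spans <- character(n_cass)
    for (r in seq_len(n_cass)) {
      seqv <- paste0(substr(seqv, 1L, starts[r] - 1L), cassettes[r],
                     substr(seqv, starts[r] + lc[r], L))
      p0 <- starts[r] - 1L               # 0-based cassette start
      if (plan$molecule[r] == "protein") {
        span <- if (strands[r] == "+") c(p0 + 3L, p0 + lc[r]) else
          c(p0, p0 + lc[r] - 3L)
      } else {
        span <- c(p0, p0 + lc[r])
      }
      spans[r] <- sprintf("%s:%d-%d:%s", plan$category[r], span[1], span[2],
                          strands[r])
    }
    tat_pair <- unname(feats["tat"])
    n_feat <- sum(feats)
    planted <- paste(sprintf("%s:%s", plan$category, plan$family),
                     collapse = ";")
    list(
      plasmid = data.frame(id = id, sequence = seqv, stringsAsFactors = FALSE),
      truth = data.frame(
        plasmid_id = id, true_class = cls, planted_categories = planted,
        true_bhr = n_feat >= 3L, true_cluster = 0L,
        spans = paste(spans, collapse = ";"), stringsAsFactors = FALSE),
      occupied = occupied)
  })
}

#' Simulate a plasmid cohort with planted ground truth
#'
#' Each plasmid draws a mobility class from `class_mix`, a backbone length
#' from its class log-normal (extended if needed to fit the planted
#' cassettes) and iid bases at the class GC. Cassettes realize the class
#' (conjugative: relaxase + a complete five-gene MPF set + oriT;
#' mobilizable: oriT with an optional relaxase; non-mobilizable: none),
#' the five host-range features, ARGs and virulence factors at the
#' configured probabilities. The first `n_clusters` plasmids act as cluster
#' seeds (forced broad-host-range so dereplication has work to do) and are
#' copied `cluster_copies` times with `within_cluster_subst` substitutions
#' outside the planted cassettes. The run is fully reproducible from the
#' seed, and plasmid `i` is stable under changes of `n_plasmids`.
#'
#' @param config a [sim_config()] object (or arguments for one).
#' @return list of class `plasbhr_sim`: `plasmids` ([plasmid_records()]
#'   layout), `panel` (reference table), `truth` (one row per plasmid),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "plasbhr_sim_config")) config <- do.call(sim_config,
                                                                 config)
  panel <- make_reference_panel(config$seed)
  n_copies <- config$n_clusters * config$cluster_copies
  n_base <- config$n_plasmids - n_copies
  base <- lapply(seq_len(n_base), function(i)
    .simulate_plasmid(i, config, panel,
                      force_bhr = i <= config$n_clusters))
  plasmids <- do.call(rbind, lapply(base, `[[`, "plasmid"))
  truth <- do.call(rbind, lapply(base, `[[`, "truth"))

  for (k in seq_len(config$n_clusters)) {
    truth$true_cluster[k] <- k
    seed_row <- base[[k]]
    occ <- seed_row$occupied
    L <- nchar(seed_row$plasmid$sequence)
    keep_free <- setdiff(seq_len(L),
                         unlist(lapply(seq_len(nrow(occ)), function(r)
                           seq(occ[r, 1], occ[r, 2]))))
    for (cc in seq_len(config$cluster_copies)) {
      cid <- sprintf("P%03d_c%d", k, cc)
      seqv <- with_seed(derive_seed(config$seed, 100000L + 1000L * k + cc),
                        .mutate_dna(seed_row$plasmid$sequence,
                                    config$within_cluster_subst,
                                    positions = keep_free))
      plasmids <- rbind(plasmids,
                        data.frame(id = cid, sequence = seqv,
                                   stringsAsFactors = FALSE))
      tr <- seed_row$truth
      tr$plasmid_id <- cid
      tr$true_cluster <- k
      truth <- rbind(truth, tr)
    }
  }
  plasmids <- plasmid_records(plasmids)
  rownames(plasmids) <- rownames(truth) <- NULL
  structure(list(plasmids = plasmids, panel = panel, truth = truth,
                 config = config), class = "plasbhr_sim")
}

#' Write a simulated cohort to disk
#'
#' Writes `cohort.fasta`, the per-category `panel_<category>.fasta` files
#' and `truth.tsv`.
#'
#' @param sim object from [simulate_cohort()].
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "plasbhr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "cohort.fasta")
  write_fasta(sim$plasmids[, c("id", "sequence")], fasta)
  panel_paths <- write_reference_panel(sim$panel, dir)
  truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(cohort = fasta, panel = panel_paths, truth = truth))
}
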