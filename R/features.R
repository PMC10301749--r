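#' Detect a complete toxin-antitoxin system
#'
#' A T-AT system is complete when some toxin hit's cognate partner family is
#' present among the antitoxin hits (protein antitoxins or RNA antitoxins
#' found by the nucleotide search).
#'
#' @param hits hit table rows for one plasmid.
#' @return list with `tat_system` (logical), `toxins_found`,
#'   `antitoxins_found` (sorted character vectors of families).
#' @export
detect_tat <- function(hits) {
  tox <- hits[hits$category == "TOXIN", , drop = FALSE]
  anti <- hits[hits$category %in% c("ANTITOXIN", "RNA_ANTITOXIN"), ,
               drop = FALSE]
  toxins <- sort(unique(tox$family))
  antitoxins <- sort(unique(anti$family))
  partners <- tox$cognate_partner[!is.na(tox$cognate_partner)]
  tat <- any(partners %in% antitoxins)
  list(tat_system = tat, toxins_found = toxins,
       antitoxins_found = antitoxins)
}

#' Host-range feature profile for one plasmid
#'
#' Five host-range feature categories are scored: a complete cognate
#' toxin-antitoxin pair (or any toxin when `tat_pair_required = FALSE`),
#' partitioning, SOS inhibition, mating-pair stabilization, and
#' methyltransferase presence. A plasmid with at least `bhr_min_features`
#' of the five is flagged as a broad-host-range candidate. ARG and
#' virulence-factor content is collected alongside.
#'
#' @param plasmid_id plasmid id.
#' @param hits hit table rows for this plasmid.
#' @param bhr_min_features candidate threshold (default 3 of 5).
#' @param tat_pair_required require the complete cognate pair for the T-AT
#'   feature (default), or accept a lone toxin.
#' @return one-row data.frame: `plasmid_id`, `tat_system`, `par`, `psi`,
#'   `mps`, `mtase`, `n_features`, `bhr_candidate`, and comma-joined sorted
#'   sets `toxins`, `antitoxins`, `args`, `arg_classes`, `vfs`.
#' @export
build_profile <- function(plasmid_id, hits, bhr_min_features = 3L,
                          tat_pair_required = TRUE) {
  if (nrow(hits) && !all(hits$plasmid_id == plasmid_id))
    stop_plasbhr("build_profile: hits carry a different plasmid_id")
  tat <- detect_tat(hits)
  tat_flag <- if (tat_pair_required) tat$tat_system else
    length(tat$toxins_found) > 0L
  has <- function(cat) any(hits$category == cat)
  flags <- c(tat_system = tat_flag, par = has("PAR"), psi = has("PSI"),
             mps = has("MPS"), mtase = has("MTASE"))
  n_features <- sum(flags)
  argrows <- hits[hits$category == "ARG", , drop = FALSE]
  setcol <- function(x) paste(sort(unique(x[!is.na(x)])), collapse = ",")
  data.frame(
    plasmid_id = plasmid_id,
    tat_system = unname(flags["tat_system"]), par = unname(flags["par"]),
    psi = unname(flags["psi"]), mps = unname(flags["mps"]),
    mtase = unname(flags["mtase"]),
    n_features = n_features,
    bhr_candidate = n_features >= bhr_min_features,
    toxins = setcol(tat$toxins_found),
    antitoxins = setcol(tat$antitoxins_found),
    args = setcol(argrows$family),
    arg_classes = setcol(argrows$arg_class),
    vfs = setcol(hits$family[hits$category == "VF"]),
    stringsAsFactors = FALSE)
}

#' Feature profiles for a whole cohort
#'
#' @param hits cohort hit table.
#' @param plasmid_ids all plasmid ids (plasmids without hits get an
#'   all-false profile).
#' @inheritParams build_profile
#' @return data.frame, one row per plasmid.
#' @export
profile_table <- function(hits, plasmid_ids, bhr_min_features = 3L,
                          tat_pair_required = TRUE) {
  out <- lapply(plasmid_ids, function(id)
    build_profile(id, hits[hits$plasmid_id == id, , drop = FALSE],
                  bhr_min_features = bhr_min_features,
                  tat_pair_required = tat_pair_required))
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Virulence-free broad-host-range candidates
#'
#' Candidate plasmids (BHR flag set) that carry no virulence-factor hit.
#'
#' @param profiles table from [profile_table()].
#' @return sorted character vector of plasmid ids.
#' @export
vf_free_subset <- function(profiles) {
  sort(profiles$plasmid_id[profiles$bhr_candidate & !nzchar(profiles$vfs)])
}

#' Write the feature table
#'
#' @param profiles table from [profile_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
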