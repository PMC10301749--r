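.is_atpase <- function(ref_id, family) {
  grepl("_ATPase$", ref_id) | grepl("_ATPase$", family)
}

.mpf_family <- function(family) sub("_ATPase$", "", family)

#' Mobility call for one plasmid
#'
#' A plasmid is conjugative when it encodes both a relaxase and the T4SS
#' (mating-pair formation) machinery; the T4SS rule requires at least one
#' hit to an MPF ATPase reference (VirB4/TraC class, flagged by an
#' `_ATPase` suffix on the reference id or family) and at least
#' `t4ss_min_genes` distinct T4SS reference genes in total. Under the
#' default `"strict_paper"` rule a non-conjugative plasmid is mobilizable
#' when an oriT is detected; under `"relaxase_or_orit"` a relaxase alone
#' also suffices (transfer in trans). Everything else is non-mobilizable.
#'
#' @param hits hit table rows for a single plasmid (may be empty).
#' @param plasmid_id the plasmid id (required when `hits` is empty).
#' @param mobilizable_rule `"strict_paper"` or `"relaxase_or_orit"`.
#' @param t4ss_min_genes minimum number of distinct T4SS genes.
#' @param require_atpase require an MPF ATPase hit for T4SS presence.
#' @return one-row data.frame: `plasmid_id`, `mobility`,
#'   `relaxase_present`, `t4ss_present`, `orit_present`, `mob_type`,
#'   `mpf_type`, `inc_types` (comma-joined, sorted).
#' @export
call_mobility <- function(hits, plasmid_id = NULL,
                          mobilizable_rule = c("strict_paper",
                                               "relaxase_or_orit"),
                          t4ss_min_genes = 3L, require_atpase = TRUE) {
  mobilizable_rule <- match.arg(mobilizable_rule)
  if (is.null(plasmid_id)) {
    ids <- unique(hits$plasmid_id)
    if (length(ids) != 1L)
      stop_plasbhr("call_mobility: hits must belong to one plasmid")
    plasmid_id <- ids
  } else if (nrow(hits) && !all(hits$plasmid_id == plasmid_id)) {
    stop_plasbhr("call_mobility: hits carry a different plasmid_id")
  }
  rel <- hits[hits$category == "RELAXASE", , drop = FALSE]
  t4 <- hits[hits$category == "T4SS", , drop = FALSE]
  ori <- hits[hits$category == "ORIT", , drop = FALSE]
  relaxase_present <- nrow(rel) > 0L
  orit_present <- nrow(ori) > 0L
  n_t4_genes <- length(unique(t4$ref_id))
  has_atpase <- any(.is_atpase(t4$ref_id, t4$family))
  t4ss_present <- n_t4_genes >= t4ss_min_genes &&
    (!require_atpase || has_atpase)
  mobility <- if (relaxase_present && t4ss_present) {
    "conjugative"
  } else if (orit_present ||
             (mobilizable_rule == "relaxase_or_orit" && relaxase_present)) {
    "mobilizable"
  } else {
    "non_mobilizable"
  }
  ty <- assign_types(hits, t4ss_present = t4ss_present)
  data.frame(plasmid_id = plasmid_id, mobility = mobility,
             relaxase_present = relaxase_present,
             t4ss_present = t4ss_present, orit_present = orit_present,
             mob_type = if (relaxase_present) ty$mob_type else NA_character_,
             mpf_type = if (t4ss_present) ty$mpf_type else NA_character_,
             inc_types = ty$inc_types, stringsAsFactors = FALSE)
}

#' MOB / MPF / Inc type assignment for one plasmid
#'
#' `mob_type` is the family of the highest-bitscore relaxase hit
#' (lexicographically smallest family on ties); `mpf_type` is the MPF
#' family with the most distinct T4SS gene hits (family of the highest
#' single bitscore on ties); `inc_types` is the set of all replicon (Rep)
#' hit families, so multi-replicon plasmids keep every Inc type.
#'
#' @param hits hit table rows for one plasmid.
#' @param t4ss_present report `mpf_type` regardless; callers gate on this.
#' @return list with `mob_type`, `mpf_type`, `inc_types` (comma-joined
#'   sorted string, empty if none).
#' @export
assign_types <- function(hits, t4ss_present = TRUE) {
  rel <- hits[hits$category == "RELAXASE", , drop = FALSE]
  mob_type <- NA_character_
  if (nrow(rel)) {
    best <- max(rel$bitscore)
    fams <- sort(rel$family[rel$bitscore == best])
    mob_type <- fams[1]
  }
  t4 <- hits[hits$category == "T4SS", , drop = FALSE]
  mpf_type <- NA_character_
  if (nrow(t4)) {
    fam <- .mpf_family(t4$family)
    n_genes <- tapply(t4$ref_id, fam, function(x) length(unique(x)))
    top <- names(n_genes)[n_genes == max(n_genes)]
    if (length(top) > 1L) {
      sub <- t4[fam %in% top, , drop = FALSE]
      top <- .mpf_family(sub$family[which.max(sub$bitscore)])
    }
    mpf_type <- top[1]
  }
  rep <- hits[hits$category == "REP", , drop = FALSE]
  inc <- paste(sort(unique(rep$family)), collapse = ",")
  list(mob_type = mob_type, mpf_type = mpf_type, inc_types = inc)
}

#' Mobility calls for a whole cohort
#'
#' Plasmids without any hit are included as non-mobilizable.
#'
#' @param hits cohort hit table.
#' @param plasmid_ids character vector of all plasmid ids.
#' @inheritParams call_mobility
#' @return data.frame, one row per plasmid (see [call_mobility()]).
#' @export
mobility_table <- function(hits, plasmid_ids,
                           mobilizable_rule = c("strict_paper",
                                                "relaxase_or_orit"),
                           t4ss_min_genes = 3L, require_atpase = TRUE) {
  mobilizable_rule <- match.arg(mobilizable_rule)
  out <- lapply(plasmid_ids, function(id)
    call_mobility(hits[hits$plasmid_id == id, , drop = FALSE],
                  plasmid_id = id, mobilizable_rule = mobilizable_rule,
                  t4ss_min_genes = t4ss_min_genes,
                  require_atpase = require_atpase))
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Write the mobility table
#'
#' @param calls table from [mobility_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mobility_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
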