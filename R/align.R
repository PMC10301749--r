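#' Karlin-Altschul parameters used for E-values
#'
#' Published gapped-BLAST constants for BLOSUM62 with gap open 11 / extend 1
#' are used in protein mode. In nucleotide mode, lambda is the ungapped
#' solution for the +2/-3 scheme at uniform base composition (computed at
#' load time) and K is a configurable constant. Composition-adjusted
#' statistics and per-matrix gapped-lambda recomputation are deliberately
#' not implemented; E-values here serve the fixed filter semantics, not
#' BLAST-number reproduction.
#'
#' @param mode `"protein"` or `"nucleotide"`.
#' @return list with elements `lambda` and `K`.
#' @export
ka_params <- function(mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (mode == "protein") list(lambda = 0.267, K = 0.041)
  else list(lambda = .plasbhr$lambda_nt, K = 0.41)
}

#' Bit score from a raw alignment score
#'
#' `bits = (lambda * S - ln K) / ln 2`.
#'
#' @param raw_score integer raw score.
#' @inheritParams ka_params
#' @return numeric bit score.
#' @export
bitscore <- function(raw_score, mode = c("protein", "nucleotide")) {
  p <- ka_params(mode)
  (p$lambda * raw_score - log(p$K)) / log(2)
}

#' Karlin-Altschul expectation value
#'
#' `E = m * n * 2^(-bits)`, with `m` the reference (query) length and `n`
#' the total database length. Monotone non-increasing in the raw score.
#'
#' @param raw_score integer raw score (>= 0).
#' @param ref_len reference length.
#' @param db_len total residue count of the search database.
#' @inheritParams ka_params
#' @return numeric E-value.
#' @export
evalue <- function(raw_score, ref_len, db_len,
                   mode = c("protein", "nucleotide")) {
  stopifnot(raw_score >= 0, ref_len > 0, db_len > 0)
  ref_len * db_len * 2^(-bitscore(raw_score, mode))
}

.encode_seq <- function(s, mode) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (mode == "protein") {
    idx <- match(ch, .plasbhr_aa_alphabet)
    idx[is.na(idx)] <- match("X", .plasbhr_aa_alphabet)
  } else {
    idx <- match(ch, .plasbhr_nt_alphabet)
    idx[is.na(idx)] <- match("N", .plasbhr_nt_alphabet)  # IUPAC codes -> N
  }
  as.integer(idx)
}

.sw_gap <- function(mode) {
  if (mode == "protein") c(open = 11L, ext = 1L) else c(open = 5L, ext = 2L)
}

.sw_matrix <- function(mode) {
  if (mode == "protein") .plasbhr$blosum62 else .plasbhr$ntmat
}

# single-strand Smith-Waterman on pre-encoded integer vectors
.sw_raw <- function(ref_enc, tgt_enc, mode) {
  g <- .sw_gap(mode)
  sw_align_cpp(ref_enc, tgt_enc, .sw_matrix(mode), g[["open"]], g[["ext"]])
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman with affine gaps: BLOSUM62, gap open 11 / extend 1
#' for protein; match +2 / mismatch -3, gap open 5 / extend 2 for
#' nucleotide. In nucleotide mode both strands of the target are aligned
#' and the better one is returned (the plus strand on score ties). Identity
#' is identical columns over all alignment columns, gap columns included;
#' `ref_cover` is aligned reference residues over the reference length.
#'
#' @param ref reference sequence (query).
#' @param target target sequence (database side).
#' @param mode `"protein"` or `"nucleotide"`.
#' @return list with `raw_score`, `bitscore`, `identity`, `ref_cover`,
#'   `ref_start`, `ref_end`, `tgt_start`, `tgt_end` (0-based half-open,
#'   forward coordinates), `strand` (`"+"`, `"-"`, or `"n/a"` for protein),
#'   `n_match`, `n_cols`.
#' @export
align_local <- function(ref, target, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (!nzchar(ref) || !nzchar(target))
    stop_plasbhr("align_local: empty input sequence")
  ref_enc <- .encode_seq(ref, mode)
  a <- .sw_raw(ref_enc, .encode_seq(target, mode), mode)
  strand <- "n/a"
  if (mode == "nucleotide") {
    strand <- "+"
    n <- nchar(target)
    b <- .sw_raw(ref_enc, .encode_seq(revcomp(target), mode), mode)
    if (b$score > a$score) {
      # convert minus-strand coordinates to forward coordinates
      b2 <- b
      b2$tgt_start <- n - b$tgt_end
      b2$tgt_end <- n - b$tgt_start
      a <- b2
      strand <- "-"
    }
  }
  rl <- length(ref_enc)
  list(raw_score = a$score,
       bitscore = bitscore(a$score, mode),
       identity = if (a$n_cols > 0) a$n_match / a$n_cols else 0,
       ref_cover = (a$ref_end - a$ref_start) / rl,
       ref_start = a$ref_start, ref_end = a$ref_end,
       tgt_start = a$tgt_start, tgt_end = a$tgt_end,
       strand = strand, n_match = a$n_match, n_cols = a$n_cols)
}

#' Per-category hit thresholds
#'
#' Defaults follow the published filter tiers, applied as strict
#' inequalities exactly as printed (an identity of exactly 0.50 fails a
#' ">50%" rule): replication, toxin, antitoxin and RNA-antitoxin hits need
#' E < 1e-5, identity > 50% and reference coverage > 50%; virulence, ARG,
#' T4SS and relaxase hits raise coverage to > 70%; partitioning, SOS
#' inhibition and mating-pair stabilization raise identity to > 80%;
#' methyltransferases use the 50/50 tier; oriT (nucleotide) uses a
#' MOB-typer-style 90/90 tier.
#'
#' @param overrides optional named list of lists with elements `max_evalue`,
#'   `min_identity`, `min_ref_cover` to replace a category's defaults.
#' @return named list of threshold lists, one per category.
#' @export
default_thresholds <- function(overrides = NULL) {
  thr <- function(e, i, c) list(max_evalue = e, min_identity = i,
                                min_ref_cover = c)
  out <- list(
    REP           = thr(1e-5, 0.50, 0.50),
    TOXIN         = thr(1e-5, 0.50, 0.50),
    ANTITOXIN     = thr(1e-5, 0.50, 0.50),
    RNA_ANTITOXIN = thr(1e-5, 0.50, 0.50),
    VF            = thr(1e-5, 0.50, 0.70),
    ARG           = thr(1e-5, 0.50, 0.70),
    T4SS          = thr(1e-5, 0.50, 0.70),
    RELAXASE      = thr(1e-5, 0.50, 0.70),
    PAR           = thr(1e-5, 0.80, 0.70),
    PSI           = thr(1e-5, 0.80, 0.70),
    MPS           = thr(1e-5, 0.80, 0.70),
    MTASE         = thr(1e-5, 0.50, 0.50),
    ORIT          = thr(1e-5, 0.90, 0.90))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) out[[nm]] <- utils::modifyList(
      out[[nm]] %||% thr(1e-5, 0.5, 0.5), overrides[[nm]])
  }
  out
}

#' Does an alignment pass a threshold set?
#'
#' All three filters are strict inequalities.
#'
#' @param evalue,identity,ref_cover alignment statistics.
#' @param thresholds list with `max_evalue`, `min_identity`,
#'   `min_ref_cover`.
#' @return logical.
#' @export
passes_thresholds <- function(evalue, identity, ref_cover, thresholds) {
  evalue < thresholds$max_evalue &
    identity > thresholds$min_identity &
    ref_cover > thresholds$min_ref_cover
}

#' Search one reference category against targets
#'
#' Aligns every reference of one category against every target and keeps at
#' most one hit per (reference, target) pair: the optimal local alignment,
#' if it passes the category thresholds. The database length for E-values is
#' the total residue count of all targets. Protein categories search ORF
#' proteins; nucleotide categories (`ORIT`, `RNA_ANTITOXIN`) search plasmid
#' DNA on both strands.
#'
#' Hopeless pairs are skipped by exact upper bounds (a target shorter than
#' `min_ref_cover * ref_len` can never pass coverage; a perfect-score
#' alignment that would still exceed `max_evalue` can never pass E-value),
#' which cannot change the result set.
#'
#' @param refs reference entries of a single category (see
#'   [load_reference_sets()]).
#' @param targets for protein categories an ORF table (columns `orf_id`,
#'   `plasmid_id`, `protein`); for nucleotide categories a plasmid table
#'   (columns `id`, `sequence`).
#' @param thresholds a single threshold list (see [default_thresholds()]);
#'   defaults to the category's default tier.
#' @return data.frame of hits sorted by `plasmid_id`, `ref_id`,
#'   `target_id`: ref/target ids, category, family, plasmid id, raw score,
#'   bitscore, evalue, identity, ref_cover, spans, strand, and the
#'   reference's cognate partner / ARG class annotations.
#' @export
search_category <- function(refs, targets, thresholds = NULL) {
  if (nrow(refs) == 0L) return(.empty_hits())
  cat <- unique(refs$category)
  if (length(cat) != 1L)
    stop_plasbhr("search_category: refs mix categories (%s)",
                 paste(cat, collapse = ", "))
  mode <- if (cat %in% PLASBHR_NT_CATEGORIES) "nucleotide" else "protein"
  if (is.null(thresholds)) thresholds <- default_thresholds()[[cat]]
  if (mode == "protein") {
    tgt_id <- targets$orf_id
    tgt_plasmid <- targets$plasmid_id
    tgt_seq <- targets$protein
  } else {
    tgt_id <- targets$id
    tgt_plasmid <- targets$id
    tgt_seq <- targets$sequence
  }
  if (length(tgt_seq) == 0L) return(.empty_hits())
  tgt_len <- nchar(tgt_seq)
  db_len <- sum(tgt_len)
  smax_res <- max(diag(.sw_matrix(mode)))
  tgt_enc <- lapply(tgt_seq, .encode_seq, mode = mode)

  rows <- list()
  for (r in seq_len(nrow(refs))) {
    rseq <- refs$sequence[r]
    rlen <- nchar(rseq)
    renc <- .encode_seq(rseq, mode)
    for (t in seq_along(tgt_seq)) {
      # exact prune: best possible coverage
      if (min(rlen, tgt_len[t]) / rlen <= thresholds$min_ref_cover) next
      # exact prune: best possible score still fails the E-value gate
      smax <- smax_res * min(rlen, tgt_len[t])
      if (evalue(smax, rlen, db_len, mode) >= thresholds$max_evalue) next
      a <- .sw_raw(renc, tgt_enc[[t]], mode)
      strand <- if (mode == "nucleotide") "+" else "n/a"
      if (mode == "nucleotide") {
        b <- .sw_raw(renc, .encode_seq(revcomp(tgt_seq[t]), mode), mode)
        if (b$score > a$score) {
          n <- tgt_len[t]
          b2 <- b
          b2$tgt_start <- n - b$tgt_end
          b2$tgt_end <- n - b$tgt_start
          a <- b2
          strand <- "-"
        }
      }
      if (a$score <= 0 || a$n_cols == 0) next
      ident <- a$n_match / a$n_cols
      cover <- (a$ref_end - a$ref_start) / rlen
      ev <- evalue(a$score, rlen, db_len, mode)
      if (!passes_thresholds(ev, ident, cover, thresholds)) next
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = refs$id[r], target_id = tgt_id[t],
        plasmid_id = tgt_plasmid[t], category = cat,
        family = refs$family[r],
        raw_score = a$score, bitscore = bitscore(a$score, mode),
        evalue = ev, identity = ident, ref_cover = cover,
        ref_start = a$ref_start, ref_end = a$ref_end,
        tgt_start = a$tgt_start, tgt_end = a$tgt_end,
        n_cols = a$n_cols, strand = strand,
        cognate_partner = refs$cognate_partner[r],
        arg_class = refs$arg_class[r],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$plasmid_id, hits$ref_id, hits$target_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(ref_id = character(), target_id = character(),
             plasmid_id = character(), category = character(),
             family = character(), raw_score = integer(),
             bitscore = numeric(), evalue = numeric(),
             identity = numeric(), ref_cover = numeric(),
             ref_start = integer(), ref_end = integer(),
             tgt_start = integer(), tgt_end = integer(),
             n_cols = integer(), strand = character(),
             cognate_partner = character(),
             arg_class = character(), stringsAsFactors = FALSE)
}

#' Search every reference category against a cohort
#'
#' @param refs full reference table from [load_reference_sets()].
#' @param orfs ORF table from [find_orfs_cohort()].
#' @param plasmids plasmid table from [plasmid_records()].
#' @param thresholds named list per category (see [default_thresholds()]).
#' @return row-bound hit table over all categories present in `refs`.
#' @export
search_all_categories <- function(refs, orfs, plasmids,
                                  thresholds = default_thresholds()) {
  cats <- intersect(PLASBHR_CATEGORIES, unique(refs$category))
  out <- lapply(cats, function(cat) {
    sub <- refs[refs$category == cat, , drop = FALSE]
    tgt <- if (cat %in% PLASBHR_NT_CATEGORIES) plasmids else orfs
    search_category(sub, tgt, thresholds[[cat]])
  })
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- .empty_hits()
  rownames(hits) <- NULL
  hits
}

#' Write hits as a BLAST outfmt-6-like TSV
#'
#' @param hits hit table from [search_all_categories()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- data.frame(
    ref_id = hits$ref_id, target_id = hits$target_id,
    pident = signif(100 * hits$identity, 6),
    length = hits$n_cols,
    evalue = signif(hits$evalue, 6), bitscore = signif(hits$bitscore, 6),
    ref_cover = signif(100 * hits$ref_cover, 6),
    category = hits$category, family = hits$family,
    plasmid_id = hits$plasmid_id, strand = hits$strand,
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
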