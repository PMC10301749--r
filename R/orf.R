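#' Translate a codon string (bacterial table 11)
#'
#' Codons containing any character other than A/C/G/T (including N) are
#' translated as X; X never terminates an ORF. When `initiator = TRUE` and
#' the first codon is one of the configured start codons it is translated as
#' M, following bacterial usage where GTG/TTG initiators still yield fMet.
#'
#' @param codon_string DNA string with length divisible by 3.
#' @param initiator translate the first codon as M if it is a start codon.
#' @param start_codons character vector of start codons.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_dna <- function(codon_string, initiator = FALSE,
                          start_codons = c("ATG", "GTG", "TTG")) {
  n <- nchar(codon_string)
  if (n %% 3L != 0L)
    stop_plasbhr("translate_dna: length %d is not a multiple of 3", n)
  if (n == 0L) return("")
  s <- toupper(codon_string)
  pos <- seq(1L, n, by = 3L)
  codons <- substring(s, pos, pos + 2L)
  aa <- unname(.plasbhr$gencode11[codons])
  aa[is.na(aa)] <- "X"
  if (initiator && codons[1] %in% start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}

# ORFs on the forward strand of one sequence string, one strand's worth.
# Returns 0-based half-open [start, end) in the coordinates of `s`.
.orfs_one_strand <- function(s, min_length_nt, start_codons) {
  L <- nchar(s)
  out <- vector("list", 3L)
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 2L) next
    pos <- f + seq(1L, by = 3L, length.out = ncod)
    codons <- substring(s, pos, pos + 2L)
    is_stop <- codons %in% stops
    is_start <- codons %in% start_codons
    if (!any(is_stop) || !any(is_start)) next
    # segment index: increments after each stop codon
    seg <- cumsum(c(0L, utils::head(is_stop, -1L)))
    stop_idx <- which(is_stop)
    seg_of_stop <- seg[stop_idx]          # one stop per segment, its last codon
    start_idx <- which(is_start & !is_stop)
    if (length(start_idx) == 0L) next
    first_start <- start_idx[!duplicated(seg[start_idx])]
    m <- match(seg[first_start], seg_of_stop)
    ok <- !is.na(m)
    first_start <- first_start[ok]
    orf_stop <- stop_idx[m[ok]]
    if (length(first_start) == 0L) next
    start_nt <- f + 3L * (first_start - 1L)      # 0-based
    end_nt <- f + 3L * orf_stop                  # exclusive, stop included
    keep <- (end_nt - start_nt) >= min_length_nt
    if (!any(keep)) next
    out[[f + 1L]] <- data.frame(start = start_nt[keep], end = end_nt[keep])
  }
  do.call(rbind, out)
}

#' Find ORFs on both strands of a plasmid
#'
#' Deterministic longest-ORF caller: in each of the six frames an ORF runs
#' from the first start codon (ATG/GTG/TTG by default) after the previous
#' in-frame stop to the next in-frame stop (TAA/TAG/TGA), with the stop
#' codon included in the reported span. Codons containing N translate as X
#' and X never counts as a stop. Reverse-strand ORFs are reported in forward
#' coordinates with strand `-`. Nested and overlapping ORFs in different
#' frames are all reported.
#'
#' For `topology == "circular"` the scan appends a junction-spanning
#' extension (up to 3 kb) and ORFs crossing the origin are reported with
#' `end > length`; ORFs starting inside the extension are dropped as
#' duplicates.
#'
#' @param plasmid one-row data.frame with `id`, `sequence` and optionally
#'   `topology` (from [plasmid_records()]), or a character scalar sequence.
#' @param min_length_nt minimum ORF length in nt, stop codon included; must
#'   be at least 6 and divisible by 3.
#' @param start_codons allowed start codons.
#' @param id plasmid id used for `orf_id`s when `plasmid` is a bare string.
#' @return data.frame with columns `orf_id`, `plasmid_id`, `start`, `end`
#'   (0-based half-open, forward coordinates), `strand`, `protein` (no
#'   terminal stop), sorted by `start` then strand.
#' @export
find_orfs <- function(plasmid, min_length_nt = 90L,
                      start_codons = c("ATG", "GTG", "TTG"), id = "seq") {
  if (is.data.frame(plasmid)) {
    stopifnot(nrow(plasmid) == 1L)
    s <- toupper(plasmid$sequence)
    id <- plasmid$id
    topology <- plasmid$topology %||% "linear"
    if (is.na(topology)) topology <- "linear"
  } else {
    s <- toupper(plasmid)
    topology <- "linear"
  }
  if (min_length_nt < 6L || min_length_nt %% 3L != 0L)
    stop_plasbhr("min_length_nt must be >= 6 and divisible by 3")
  L <- nchar(s)
  scan_seq <- s
  if (identical(topology, "circular")) {
    ext <- min(3000L, L)
    scan_seq <- paste0(s, substr(s, 1L, ext))
  }
  Ls <- nchar(scan_seq)

  fwd <- .orfs_one_strand(scan_seq, min_length_nt, start_codons)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  rcs <- revcomp(scan_seq)
  rev <- .orfs_one_strand(rcs, min_length_nt, start_codons)
  if (!is.null(rev) && nrow(rev)) {
    # map reverse-complement coordinates to forward coordinates
    tmp <- data.frame(start = Ls - rev$end, end = Ls - rev$start,
                      strand = "-")
    rev <- tmp
  }
  orfs <- rbind(fwd, rev)
  if (is.null(orfs) || nrow(orfs) == 0L) {
    return(data.frame(orf_id = character(), plasmid_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  if (identical(topology, "circular")) {
    orfs <- orfs[orfs$start < L, , drop = FALSE]
  }
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  cds <- substring(scan_seq, orfs$start + 1L, orfs$end)
  prot <- character(nrow(orfs))
  for (k in seq_len(nrow(orfs))) {
    x <- cds[k]
    if (orfs$strand[k] == "-") x <- revcomp(x)
    p <- translate_dna(x, initiator = TRUE, start_codons = start_codons)
    prot[k] <- sub("\\*$", "", p)
  }
  data.frame(
    orf_id = paste0(id, "_", seq_len(nrow(orfs))),
    plasmid_id = id,
    start = orfs$start, end = orfs$end, strand = orfs$strand,
    protein = prot, stringsAsFactors = FALSE, row.names = NULL)
}

#' Find ORFs for a whole cohort
#'
#' @param plasmids data.frame from [plasmid_records()].
#' @inheritParams find_orfs
#' @return row-bound ORF table (see [find_orfs()]).
#' @export
find_orfs_cohort <- function(plasmids, min_length_nt = 90L,
                             start_codons = c("ATG", "GTG", "TTG")) {
  out <- lapply(seq_len(nrow(plasmids)), function(i)
    find_orfs(plasmids[i, , drop = FALSE], min_length_nt, start_codons))
  do.call(rbind, out)
}

#' Write ORFs as GFF3
#'
#' Coordinates are converted to 1-based inclusive per the GFF3 convention.
#'
#' @param orfs ORF table from [find_orfs_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf("%s\tplasbhr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     orfs$plasmid_id, orfs$start + 1L, orfs$end,
                     orfs$strand, orfs$orf_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write ORF proteins as FASTA
#'
#' @inheritParams write_orfs_gff3
#' @return `path`, invisibly.
#' @export
write_orfs_faa <- function(orfs, path) {
  write_fasta(data.frame(id = orfs$orf_id, sequence = orfs$protein), path)
  invisible(path)
}
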