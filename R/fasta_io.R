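#' Reference categories
#'
#' The functional categories a reference entry can belong to. `ORIT` and
#' `RNA_ANTITOXIN` are nucleotide references (searched against plasmid DNA);
#' all others are protein references (searched against predicted ORFs).
#'
#' @export
PLASBHR_CATEGORIES <- c("REP", "RELAXASE", "T4SS", "TOXIN", "ANTITOXIN",
                        "PAR", "PSI", "MPS", "MTASE", "ARG", "VF",
                        "ORIT", "RNA_ANTITOXIN")

#' Nucleotide reference categories
#' @rdname PLASBHR_CATEGORIES
#' @export
PLASBHR_NT_CATEGORIES <- c("ORIT", "RNA_ANTITOXIN")

.valid_nt <- "ACGTUNRYSWKMBDHV"
.valid_aa <- "ACDEFGHIKLMNPQRSTVWYBZX"

#' Read a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file. Sequences are
#' uppercased and whitespace-stripped; for nucleotide files U is mapped to T.
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique. Residues are validated against the declared molecule
#' alphabet (IUPAC nucleotide codes are accepted for DNA; they are treated
#' as N downstream).
#'
#' @param path path to a FASTA file.
#' @param molecule `"protein"` or `"nucleotide"`.
#' @return data.frame with columns `id`, `sequence`, `header` (full header
#'   line), in file order.
#' @export
read_fasta <- function(path, molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop_plasbhr("FASTA file not found: %s", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L) stop_plasbhr("empty FASTA file: %s", path)
  if (!startsWith(trimws(first[nonblank[1]]), ">"))
    stop_plasbhr("malformed FASTA header at line %d of %s: expected '>'",
                 nonblank[1], path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("[[:space:]]", "", seqs)
  ids <- sub("[[:space:]].*$", "", headers)
  if (any(!nzchar(ids)))
    stop_plasbhr("malformed FASTA header (empty id) in %s", path)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_plasbhr("duplicate FASTA id '%s' in %s", dup, path)
  }
  if (molecule == "nucleotide") {
    seqs <- chartr("U", "T", seqs)
    bad <- grepl(sprintf("[^%s]", .valid_nt), seqs)
  } else {
    bad <- grepl(sprintf("[^%s*]", .valid_aa), seqs)
    seqs <- sub("\\*$", "", seqs)  # tolerate a trailing stop
    if (!all(nzchar(seqs))) bad <- bad | !nzchar(seqs)
  }
  if (any(bad))
    stop_plasbhr("record '%s' in %s contains residues illegal for %s",
                 ids[which(bad)[1]], path, molecule)
  if (any(!nzchar(seqs)))
    stop_plasbhr("record '%s' in %s has an empty sequence",
                 ids[which(!nzchar(seqs))[1]], path)
  data.frame(id = ids, sequence = unname(seqs), header = unname(headers),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with columns `id` and `sequence` (an optional
#'   `header` column is used verbatim when present).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- if ("header" %in% names(records)) records$header else records$id
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T). N and other ambiguity codes are
#' excluded from both numerator and denominator. Returns `NA_real_` when the
#' sequence contains no unambiguous base.
#'
#' @param sequence non-empty DNA string.
#' @return numeric in \[0, 1\], or `NA_real_` if undefined.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop_plasbhr("gc_content: empty sequence")
  x <- Biostrings::BString(toupper(sequence))
  cnt <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- sum(cnt)
  if (denom == 0) return(NA_real_)
  unname((cnt[["G"]] + cnt[["C"]]) / denom)
}

#' Build plasmid records from sequences
#'
#' Attaches derived length and GC content and validates uniqueness of ids.
#'
#' @param seqs data.frame with `id` and `sequence` columns (e.g. from
#'   [read_fasta()]).
#' @param topology `"linear"` or `"circular"` (recycled).
#' @param source_isolate optional character vector (recycled).
#' @return data.frame with columns `id`, `sequence`, `length`, `gc_content`,
#'   `topology`, `source_isolate`.
#' @export
plasmid_records <- function(seqs, topology = "linear",
                            source_isolate = NA_character_) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  if (anyDuplicated(seqs$id))
    stop_plasbhr("duplicate plasmid id '%s'", seqs$id[duplicated(seqs$id)][1])
  if (any(!nzchar(seqs$sequence)))
    stop_plasbhr("plasmid '%s' has an empty sequence",
                 seqs$id[!nzchar(seqs$sequence)][1])
  stopifnot(all(topology %in% c("linear", "circular")))
  data.frame(
    id = seqs$id,
    sequence = seqs$sequence,
    length = nchar(seqs$sequence),
    gc_content = vapply(seqs$sequence, gc_content, numeric(1),
                        USE.NAMES = FALSE),
    topology = rep_len(topology, nrow(seqs)),
    source_isolate = rep_len(source_isolate, nrow(seqs)),
    stringsAsFactors = FALSE)
}

#' Load category-tagged reference sets
#'
#' Headers follow the dialect `id|family[|third]` where the third field is
#' the cognate partner family for `TOXIN`/`ANTITOXIN` entries and the
#' antibiotic class for `ARG` entries. `ORIT` and `RNA_ANTITOXIN` files are
#' nucleotide; all other categories are protein.
#'
#' @param paths named list/character vector mapping category (see
#'   [PLASBHR_CATEGORIES]) to a FASTA path.
#' @return data.frame of reference entries: `id`, `category`, `family`,
#'   `molecule`, `sequence`, `cognate_partner`, `arg_class`.
#' @export
load_reference_sets <- function(paths) {
  cats <- names(paths)
  if (is.null(cats) || !all(cats %in% PLASBHR_CATEGORIES))
    stop_plasbhr("reference paths must be named by category (%s)",
                 paste(PLASBHR_CATEGORIES, collapse = ", "))
  out <- lapply(cats, function(cat) {
    mol <- if (cat %in% PLASBHR_NT_CATEGORIES) "nucleotide" else "protein"
    fa <- read_fasta(paths[[cat]], molecule = mol)
    parts <- strsplit(fa$id, "|", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 2))
      stop_plasbhr("reference header '%s' (%s): expected 'id|family[|...]'",
                   fa$id[nfield < 2][1], cat)
    id <- vapply(parts, `[`, "", 1L)
    family <- vapply(parts, `[`, "", 2L)
    third <- vapply(parts, function(p) if (length(p) >= 3) p[3] else
      NA_character_, "")
    cognate <- if (cat %in% c("TOXIN", "ANTITOXIN")) third else NA_character_
    argclass <- if (cat == "ARG") third else NA_character_
    if (cat %in% c("TOXIN", "ANTITOXIN") &&
        any(is.na(cognate) | !nzchar(cognate)))
      stop_plasbhr("%s entry '%s' lacks a cognate partner field",
                   cat, id[is.na(cognate) | !nzchar(cognate)][1])
    data.frame(id = id, category = cat, family = family, molecule = mol,
               sequence = fa$sequence, cognate_partner = cognate,
               arg_class = argclass, stringsAsFactors = FALSE)
  })
  refs <- do.call(rbind, out)
  rownames(refs) <- NULL
  refs
}

#' Write the per-plasmid summary table
#'
#' @param plasmids data.frame from [plasmid_records()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_plasmids_tsv <- function(plasmids, path) {
  tab <- plasmids[, c("id", "length", "gc_content", "topology",
                      "source_isolate")]
  names(tab) <- c("id", "length_nt", "gc_content", "topology",
                  "source_isolate")
  tab$gc_content <- signif(tab$gc_content, 6)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
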