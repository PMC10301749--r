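#' Reverse complement of a DNA string
#'
#' Base-R reverse complement over the IUPAC alphabet (ambiguity codes are
#' complemented too; N stays N).
#'
#' @param sequence character scalar, DNA.
#' @return character scalar.
#' @export
revcomp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  from <- "ACGTUNRYSWKMBDHV"
  to   <- "TGCAANYRSWMKVHDB"
  chartr(from, to, paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]),
                         collapse = ""))
}

# run code with a temporarily-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a per-record substream seed from a base seed and a counter, kept
# below 2^31 so set.seed() accepts it
derive_seed <- function(base_seed, counter) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(counter) * 104729) %%
               2147483647)
}

# random sequence helpers (draw from the current RNG stream)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(n) {
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_plasbhr <- function(...) stop(sprintf(...), call. = FALSE)
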