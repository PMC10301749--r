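# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately coded differently from the package internals.

# --- random sequence helpers ------------------------------------------------

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

substitute_dna <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), round(rate * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# --- bacterial code, transcribed independently of the package --------------

TABLE11 <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# --- ORF oracle: plain state-machine walk over each frame -------------------

orf_oracle_one <- function(s, min_len, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  L <- nchar(s)
  for (f in 0:2) {
    in_orf <- FALSE
    orf_start <- NA
    pos <- f + 1
    while (pos + 2 <= L) {
      codon <- substr(s, pos, pos + 2)
      if (!in_orf && codon %in% starts) {
        in_orf <- TRUE
        orf_start <- pos - 1          # 0-based
      }
      if (codon %in% stops) {
        if (in_orf && (pos + 2 - orf_start) >= min_len)
          out[[length(out) + 1]] <- c(orf_start, pos + 2)
        in_orf <- FALSE
      }
      pos <- pos + 3
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind.data.frame, lapply(out, function(x)
    data.frame(start = x[1], end = x[2])))
}

orf_oracle <- function(s, min_len, starts = c("ATG", "GTG", "TTG")) {
  fwd <- orf_oracle_one(s, min_len, starts)
  if (nrow(fwd)) fwd$strand <- "+"
  L <- nchar(s)
  rc <- plasbhr::revcomp(s)
  rev <- orf_oracle_one(rc, min_len, starts)
  if (nrow(rev)) {
    rev <- data.frame(start = L - rev$end, end = L - rev$start, strand = "-")
  }
  res <- rbind(fwd, rev)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# --- Kruskal-Wallis oracle: textbook formula --------------------------------

kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

kw_perm_oracle <- function(groups, n_perm) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  h0 <- kw_oracle(groups)
  hits <- 0
  for (b in seq_len(n_perm)) {
    gp <- sample(g)
    hb <- kw_oracle(split(x, gp))
    if (hb >= h0 - 1e-12) hits <- hits + 1
  }
  (1 + hits) / (n_perm + 1)
}

# --- union-find clustering oracle -------------------------------------------

uf_oracle <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(ids, find, "")
  # renumber by smallest member id
  smallest <- tapply(ids, roots, min)
  lab <- rank(smallest, ties.method = "first")
  stats::setNames(as.integer(lab[match(roots, names(smallest))]), ids)
}

# --- hit-row fixture builder ------------------------------------------------

make_hit <- function(category, family, plasmid_id = "p1",
                     ref_id = paste0(family, "_1"), bitscore = 100,
                     cognate_partner = NA_character_,
                     arg_class = NA_character_) {
  data.frame(ref_id = ref_id, target_id = paste0(plasmid_id, "_1"),
             plasmid_id = plasmid_id, category = category, family = family,
             raw_score = 300L, bitscore = bitscore, evalue = 1e-30,
             identity = 0.95, ref_cover = 0.95, ref_start = 0L,
             ref_end = 100L, tgt_start = 0L, tgt_end = 100L, n_cols = 100L,
             strand = "n/a", cognate_partner = cognate_partner,
             arg_class = arg_class, stringsAsFactors = FALSE)
}

hit_block <- function(...) do.call(rbind, list(...))

# a tiny fully-specified cohort: conjugative machinery on p1, oriT-only p2,
# empty p3
example_hits_p1_conj <- function() {
  rbind(
    make_hit("RELAXASE", "MOBF", "p1"),
    make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traC_ATPase"),
    make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traE"),
    make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traK"),
    make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traB"))
}
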