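# directed fragment-based ANI: fragments of `a` aligned against all of `b`
.directed_ani <- function(a_seq, b_seq, fragment_nt, min_frag_cover,
                          min_frag_identity) {
  la <- nchar(a_seq)
  n_frag <- la %/% fragment_nt           # final short remnant dropped
  starts <- (seq_len(n_frag) - 1L) * fragment_nt + 1L
  idents <- numeric(0)
  b_rc <- revcomp(b_seq)
  b_enc <- .encode_seq(b_seq, "nucleotide")
  b_rc_enc <- .encode_seq(b_rc, "nucleotide")
  for (s in starts) {
    frag <- substr(a_seq, s, s + fragment_nt - 1L)
    # exact-substring shortcut: a verbatim fragment is a perfect alignment
    if (grepl(frag, b_seq, fixed = TRUE) || grepl(frag, b_rc, fixed = TRUE)) {
      idents <- c(idents, 1)
      next
    }
    fe <- .encode_seq(frag, "nucleotide")
    al <- .sw_raw(fe, b_enc, "nucleotide")
    al2 <- .sw_raw(fe, b_rc_enc, "nucleotide")
    if (al2$score > al$score) al <- al2
    if (al$n_cols == 0L) next
    cover <- (al$ref_end - al$ref_start) / fragment_nt
    ident <- al$n_match / al$n_cols
    if (cover >= min_frag_cover && ident >= min_frag_identity)
      idents <- c(idents, ident)
  }
  list(ani = if (length(idents)) 100 * mean(idents) else NA_real_,
       aligned_fraction = if (n_frag) length(idents) / n_frag else 0)
}

#' Fragment-based average nucleotide identity between two plasmids
#'
#' ANIb-style: each sequence is cut into consecutive non-overlapping
#' fragments of `fragment_nt` (the final short remnant is dropped) and each
#' fragment is locally aligned against the whole of the other sequence on
#' both strands. Fragments whose best alignment covers at least
#' `min_frag_cover` of the fragment with identity at least
#' `min_frag_identity` count as aligned; the directed ANI is the mean
#' alignment identity (percent) over aligned fragments. The reported ANI is
#' the mean of the two directed values when both are defined, the defined
#' one otherwise, and `NA` (undefined; never links plasmids) when no
#' fragment aligns in either direction.
#'
#' @param a,b plasmid records (one-row data.frames with `id`, `sequence`)
#'   or bare sequence strings.
#' @param fragment_nt fragment size in nt; both sequences must be at least
#'   this long.
#' @param min_frag_cover,min_frag_identity fragment acceptance gates.
#' @return one-row data.frame: `id_a`, `id_b`, `ani` (percent, `NA` when
#'   undefined), `aligned_fraction` (mean over the defined directions).
#' @export
pairwise_ani <- function(a, b, fragment_nt = 1000L, min_frag_cover = 0.7,
                         min_frag_identity = 0.3) {
  get <- function(x, which) {
    if (is.data.frame(x)) list(id = x$id[1], seq = toupper(x$sequence[1]))
    else list(id = which, seq = toupper(x))
  }
  A <- get(a, "a"); B <- get(b, "b")
  if (nchar(A$seq) < fragment_nt || nchar(B$seq) < fragment_nt)
    stop_plasbhr(
      "pairwise_ani: sequence shorter than fragment_nt = %d (lower it)",
      fragment_nt)
  d1 <- .directed_ani(A$seq, B$seq, fragment_nt, min_frag_cover,
                      min_frag_identity)
  d2 <- .directed_ani(B$seq, A$seq, fragment_nt, min_frag_cover,
                      min_frag_identity)
  anis <- c(d1$ani, d2$ani)
  def <- !is.na(anis)
  ani <- if (any(def)) mean(anis[def]) else NA_real_
  af <- mean(c(d1$aligned_fraction, d2$aligned_fraction))
  data.frame(id_a = A$id, id_b = B$id, ani = ani, aligned_fraction = af,
             stringsAsFactors = FALSE)
}

#' All-pairs ANI for a set of plasmids
#'
#' @param plasmids plasmid table from [plasmid_records()].
#' @inheritParams pairwise_ani
#' @return data.frame of unordered pairs (`id_a < id_b` in input order).
#' @export
ani_matrix <- function(plasmids, fragment_nt = 1000L, min_frag_cover = 0.7,
                       min_frag_identity = 0.3) {
  n <- nrow(plasmids)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      rows[[length(rows) + 1L]] <- pairwise_ani(
        plasmids[i, , drop = FALSE], plasmids[j, , drop = FALSE],
        fragment_nt, min_frag_cover, min_frag_identity)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      ani = numeric(), aligned_fraction = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cluster plasmids at an ANI threshold
#'
#' Builds a graph with an edge wherever `ani >= threshold_pct` (missing or
#' undefined pairs never link) and reports single-linkage clusters as
#' connected components; `linkage = "complete"` instead requires every
#' within-cluster pair to reach the threshold (hierarchical clustering on
#' `100 - ani`, cut at `100 - threshold_pct`). Clusters are numbered
#' 1-based in order of their lexicographically smallest member id.
#'
#' @param results pair table from [ani_matrix()].
#' @param ids all plasmid ids to assign (isolated plasmids become
#'   singletons).
#' @param threshold_pct ANI threshold in percent (default 95).
#' @param linkage `"single"` or `"complete"`.
#' @return data.frame: `plasmid_id`, `cluster_id`, `cluster_size`.
#' @export
cluster_at_threshold <- function(results, ids, threshold_pct = 95,
                                 linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  ids <- as.character(ids)
  if (linkage == "single") {
    edges <- results[!is.na(results$ani) & results$ani >= threshold_pct, ,
                     drop = FALSE]
    g <- igraph::graph_from_data_frame(
      edges[, c("id_a", "id_b")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    member <- comp[ids]
  } else {
    d <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
    diag(d) <- 0
    for (k in seq_len(nrow(results))) {
      if (is.na(results$ani[k])) next
      a <- results$id_a[k]; b <- results$id_b[k]
      d[a, b] <- d[b, a] <- 100 - results$ani[k]
    }
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    member <- stats::cutree(hc, h = 100 - threshold_pct)[ids]
  }
  # deterministic numbering: order clusters by smallest member id
  smallest <- tapply(ids, member, min)
  new_id <- stats::setNames(rank(smallest, ties.method = "first"),
                            names(smallest))
  cluster_id <- as.integer(new_id[as.character(member)])
  size <- as.integer(table(cluster_id)[as.character(cluster_id)])
  data.frame(plasmid_id = ids, cluster_id = cluster_id,
             cluster_size = size, stringsAsFactors = FALSE)
}

#' Write ANI and cluster tables
#'
#' @param ani pair table from [ani_matrix()].
#' @param clusters assignment from [cluster_at_threshold()].
#' @param ani_path,clusters_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_ani_tsv <- function(ani, clusters, ani_path, clusters_path) {
  a <- ani
  a$ani <- signif(a$ani, 6)
  a$aligned_fraction <- signif(a$aligned_fraction, 6)
  write.table(a, ani_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clusters, clusters_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(ani_path, clusters_path))
}
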