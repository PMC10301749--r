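test_that("self-alignment and the BLOSUM62 hand sum are exact", {
  a <- align_local("MKV", "MKV", "protein")
  expect_equal(a$identity, 1.0)
  expect_equal(a$ref_cover, 1.0)
  # BLOSUM62: M/M = 5, K/K = 5, V/V = 4
  expect_equal(a$raw_score, 14L)
})

test_that("protein scores match the Biostrings local-alignment oracle", {
  set.seed(2024)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (i in 1:200) {
    a <- rand_aa(sample(10:40, 1))
    b <- rand_aa(sample(10:40, 1))
    got <- align_local(a, b, "protein")$raw_score
    want <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(got, as.integer(want), label = sprintf("pair %d", i))
  }
})

test_that("nucleotide scores (both strands) match the Biostrings oracle", {
  set.seed(77)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:60) {
    a <- rand_dna(sample(15:60, 1))
    b <- rand_dna(sample(15:60, 1))
    got <- align_local(a, b, "nucleotide")$raw_score
    sc <- function(x, y) Biostrings::pairwiseAlignment(
      Biostrings::DNAString(x), Biostrings::DNAString(y), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
    want <- max(sc(a, b), sc(a, revcomp(b)))
    expect_equal(got, as.integer(want), label = sprintf("pair %d", i))
  }
})

test_that("raw score is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:50) {
    a <- rand_aa(sample(10:50, 1))
    b <- rand_aa(sample(10:50, 1))
    expect_equal(align_local(a, b, "protein")$raw_score,
                 align_local(b, a, "protein")$raw_score)
  }
})

test_that("minus-strand coordinates map back to the forward strand", {
  set.seed(55)
  frag <- rand_dna(60)
  tgt <- paste0(rand_dna(100), revcomp(frag), rand_dna(80))
  al <- align_local(frag, tgt, "nucleotide")
  expect_equal(al$strand, "-")
  expect_equal(al$identity, 1.0)
  expect_equal(substr(tgt, al$tgt_start + 1, al$tgt_end), revcomp(frag))
})

test_that("E-value follows the Karlin-Altschul formula", {
  p <- ka_params("protein")
  # S = 0 reduces to m * n * K
  expect_equal(evalue(0, 200, 1e6, "protein"), 200 * 1e6 * p$K)
  # linear in database length
  expect_equal(evalue(80, 200, 2e6, "protein"),
               2 * evalue(80, 200, 1e6, "protein"))
  # frozen regression value, computed directly from the formula
  expect_equal(evalue(100, 200, 1e6, "protein"), 2.080421e-05,
               tolerance = 1e-6)
  # monotone non-increasing in score
  ev <- vapply(seq(0, 300, by = 10), evalue, 1, ref_len = 150,
               db_len = 1e5, mode = "protein")
  expect_true(all(diff(ev) <= 0))
})

test_that("threshold filters are strict inequalities as printed", {
  thr <- default_thresholds()$REP
  expect_false(passes_thresholds(1e-9, identity = 0.50, ref_cover = 0.9, thr))
  expect_true(passes_thresholds(1e-9, identity = 0.501, ref_cover = 0.9, thr))
  expect_false(passes_thresholds(1e-9, identity = 0.9, ref_cover = 0.50, thr))
  expect_false(passes_thresholds(1e-5, identity = 0.9, ref_cover = 0.9, thr))
  expect_true(passes_thresholds(0.99e-5, identity = 0.9, ref_cover = 0.9, thr))
})

test_that("search finds planted references and ignores random proteins", {
  set.seed(91)
  refprot <- rand_aa(200)
  refs <- data.frame(id = "REF_1", category = "PAR", family = "sopB",
                     molecule = "protein", sequence = refprot,
                     cognate_partner = NA, arg_class = NA)
  orfs <- data.frame(
    orf_id = c("p1_1", paste0("p2_", 1:100)),
    plasmid_id = c("p1", rep("p2", 100)),
    protein = c(paste0("M", refprot), replicate(100, rand_aa(300))))
  hits <- search_category(refs, orfs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$plasmid_id, "p1")
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$ref_cover, 1.0)
})

test_that("search results are invariant to input ordering", {
  set.seed(14)
  p1 <- rand_aa(150); p2 <- rand_aa(180)
  refs <- data.frame(id = c("A_1", "B_1"), category = "REP",
                     family = c("IncF", "IncX"), molecule = "protein",
                     sequence = c(p1, p2), cognate_partner = NA,
                     arg_class = NA)
  orfs <- data.frame(orf_id = c("x_1", "y_1"), plasmid_id = c("x", "y"),
                     protein = c(paste0("M", p1), paste0("M", p2)))
  h1 <- search_category(refs, orfs)
  h2 <- search_category(refs[2:1, ], orfs[2:1, ])
  expect_equal(h1, h2)
})

test_that("mixed categories are rejected", {
  refs <- data.frame(id = c("a", "b"), category = c("REP", "PAR"),
                     family = "f", molecule = "protein", sequence = "MKV",
                     cognate_partner = NA, arg_class = NA)
  expect_error(search_category(refs, data.frame(orf_id = "o",
                                                plasmid_id = "p",
                                                protein = "MKV")),
               "mix")
})
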