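test_that("relaxase + T4SS machinery is conjugative", {
  hits <- example_hits_p1_conj()
  call <- call_mobility(hits)
  expect_equal(call$mobility, "conjugative")
  expect_true(call$relaxase_present)
  expect_true(call$t4ss_present)
  expect_equal(call$mob_type, "MOBF")
  expect_equal(call$mpf_type, "MPFF")
})

test_that("oriT without T4SS machinery is mobilizable; no hits is not", {
  expect_equal(call_mobility(make_hit("ORIT", "oriT_F", "p2"))$mobility,
               "mobilizable")
  empty <- make_hit("ORIT", "x", "p")[0, ]
  expect_equal(call_mobility(empty, plasmid_id = "p3")$mobility,
               "non_mobilizable")
})

test_that("the T4SS rule needs an ATPase and three distinct genes", {
  base <- make_hit("RELAXASE", "MOBF", "p1")
  # three genes but no ATPase
  no_atp <- rbind(base,
                  make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traE"),
                  make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traK"),
                  make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traB"))
  expect_false(call_mobility(no_atp)$t4ss_present)
  # ATPase but only two genes
  two <- rbind(base,
               make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traC_ATPase"),
               make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traE"))
  expect_false(call_mobility(two)$t4ss_present)
  # both knobs relaxable
  expect_true(call_mobility(two, t4ss_min_genes = 2)$t4ss_present)
  expect_true(call_mobility(no_atp, require_atpase = FALSE)$t4ss_present)
})

test_that("mobilizable rule modes differ on relaxase-only plasmids", {
  rel_only <- make_hit("RELAXASE", "MOBP", "p9")
  expect_equal(call_mobility(rel_only, mobilizable_rule = "strict_paper")$mobility,
               "non_mobilizable")
  expect_equal(call_mobility(rel_only,
                             mobilizable_rule = "relaxase_or_orit")$mobility,
               "mobilizable")
})

test_that("type assignment follows bitscore and distinct-gene rules", {
  # highest-bitscore relaxase wins
  hits <- rbind(make_hit("RELAXASE", "MOBP", "p1", bitscore = 80),
                make_hit("RELAXASE", "MOBF", "p1", ref_id = "MOBF_1",
                         bitscore = 95))
  expect_equal(assign_types(hits)$mob_type, "MOBF")
  # multi-replicon plasmids keep every Inc type
  reps <- rbind(make_hit("REP", "IncF", "p1"),
                make_hit("REP", "IncX", "p1", ref_id = "RepX_1"))
  expect_equal(assign_types(reps)$inc_types, "IncF,IncX")
  # MPF family with most distinct genes wins
  t4 <- rbind(make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traC_ATPase"),
              make_hit("T4SS", "MPFF", "p1", ref_id = "MPFF_traE"),
              make_hit("T4SS", "MPFT", "p1", ref_id = "MPFT_traC_ATPase",
                       bitscore = 500))
  expect_equal(assign_types(t4)$mpf_type, "MPFF")
})

test_that("the three mobility classes partition any hit combination", {
  set.seed(101)
  cats <- c("RELAXASE", "ORIT", "T4SS")
  for (i in 1:50) {
    pick <- cats[runif(3) < 0.5]
    hits <- make_hit("ORIT", "x", "p")[0, ]
    if ("RELAXASE" %in% pick) hits <- rbind(hits, make_hit("RELAXASE", "MOBF", "p"))
    if ("ORIT" %in% pick) hits <- rbind(hits, make_hit("ORIT", "oriT_F", "p"))
    if ("T4SS" %in% pick)
      hits <- rbind(hits,
                    make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traC_ATPase"),
                    make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traE"),
                    make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traK"))
    call <- call_mobility(hits, plasmid_id = "p")
    expect_true(call$mobility %in% c("conjugative", "mobilizable",
                                     "non_mobilizable"))
    expect_equal(sum(call$mobility == c("conjugative", "mobilizable",
                                        "non_mobilizable")), 1L)
  }
})

test_that("adding T4SS evidence never demotes a plasmid", {
  rank <- c(non_mobilizable = 0, mobilizable = 1, conjugative = 2)
  base <- rbind(make_hit("RELAXASE", "MOBF", "p"),
                make_hit("ORIT", "oriT_F", "p"))
  before <- call_mobility(base)$mobility
  more <- rbind(base,
                make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traC_ATPase"),
                make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traE"),
                make_hit("T4SS", "MPFF", "p", ref_id = "MPFF_traK"))
  after <- call_mobility(more)$mobility
  expect_gte(rank[[after]], rank[[before]])
})

test_that("mobility_table covers plasmids without hits", {
  hits <- example_hits_p1_conj()
  tab <- mobility_table(hits, c("p1", "zzz"))
  expect_equal(tab$mobility, c("conjugative", "non_mobilizable"))
})
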