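test_that("the reference panel is deterministic and self-consistent", {
  p1 <- make_reference_panel(5)
  p2 <- make_reference_panel(5)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_reference_panel(6)))
  # at least two families per category, unique within category
  for (cat in unique(p1$category)) {
    fams <- p1$family[p1$category == cat]
    if (!cat %in% c("ORIT", "RNA_ANTITOXIN"))
      expect_gte(length(unique(fams)), 2)
  }
  ids <- p1$id
  expect_equal(anyDuplicated(ids), 0)
  # round-trips through the FASTA dialect and validation
  dir <- withr::local_tempdir()
  paths <- write_reference_panel(p1, dir)
  back <- load_reference_sets(as.list(paths))
  back <- back[match(paste(p1$category, p1$id),
                     paste(back$category, back$id)), ]
  expect_equal(back$sequence, p1$sequence)
  expect_equal(back$family, p1$family)
  expect_equal(back$cognate_partner, p1$cognate_partner)
  # written twice -> byte-identical files
  dir2 <- withr::local_tempdir()
  paths2 <- write_reference_panel(make_reference_panel(5), dir2)
  expect_identical(unname(tools::md5sum(unlist(paths))),
                   unname(tools::md5sum(unlist(paths2))))
})

test_that("planted divergence translates into alignment identity", {
  set.seed(80)
  prot <- rand_aa(200)
  refs <- data.frame(id = "R_1", category = "MPS", family = "traN",
                     molecule = "protein", sequence = prot,
                     cognate_partner = NA, arg_class = NA)
  # zero divergence: exact recovery through ORF calling + search
  pl <- plant_cassette(rand_dna(4000), prot, divergence = 0)
  orfs <- find_orfs(pl$sequence, id = "p")
  orfs$plasmid_id <- "p"
  hits <- search_category(refs, orfs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  # 20% divergence: identity tracks the substitution count
  idents <- vapply(1:20, function(i) {
    set.seed(80 + i)
    pl <- plant_cassette(rand_dna(4000), prot, divergence = 0.2)
    orfs <- find_orfs(pl$sequence, id = "p")
    orfs$plasmid_id <- "p"
    h <- search_category(refs, orfs,
                         default_thresholds()$RELAXASE)
    expect_equal(nrow(h), 1L)
    h$identity
  }, 1)
  expect_true(all(abs(idents - 0.8) <= 0.05))
  # 60% divergence cannot pass an >80% identity tier
  set.seed(81)
  pl <- plant_cassette(rand_dna(4000), prot, divergence = 0.6)
  orfs <- find_orfs(pl$sequence, id = "p")
  orfs$plasmid_id <- "p"
  expect_equal(nrow(search_category(refs, orfs)), 0L)
})

test_that("cassettes refuse to land on an overfull backbone", {
  set.seed(82)
  expect_error(plant_cassette(rand_dna(100), rand_aa(200), 0),
               "longer than")
})

test_that("simulate_cohort is reproducible and validates its config", {
  cfg <- sim_config(seed = 9, n_plasmids = 8, n_clusters = 1,
                    cluster_copies = 1)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$plasmids, s2$plasmids)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  expect_error(sim_config(class_mix = c(conjugative = 0.5,
                                        mobilizable = 0.3,
                                        non_mobilizable = 0.1)),
               "sum to 1")
  expect_error(sim_config(cassette_divergence = 0.9), "0.6")
  expect_error(sim_config(n_plasmids = 3, n_clusters = 2,
                          cluster_copies = 2), "too small")
})

test_that("truth spans translate back to planted proteins at divergence 0", {
  cfg <- sim_config(seed = 10, n_plasmids = 6, cassette_divergence = 0,
                    n_clusters = 1, cluster_copies = 1)
  sim <- simulate_cohort(cfg)
  for (r in seq_len(nrow(sim$truth))) {
    spans <- strsplit(sim$truth$spans[r], ";")[[1]]
    seqv <- sim$plasmids$sequence[sim$plasmids$id ==
                                    sim$truth$plasmid_id[r]]
    for (sp in spans) {
      parts <- strsplit(sp, ":")[[1]]
      cat <- parts[1]
      coords <- as.integer(strsplit(parts[2], "-")[[1]])
      strand <- parts[3]
      frag <- substr(seqv, coords[1] + 1, coords[2])
      if (cat %in% c("ORIT", "RNA_ANTITOXIN")) {
        if (strand == "-") frag <- revcomp(frag)
        ref <- sim$panel$sequence[sim$panel$category == cat][1]
        expect_equal(frag, ref, label = sp)
      } else {
        if (strand == "-") frag <- revcomp(frag)
        prot <- translate_dna(frag, initiator = TRUE)
        expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
        body <- substr(prot, 1, nchar(prot) - 1)
        expect_false(grepl("*", body, fixed = TRUE))
        # the planted body minus the leading M equals a panel protein
        expect_true(substr(body, 2, nchar(body)) %in%
                      sim$panel$sequence[sim$panel$category == cat],
                    label = sp)
      }
    }
  }
})

test_that("a pure-conjugative cohort at divergence 0 classifies perfectly", {
  cfg <- sim_config(seed = 11, n_plasmids = 5,
                    class_mix = c(conjugative = 1, mobilizable = 0,
                                  non_mobilizable = 0),
                    cassette_divergence = 0, n_clusters = 0,
                    cluster_copies = 0)
  sim <- simulate_cohort(cfg)
  run <- run_characterize(plasbhr_config(ani = FALSE, log_level = "quiet"),
                          plasmids = sim$plasmids, refs_dir = sim$panel)
  expect_true(all(run$mobility$mobility == "conjugative"))
})

test_that("planted ANI clusters are recovered at the 95% threshold", {
  cfg <- sim_config(seed = 12, n_plasmids = 10, n_clusters = 3,
                    cluster_copies = 1,
                    length_meanlog = c(conjugative = log(4000),
                                       mobilizable = log(3000),
                                       non_mobilizable = log(2000)),
                    length_sdlog = c(conjugative = 0.1, mobilizable = 0.1,
                                     non_mobilizable = 0.1))
  sim <- simulate_cohort(cfg)
  ani <- ani_matrix(sim$plasmids)
  cl <- cluster_at_threshold(ani, sim$plasmids$id)
  multi <- unique(cl$cluster_id[cl$cluster_size > 1])
  expect_equal(length(multi), 3L)
  tr <- merge(cl, sim$truth, by = "plasmid_id")
  for (k in 1:3) {
    members <- tr$cluster_id[tr$true_cluster == k]
    expect_equal(length(unique(members)), 1L)
    expect_equal(sum(tr$cluster_id == members[1]), length(members))
  }
})
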