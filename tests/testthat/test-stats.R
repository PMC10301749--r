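test_that("exchangeable groups give H = 0 and p = 1", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$h_statistic, 0)
  expect_equal(r$kw_p, 1)
})

test_that("H and p match the textbook rank formula oracle", {
  set.seed(60)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      round(rnorm(sample(4:12, 1), mean = j * runif(1)), 1))
    names(groups) <- paste0("g", seq_len(k))
    r <- kruskal_wallis(groups)
    expect_equal(r$h_statistic, kw_oracle(groups), tolerance = 1e-10)
    expect_equal(r$kw_p,
                 pchisq(kw_oracle(groups), k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the tie-corrected 9-observation hand example is reproduced", {
  # groups (1,2,2), (2,3,5), (5,5,7): midranks give H = 5.68889 before the
  # tie correction 1 - 48/720, hence H = 6.095238
  groups <- list(a = c(1, 2, 2), b = c(2, 3, 5), c = c(5, 5, 7))
  r <- kruskal_wallis(groups)
  expect_equal(r$h_statistic, 6.095238, tolerance = 1e-6)
})

test_that("permutation p agrees with an independent permutation oracle", {
  groups <- list(a = c(1, 2, 3, 9), b = c(4, 5, 6, 2), c = c(7, 8, 10, 11))
  set.seed(61)
  p_impl <- kruskal_wallis(groups, p_method = "permutation",
                           n_perm = 4000)$kw_p
  set.seed(62)
  p_oracle <- kw_perm_oracle(groups, 4000)
  # both are Monte-Carlo estimates of the same exact p
  se <- sqrt(p_oracle * (1 - p_oracle) / 4000)
  expect_lt(abs(p_impl - p_oracle), 5 * se + 1e-4)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(63)
  groups <- list(a = runif(10), b = runif(12) + 0.3, c = runif(8))
  h0 <- kruskal_wallis(groups)$h_statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$h_statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x)
    x^3 + 5))$h_statistic, h0)
})

test_that("Dunn z and p reproduce the no-ties hand example", {
  # a = 1..4, b = 5..8, c = 9..12: mean ranks 2.5 / 6.5 / 10.5, sigma0^2 =
  # N(N+1)/12 = 13, se = sqrt(13 * 1/2), z_ab = -4/se = -1.5689,
  # z_ac = -8/se = -3.1379
  groups <- list(a = 1:4, b = 5:8, c = 9:12)
  d <- dunn_posthoc(groups)
  expect_equal(nrow(d), 3L)
  se <- sqrt(13 * 0.5)
  expect_equal(d$z[d$group_i == "a" & d$group_j == "b"], -4 / se,
               tolerance = 1e-10)
  expect_equal(d$z[d$group_i == "a" & d$group_j == "c"], -8 / se,
               tolerance = 1e-10)
  expect_equal(d$p_adjusted,
               pmin(1, 3 * 2 * pnorm(-abs(d$z))), tolerance = 1e-10)
})

test_that("identical groups give z = 0 and adjusted p = 1", {
  d <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d$z, 0)
  expect_equal(d$p_adjusted, 1)
})

test_that("a far-shifted group owns the smallest adjusted p-values", {
  set.seed(64)
  groups <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 50)
  d <- dunn_posthoc(groups)
  involved <- d$group_i == "c" | d$group_j == "c"
  expect_lt(max(d$p_adjusted[involved]), min(d$p_adjusted[!involved]))
})

test_that("adjusted p-values are never below unadjusted; Holm <= Bonferroni", {
  set.seed(65)
  groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  bon <- dunn_posthoc(groups, "bonferroni")
  expect_true(all(bon$p_adjusted >= bon$p_unadjusted - 1e-12))
  holm <- dunn_posthoc(groups, "holm")
  expect_true(all(holm$p_adjusted <= bon$p_adjusted + 1e-12))
})

test_that("group validation rejects degenerate input", {
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))),
               "observation")
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))), "observation")
})

test_that("summarize_cohort reports the carriers-mobile fraction to 1 dp", {
  # 77 carriers of one gene, 68 conjugative or mobilizable -> 88.3%
  n <- 90
  ids <- sprintf("p%02d", seq_len(n))
  mob <- c(rep("conjugative", 40), rep("mobilizable", 28),
           rep("non_mobilizable", 22))
  # 40 conjugative + 28 mobilizable carriers = 68 mobile; 9 non-mobilizable
  carries <- rep(FALSE, n)
  carries[1:40] <- TRUE                  # conjugative carriers
  carries[41:68] <- TRUE                 # mobilizable carriers (28) -> 68
  carries[69:77] <- TRUE                 # non-mobilizable carriers (9)
  calls <- data.frame(plasmid_id = ids, mobility = mob,
                      relaxase_present = FALSE, t4ss_present = FALSE,
                      orit_present = FALSE, mob_type = NA, mpf_type = NA,
                      inc_types = "")
  profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    hits <- if (carries[i])
      make_hit("ARG", "TEM-1", ids[i], arg_class = "beta_lactam") else
        make_hit("ARG", "x", ids[i])[0, ]
    build_profile(ids[i], hits)
  }))
  set.seed(66)
  plasmids <- plasmid_records(data.frame(
    id = ids, sequence = replicate(n, rand_dna(1200))))
  s <- summarize_cohort(profiles, calls, plasmids)
  row <- s$arg_table[s$arg_table$arg == "TEM-1", ]
  expect_equal(row$n_plasmids, 77L)
  expect_equal(row$n_mobile, 68L)
  expect_equal(row$pct_mobile, 88.3)
  expect_equal(s$arg_class_table$n_plasmids[
    s$arg_class_table$arg_class == "beta_lactam"], 77L)
})

test_that("single-class cohorts skip comparisons with a notice", {
  ids <- c("a", "b", "c")
  calls <- data.frame(plasmid_id = ids, mobility = "conjugative",
                      relaxase_present = TRUE, t4ss_present = TRUE,
                      orit_present = TRUE, mob_type = "MOBF",
                      mpf_type = "MPFF", inc_types = "IncF")
  profiles <- do.call(rbind, lapply(ids, function(i)
    build_profile(i, make_hit("ARG", "x", i)[0, ])))
  set.seed(67)
  plasmids <- plasmid_records(data.frame(
    id = ids, sequence = replicate(3, rand_dna(1500))))
  s <- summarize_cohort(profiles, calls, plasmids)
  expect_null(s$tests$length)
  expect_true(any(grepl("skipped", s$notices)))
})

test_that("planted class separation is detected by the KW + Dunn pipeline", {
  set.seed(68)
  n <- 12
  ids <- sprintf("p%02d", 1:(3 * n))
  mob <- rep(c("conjugative", "mobilizable", "non_mobilizable"), each = n)
  len <- c(round(rlnorm(n, log(40000), 0.2)), round(rlnorm(n, log(8000), 0.2)),
           round(rlnorm(n, log(2000), 0.2)))
  calls <- data.frame(plasmid_id = ids, mobility = mob,
                      relaxase_present = FALSE, t4ss_present = FALSE,
                      orit_present = FALSE, mob_type = NA, mpf_type = NA,
                      inc_types = "")
  profiles <- do.call(rbind, lapply(ids, function(i)
    build_profile(i, make_hit("ARG", "x", i)[0, ])))
  plasmids <- data.frame(id = ids, sequence = NA, length = len,
                         gc_content = runif(3 * n, 0.4, 0.6),
                         topology = "linear", source_isolate = NA)
  s <- summarize_cohort(profiles, calls, plasmids)
  expect_lt(s$tests$length$kw$kw_p, 0.05)
  d <- s$tests$length$dunn
  cm <- d[d$group_i == "conjugative" & d$group_j == "non_mobilizable", ]
  expect_lt(cm$p_adjusted, 0.05)
})
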