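test_that("pooled t statistic matches hand-derived and oracle values", {
  # hand-derived: pooled var 250/3, SE 25/3, t = 65/(25/3) = 7.8, df 3
  res <- kp_t_test(c(90, 80), c(20, 30, 10))
  expect_equal(res$t, 7.8, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-7.8, 3), tolerance = 1e-12)
  expect_lt(abs(res$p - 0.0044), 5e-4)

  # equal constant groups carry no signal
  res0 <- kp_t_test(c(50, 50), c(50, 50, 50))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_true(res0$defined)

  # degenerate groups are undefined, never an error
  expect_false(kp_t_test(90, c(10, 20))$defined)
  expect_false(kp_t_test(numeric(), c(10, 20))$defined)
  expect_false(kp_t_test(c(50, 50), c(60, 60))$defined)  # 0 var, means differ
  expect_error(kp_t_test(c(1, Inf), c(1, 2)), "finite")
})

test_that("pooled and Welch t match stats::t.test across random groups", {
  set.seed(101)
  for (i in 1:300) {
    x <- runif(sample(2:8, 1), 0, 100)
    y <- runif(sample(2:8, 1), 0, 100)
    mine <- kp_t_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
    minew <- kp_t_test(x, y, var_equal = FALSE)
    refw <- t.test(x, y)
    expect_equal(minew$t, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(minew$p, refw$p.value, tolerance = 1e-9)
    # one-sided p is the observed-direction tail: half the two-sided p
    expect_equal(kp_t_test(x, y, alternative = "one.sided")$p, mine$p / 2,
                 tolerance = 1e-12)
  }
})

test_that("t is invariant under positive affine weight maps and flips under negation", {
  set.seed(7)
  x <- runif(6, 0, 100); y <- runif(9, 0, 100)
  base <- kp_t_test(x, y)
  aff <- kp_t_test(2.5 * x + 7, 2.5 * y + 7)
  expect_equal(aff$t, base$t, tolerance = 1e-12)
  expect_equal(aff$p, base$p, tolerance = 1e-12)
  neg <- kp_t_test(-x, -y)
  expect_equal(neg$t, -base$t, tolerance = 1e-12)
  expect_equal(neg$p, base$p, tolerance = 1e-12)
})

test_that("partition_by_feature splits weights by the queried nucleotide", {
  gs <- toy_guide_set(c("ACGTACGTACGTACGTACGTAGG",
                        "TCGTACGTACGTACGTACGTCGG"), c(90, 10))
  pr <- partition_by_feature(gs, 1, "A")
  expect_equal(pr$weights_in, 90)
  expect_equal(pr$weights_out, 10)
  # all guides carry G at PAM positions 22-23
  pr <- partition_by_feature(gs, 22, "G")
  expect_length(pr$weights_out, 0)
  expect_length(pr$weights_in, 2)
  expect_error(partition_by_feature(gs, 24, "A"), "1\\.\\.23")

  # partition completeness at every position <= 21
  gs <- random_guide_set(51, runif(51, 0, 100), seed = 5)
  for (pos in c(1, 9, 21)) {
    sizes <- vapply(c("A", "C", "G", "T"), function(nt)
      length(partition_by_feature(gs, pos, nt)$weights_in), 1L)
    expect_equal(sum(sizes), 51L)
  }
})

test_that("the fitted feature table has the 4 x 23 layout with undefined PAM GG cells", {
  gs <- random_guide_set(30, runif(30, 0, 100), seed = 2,
                         condition_label = "toy")
  fit <- crisprkp(gs)
  f <- fit$features
  expect_equal(nrow(f), 92L)
  expect_equal(nrow(unique(f[, c("position", "nucleotide")])), 92L)
  expect_equal(f$n_in + f$n_out, rep(30L, 92))
  # fixed GG: G cells have empty out-group, A/C/T cells empty in-group
  pam <- f[f$position %in% 22:23, ]
  expect_true(all(pam$direction == "undefined"))
  expect_true(all(pam$signed_score == 0))
  expect_true(all(is.na(pam$t)))
  expect_equal(pam$n_in[pam$nucleotide == "G"], c(30L, 30L))
  expect_equal(pam$n_out[pam$nucleotide != "G"], rep(30L, 6))
  # sign coherence on defined cells
  def <- f[!is.na(f$t) & f$t != 0, ]
  expect_true(all(sign(def$signed_score) == sign(def$t)))
  expect_true(all(def$direction[def$t > 0] == "favored"))
  expect_true(all(def$direction[def$t < 0] == "disfavored"))
  expect_error(crisprkp(toy_guide_set(
    c("ACGTACGTACGTACGTACGTAGG", "TCGTACGTACGTACGTACGTCGG"),
    c(1, 2))), "at least 4")
})

test_that("fits are exactly permutation-invariant and affine-equivariant", {
  gs <- random_guide_set(25, runif(25, 0, 100), seed = 8)
  fit <- crisprkp(gs)
  set.seed(99)
  perm <- sample(25)
  shuffled <- guide_set(gs$name[perm], gs$protospacer[perm], gs$pam[perm],
                        gs$replicates[perm])
  fit2 <- crisprkp(shuffled)
  expect_identical(fit$features$t, fit2$features$t)
  expect_identical(fit$features$p, fit2$features$p)
  expect_identical(fit$features$signed_score, fit2$features$signed_score)

  w <- gs$mean_efficiency
  aff <- crisprkp(gs, weights = 3 * w + 11)
  expect_equal(aff$features$t, fit$features$t, tolerance = 1e-9)
  expect_equal(aff$features$p, fit$features$p, tolerance = 1e-9)
  expect_identical(aff$features$direction, fit$features$direction)
  neg <- crisprkp(gs, weights = -w)
  expect_equal(neg$features$t, -fit$features$t, tolerance = 1e-12)
  expect_equal(neg$features$p, fit$features$p, tolerance = 1e-12)
})

test_that("a null guide set (all equal weights) gives p = 1 everywhere", {
  gs <- random_guide_set(20, rep(50, 20), seed = 4)
  fit <- crisprkp(gs)
  def <- !is.na(fit$features$p)
  expect_true(all(fit$features$p[def] == 1))
  expect_true(all(fit$features$signed_score == 0))
  expect_equal(nrow(top_features(fit, 10)), 0L)  # p < 1 filter empties it
})

test_that("Bonferroni flags follow the per-position 0.05/4 and 0.01/4 thresholds", {
  f <- data.frame(p = c(0.003, 0.0024, 0.013, 0.0125, 0.0025, NA),
                  sig_flag = "none")
  out <- bonferroni_flags(f)
  expect_identical(out$sig_flag,
                   c("p<0.0125", "p<0.0025", "none", "none", "p<0.0125",
                     "none"))
})

test_that("top_features ranks by p with deterministic tie-breaking and clips k", {
  gs <- random_guide_set(40, runif(40, 0, 100), seed = 12)
  fit <- crisprkp(gs)
  tf <- top_features(fit, 5)
  expect_equal(nrow(tf), 5L)
  expect_true(!is.unsorted(tf$p))
  all_def <- top_features(fit, 1e6)  # k beyond the defined-cell count
  expect_lte(nrow(all_def), 92L)
  expect_true(all(all_def$p < 1))
  expect_error(top_features(fit, 0), "positive")
  # ties broken by position then nucleotide
  f <- fit$features
  f$p <- rep(0.5, 92); f$signed_score <- 1; f$t <- 1
  tied <- top_features(f, 3)
  expect_equal(tied$position, c(1L, 1L, 1L))
  expect_equal(tied$nucleotide, c("A", "C", "G"))
})

test_that("a strongly planted effect is the top-ranked feature with matching sign", {
  sim <- simulate_guides(kp_sim_config(
    n_guides = 200, effects = planted_effects(5, "T", 40), noise_sd = 10
  ), seed = 21)
  fit <- crisprkp(sim$guides)
  tf <- top_features(fit, 1)
  expect_equal(tf$position, 5L)
  expect_identical(tf$nucleotide, "T")
  expect_identical(tf$direction, "favored")

  # two opposite-signed planted effects recovered with matching directions
  sim2 <- simulate_guides(kp_sim_config(
    n_guides = 200, effects = planted_effects(c(5, 16), c("T", "C"),
                                              c(40, -40)),
    noise_sd = 10
  ), seed = 22)
  rec <- recovery_assessment(sim2, crisprkp(sim2$guides), k = 2)
  expect_equal(rec$precision_at_k, 1)
  expect_true(rec$all_signs_agree)
})
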