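test_that("correlations match textbook formulas and flag degenerate input", {
  expect_equal(as.numeric(pearson_r(1:10, 2 * (1:10) + 1)), 1)
  expect_equal(as.numeric(pearson_r(1:10, -(1:10))), -1)
  # by the covariance formula: cov = 1, sd_x = sd_y = 1 -> r = 0.5
  expect_equal(as.numeric(pearson_r(c(1, 2, 3), c(1, 3, 2))), 0.5)
  # Spearman via the sum-of-squared-rank-differences formula: 1 - 6*2/60
  expect_equal(as.numeric(spearman_r(1:4, c(1, 2, 4, 3))), 0.8)
  expect_equal(as.numeric(spearman_r(1:5, exp(1:5))), 1)   # monotone map
  expect_equal(as.numeric(spearman_r(1:5, 5:1)), -1)
  expect_warning(r <- pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(r))
  expect_warning(r <- spearman_r(1:3, c(2, 2, 2)), "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")

  # brute-force equivalence on random vectors, including ties for Spearman
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    x <- round(runif(n, 0, 100), 1)
    y <- round(runif(n, 0, 100), 1)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(as.numeric(pearson_r(x, y)), r_brute, tolerance = 1e-12)
    rx <- rank(x); ry <- rank(y)  # mid-ranks
    rs_brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(as.numeric(spearman_r(x, y)), rs_brute, tolerance = 1e-12)
  }
})

test_that("activity-class counts use strict thresholds and ignore order", {
  gs <- random_guide_set(10, rep(50, 10), seed = 42)
  expect_equal(class_counts(gs), list(n_high = 0L, n_low = 0L, n_total = 10L))
  w <- c(80, 76, 75, 74, 25, 24, 10, 50, 100, 0)
  gs <- random_guide_set(10, w, seed = 43)
  cc <- class_counts(gs)
  expect_equal(cc$n_high, sum(w > 75))  # 75 itself is in neither class
  expect_equal(cc$n_low, sum(w < 25))   # 25 itself is in neither class
  expect_equal(cc$n_high + cc$n_low <= cc$n_total, TRUE)
  set.seed(44)
  perm <- sample(10)
  gs2 <- guide_set(gs$name[perm], gs$protospacer[perm], gs$pam[perm],
                   gs$replicates[perm])
  expect_equal(class_counts(gs2)[c("n_high", "n_low")],
               cc[c("n_high", "n_low")])
})

test_that("GC content covers protospacer positions 1-20 only", {
  gs <- toy_guide_set(c("GCGCGCGCGCGCGCGCGCGCAGG",
                        "ATATATATATATATATATATCGG",
                        "GGGGGGGGGGATATATATATTGG"), c(10, 50, 90))
  gc <- gc_association(gs)
  expect_equal(unname(gc$gc_percent), c(100, 0, 50))  # PAM GG excluded
  expect_equal(gc$gc_range, c(0, 100))
  expect_equal(gc$n, 3)
  # r/p agree with cor.test on the same data
  ct <- cor.test(gc$gc_percent, gs$mean_efficiency)
  expect_equal(gc$r, unname(ct$estimate))
  expect_equal(gc$p, ct$p.value)
})

test_that("the strand test reuses the pooled t and flags one-strand sets", {
  targets <- paste0(toy_protospacers(5), "AGG")
  gs <- toy_guide_set(targets, c(90, 80, 20, 30, 10),
                      strand = c("sense", "sense", "antisense", "antisense",
                                 "antisense"))
  st <- strand_test(gs)
  expect_true(st$defined)
  expect_equal(st$t, 7.8, tolerance = 1e-12)    # shared oracle with kp_t_test
  expect_equal(st$p, 2 * pt(-7.8, 3), tolerance = 1e-12)
  # exactly equal constant groups give p = 1
  gs_eq <- toy_guide_set(targets[1:4], c(50, 50, 50, 50),
                         strand = c("sense", "sense", "antisense",
                                    "antisense"))
  expect_equal(strand_test(gs_eq)$p, 1)
  # single-strand set is undefined, not an error
  gs1 <- toy_guide_set(targets, c(90, 80, 20, 30, 10),
                       strand = rep("sense", 5))
  st1 <- strand_test(gs1)
  expect_false(st1$defined)
  expect_true(is.na(st1$p))
})

test_that("design-tool comparison joins by name, drops constant and sparse tools", {
  gs <- random_guide_set(12, seq(5, 93, length.out = 12), seed = 45)
  tools <- data.frame(
    name = gs$name,
    perfect = gs$mean_efficiency,           # identical to measurements
    flat = rep(1, 12),                      # constant: excluded
    noisy = rev(seq_len(12)),
    sparse = c(1, 2, rep(NA, 10))           # < 3 joined guides: excluded
  )
  expect_warning(expect_warning(res <- compare_tools(gs, tools),
                                "constant"), "fewer than 3")
  expect_setequal(res$tool, c("perfect", "noisy"))
  expect_equal(res$r_spearman[res$tool == "perfect"], 1)
  expect_equal(res$r_spearman[res$tool == "noisy"], -1)
  expect_equal(res$n, c(12L, 12L))
  expect_error(compare_tools(gs, data.frame(x = 1)), "name")
})

test_that("the evaluation report bundles the dataset-level analyses coherently", {
  set.seed(46)
  sim <- simulate_guides(kp_sim_config(
    n_guides = 51, effects = planted_effects(c(5, 20), c("T", "C"),
                                             c(25, -20))
  ), seed = 46, condition_label = "variant A")
  # a second condition on the same guides: shared latent + extra noise
  reps2 <- lapply(sim$truth$latent, function(l)
    pmin(pmax(l + rnorm(4, 0, 12), 0), 100))
  gs2 <- guide_set(sim$guides$name, sim$guides$protospacer, sim$guides$pam,
                   reps2, condition_label = "variant B")
  fit <- crisprkp(sim$guides)
  ev <- evaluate_guides(sim$guides, guides2 = gs2, fit = fit,
                        in_sample = TRUE)
  expect_s3_class(ev, "kp_evaluation")
  expect_equal(ev$n, 51)
  expect_equal(ev$mean_efficiency, mean(sim$guides$mean_efficiency))
  # cross-condition agreement equals cor() on the matched means
  expect_equal(ev$cross_condition$r_pearson,
               cor(sim$guides$mean_efficiency, gs2$mean_efficiency))
  expect_gt(ev$cross_condition$r_pearson, 0.5)
  # in-sample kp score correlation is positive with planted effects
  expect_gt(ev$kp$r_spearman, 0)
  expect_true(ev$kp$in_sample)
  expect_output(print(ev), "in-sample")
})
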