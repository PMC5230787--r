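test_that("translational efficiency is the polysomal/free quotient", {
  expect_equal(translational_efficiency(3.0, 1.5), 2.0)
  x <- c(0.1, 1, 17.3)
  expect_equal(translational_efficiency(x, x), rep(1, 3))
  expect_true(is.na(translational_efficiency(1.0, 0.0)))
  expect_true(is.na(translational_efficiency(NA, 2.0)))
  expect_true(is.na(translational_efficiency(-1, 2.0)))
})

test_that("condition summaries compute mean, sd, CV and exclude outliers", {
  s <- summarize_condition(c(2, 2, 2))
  expect_equal(s$mean_te, 2)
  expect_equal(s$sd_te, 0)
  expect_equal(s$cv, 0)
  expect_equal(nrow(s$excluded), 0)

  s <- summarize_condition(c(1.0, 1.1, 0.9, 10.0))
  expect_equal(s$excluded$value, 10.0)
  expect_equal(s$excluded$reason, "outlier")
  expect_equal(s$n_used, 3L)
  expect_equal(s$mean_te, 1.0)
  expect_false(s$high_cv)

  # removal would leave a single value: keep both, flag the high CV
  s <- summarize_condition(c(1.0, 3.0))
  expect_equal(s$n_used, 2L)
  expect_equal(nrow(s$excluded), 0)
  expect_true(s$high_cv)

  # missing replicates are recorded, not zeroed
  s <- summarize_condition(c(a = 2, b = NA, c = 2.2, d = 1.8))
  expect_equal(s$n_used, 3L)
  expect_equal(s$excluded$replicate, "b")
  expect_equal(s$excluded$reason, "missing")

  expect_false(summarize_condition(c(NA, NA))$usable)
})

test_that("outlier rule agrees with the leave-one-out oracle", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    v <- rlnorm(n, 0, 0.4)
    if (runif(1) < 0.5) v[sample(n, 1)] <- v[1] * sample(c(12, 1 / 12), 1)
    s <- summarize_condition(v)
    expect_equal(sort(unname(s$te_values)),
                 sort(oracle_outlier_retained(v)),
                 info = paste(signif(v, 4), collapse = ","))
  }
})

test_that("replicate filter demands usable replicates in both conditions", {
  cfg <- analysis_config()
  mk <- function(n) list(n_used = n)
  expect_true(replicate_filter(mk(3), mk(3), cfg))
  expect_false(replicate_filter(mk(5), mk(2), cfg))
  # filter applies after outlier exclusion: 4 values, one excluded
  s4 <- summarize_condition(c(1.0, 1.1, 0.9, 10.0))
  expect_equal(s4$n_used, 3L)
  expect_true(replicate_filter(s4, mk(3), cfg))
})

test_that("KEV normalization median-centres log2 ratios", {
  gs <- tibble::tibble(gene_id = c("a", "b", "c"),
                       mean_te_untreated = c(2, 5, 0.3),
                       mean_te_treated = c(1, 5, 1.2))
  k <- compute_kevs(gs)
  expect_equal(k$kev, c(0.5, 1, 4))

  same <- tibble::tibble(gene_id = letters[1:4],
                         mean_te_untreated = c(1, 2, 3, 4),
                         mean_te_treated = 3 * c(1, 2, 3, 4))
  expect_equal(compute_kevs(same)$kev, rep(1, 4))

  set.seed(7)
  big <- tibble::tibble(gene_id = as.character(1:501),
                        mean_te_untreated = rlnorm(501),
                        mean_te_treated = rlnorm(501))
  expect_identical(median(compute_kevs(big)$log2_kev), 0)
})

test_that("KEVs are invariant to global rescaling of one condition", {
  sim <- simulate_translatome(simulation_config(n_genes = 80, seed = 21))
  res1 <- kev_analysis(sim$measurements)
  scaled <- sim$measurements
  treated <- scaled$condition == "treated"
  scaled$intensity[treated] <- scaled$intensity[treated] * 37.5
  res2 <- kev_analysis(scaled)
  expect_equal(res2$kev, res1$kev, tolerance = 1e-12)
  expect_equal(res2$class, res1$class)
})

test_that("classification uses inclusive twofold thresholds", {
  expect_equal(classify_kev(c(0.25, 5.21, 1.44)),
               c("sensitive", "resistant", "average"))
  expect_equal(classify_kev(c(0.5, 2.0)), c("sensitive", "resistant"))
  expect_equal(classify_kev(c(0.5000001, 1.9999999)),
               c("average", "average"))
  expect_equal(classify_kev(c(NA, Inf, -1)), rep("excluded", 3))
  # partition is exhaustive and exclusive over positive finite KEVs
  kev <- 2^seq(-4, 4, length.out = 201)
  cls <- classify_kev(kev)
  expect_true(all(cls %in% c("sensitive", "average", "resistant")))
  expect_equal(sum(table(cls)), length(kev))
})

test_that("per-gene test is a two-sided Welch t-test on log2 TEs", {
  x <- c(1.0, 1.3, 0.8)
  expect_equal(kev_test(x, x), 1.0)

  u <- 2^c(0, 0, 0.1)
  t <- 2^c(2, 2, 2.1)
  expect_equal(kev_test(u, t), oracle_welch_p(log2(u), log2(t)),
               tolerance = 1e-12)

  set.seed(33)
  for (i in 1:25) {
    u <- rlnorm(sample(2:6, 1), 0, 0.5)
    t <- rlnorm(sample(2:6, 1), 0.3, 0.8)
    expect_equal(kev_test(u, t), oracle_welch_p(log2(u), log2(t)),
                 tolerance = 1e-12)
  }
  expect_true(is.na(kev_test(c(1, 2), 3)))
  expect_true(is.na(kev_test(c(2, 2), c(2, 2)))) # constant data
})

test_that("KEV histogram bins conserve counts and symmetry", {
  h <- kev_distribution(0) # single gene at KEV 1
  expect_equal(nrow(h), 1)
  expect_equal(h$count, 1L)
  expect_true(h$bin_left <= 0 && 0 < h$bin_right)

  set.seed(4)
  x <- rnorm(2000, 0, 0.8)
  sym <- c(x, -x)
  h <- kev_distribution(sym)
  expect_equal(sum(h$count), length(sym))
  mirrored <- h[order(-h$bin_mid), ]
  expect_equal(h$count, mirrored$count)
  expect_equal(h$bin_mid, -mirrored$bin_mid)
})

test_that("kev_analysis gives every input gene exactly one disposition", {
  sim <- simulate_translatome(simulation_config(n_genes = 150,
                                                missing_prob = 0.3,
                                                seed = 17))
  res <- kev_analysis(sim$measurements)
  expect_equal(sort(res$gene_id), sort(unique(sim$measurements$gene_id)))
  expect_false(any(duplicated(res$gene_id)))
  expect_true(all(res$disposition %in%
                    c("sensitive", "average", "resistant",
                      "insufficient_replicates")))
  passing <- res[res$pass, ]
  expect_lt(abs(median(passing$log2_kev)), 1e-12)
  expect_equal(sum(table(passing$class)), nrow(passing))
})

test_that("log2 KEV error shrinks as measurement noise shrinks", {
  rmse <- sapply(c(0.4, 0.2, 0.1, 0), function(cv) {
    sim <- simulate_translatome(simulation_config(
      n_genes = 300, noise_cv = cv, missing_prob = 0, outlier_prob = 0,
      seed = 99))
    res <- kev_analysis(sim$measurements)
    m <- merge(res, sim$truth, by = "gene_id")
    sqrt(mean((m$log2_kev - m$true_log2_kev)^2))
  })
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[4], 1e-9)
})
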