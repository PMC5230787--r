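test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 40, seed = 11)
  a <- simulate_translatome(cfg)
  b <- simulate_translatome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_start_regions(cfg), simulate_start_regions(cfg))
  cls <- a$truth$class
  expect_identical(simulate_annotation(cfg, cls),
                   simulate_annotation(cfg, cls))
  c2 <- simulate_translatome(simulation_config(n_genes = 40, seed = 12))
  expect_false(identical(a$measurements$intensity,
                         c2$measurements$intensity))
})

test_that("noiseless null yields KEV exactly 1 for every gene", {
  cfg <- simulation_config(n_genes = 60, noise_cv = 0, missing_prob = 0,
                           outlier_prob = 0, frac_sensitive = 0,
                           frac_resistant = 0, log2_kev_sd = 0, seed = 2)
  sim <- simulate_translatome(cfg)
  res <- kev_analysis(sim$measurements)
  expect_true(all(res$pass))
  expect_equal(res$kev, rep(1, 60))
})

test_that("planted sensitive genes are recovered perfectly without noise", {
  cfg <- simulation_config(n_genes = 1000, frac_sensitive = 0.05,
                           frac_resistant = 0, effect_log2 = 2,
                           noise_cv = 0, missing_prob = 0, outlier_prob = 0,
                           seed = 42)
  sim <- simulate_translatome(cfg)
  res <- kev_analysis(sim$measurements)
  m <- merge(res, sim$truth, by = "gene_id")
  # exact recovery of the true (median-centred) log2 KEVs
  expect_lt(max(abs(m$log2_kev - m$true_log2_kev)), 1e-9)
  truly_sensitive <- m$gene_id[m$class.y == "sensitive"]
  called_sensitive <- m$gene_id[m$class.x == "sensitive"]
  recall <- mean(truly_sensitive %in% called_sensitive)
  expect_equal(recall, 1.0)
  expect_setequal(called_sensitive, truly_sensitive)
})

test_that("genes dropped below the replicate floor are kept with a reason", {
  cfg <- simulation_config(n_genes = 120, missing_prob = 0.45, seed = 9)
  sim <- simulate_translatome(cfg)
  res <- kev_analysis(sim$measurements)
  expect_setequal(res$gene_id, unique(sim$measurements$gene_id))
  dropped <- res[!res$pass, ]
  expect_gt(nrow(dropped), 0)
  expect_true(all(dropped$disposition == "insufficient_replicates"))
  expect_true(all(is.na(dropped$kev)))
})

test_that("simulated windows reproduce the requested base composition", {
  comp <- c(A = 0.29, C = 0.22, G = 0.23, T = 0.26)
  cfg <- simulation_config(n_genes = 10000, base_composition = comp,
                           sd_plant_prob = 0, seed = 5)
  sr <- simulate_start_regions(cfg)
  chars <- strsplit(paste0(sr$windows$upstream_seq,
                           sr$windows$downstream_seq), "")
  tab <- table(unlist(chars))
  obs <- as.numeric(tab[names(comp)]) / sum(tab)
  expect_true(all(abs(obs - comp) < 0.01))
})

test_that("planted SD sites round-trip through the detector", {
  cfg <- simulation_config(n_genes = 200, sd_plant_prob = 1,
                           sd_plant_mismatches = 0L, seed = 6)
  sr <- simulate_start_regions(cfg)
  calls <- detect_sd_windows(sr$windows)
  expect_true(all(calls$present))
  expect_equal(calls$distance_to_aug, sr$truth$sd_spacer)
  expect_equal(calls$total_matches, rep(8L, 200))

  fixed <- simulation_config(n_genes = 50, sd_plant_prob = 1,
                             sd_plant_mismatches = 0L,
                             sd_spacer_range = c(5, 5), seed = 7)
  calls5 <- detect_sd_windows(simulate_start_regions(fixed)$windows)
  expect_true(all(calls5$present & calls5$distance_to_aug == 5L))
})

test_that("unplanted uniform sequence matches the enumerated site-level false-positive rate", {
  cfg <- simulation_config(n_genes = 10000, sd_plant_prob = 0,
                           base_composition = c(A = .25, C = .25,
                                                G = .25, T = .25),
                           seed = 8)
  sr <- simulate_start_regions(cfg)
  # single pre-located candidate at a fixed distance: exact enumeration
  site <- substr(sr$windows$upstream_seq, 28, 35) # 3' end 5 nt upstream
  pos <- vapply(site, function(s) sd_call_from_site(s, 5)$present,
                logical(1))
  expected <- oracle_site_positive_rate()
  se <- sqrt(expected * (1 - expected) / length(pos))
  expect_lt(abs(mean(pos) - expected), 4 * se)
  # the full scan over 11 candidate offsets can only be more permissive
  scan <- detect_sd_windows(sr$windows)
  expect_gte(mean(scan$present), mean(pos))
  expect_lt(mean(scan$present), 1)
})

test_that("annotation generator plants class-dependent operon structure", {
  classes <- rep(c("sensitive", "resistant"), each = 400)
  cfg <- simulation_config(seed = 10)
  ann <- simulate_annotation(cfg, classes)
  expect_equal(nrow(ann), 800)
  frac <- tapply(ann$operon_position == "distal" & ann$listed_in_annotation,
                 ann$class, sum) /
    tapply(ann$listed_in_annotation, ann$class, sum)
  expect_gt(frac[["resistant"]], frac[["sensitive"]])
  # distal genes share their upstream neighbour's strand
  i <- which(ann$operon_position == "distal" & seq_len(800) > 1)
  expect_true(all(ann$strand[i] == ann$strand[i - 1]))
  # all intergenic distances at 14 fall under the <15 nt flag
  ann14 <- ann
  ann14$intergenic_distance <- 14L
  s <- summarize_group(ann14)
  expect_equal(s$pct_short_intergenic, 100L)
})

test_that("no distal genes means 0% distal in every group summary", {
  classes <- rep(c("sensitive", "resistant"), each = 100)
  cfg <- simulation_config(seed = 3, operon_config = list(
    frac_distal = c(sensitive = 0, average = 0, resistant = 0)))
  ann <- simulate_annotation(cfg, classes)
  s <- summarize_groups(ann)
  expect_equal(s$n_distal, c(0L, 0L))
  expect_equal(s$pct_distal, c(0L, 0L))
})

test_that("average-class true log2 KEVs centre on zero", {
  cfg <- simulation_config(n_genes = 5000, seed = 13)
  truth <- simulate_translatome(cfg)$truth
  avg <- truth$true_log2_kev[truth$planted_class == "average"]
  expect_lt(abs(mean(avg)), 3 * sd(avg) / sqrt(length(avg)) + 0.02)
  expect_equal(median(truth$true_log2_kev), 0)
})
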