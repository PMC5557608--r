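test_that("sampled parameters hit the design medians and spans", {
  cfg <- simulation_config(n_genes = 5000, seed = 19)
  truth <- sample_gene_parameters(cfg)
  expect_equal(median(truth$k_e), 0.0083, tolerance = 0.1)
  expect_equal(median(truth$k_d), 0.0140, tolerance = 0.1)
  span <- function(x) diff(log10(stats::quantile(x, c(0.05, 0.95))))
  expect_equal(unname(span(truth$k_d)), 0.9, tolerance = 0.1 / 0.9)
  expect_equal(unname(span(truth$k_e)), 0.5, tolerance = 0.2)
  # derived transcription rates span about 5 decades like the abundances
  expect_gt(span(truth$k_s), 4)
  expect_lt(span(truth$k_s), 6.5)
})

test_that("sampled truth is internally consistent", {
  cfg <- simulation_config(n_genes = 200, seed = 23)
  truth <- sample_gene_parameters(cfg)
  expect_true(all(truth$k_s > 0))
  expect_equal(truth$k_t, truth$k_d * truth$c0 / truth$w0)
  # quasi-steady state holds row-wise
  resid <- (truth$k_e + truth$k_f_prime) * truth$n0 -
    (truth$k_d + truth$k_f + cfg$ccp$g) * truth$c0
  expect_lt(max(abs(resid / truth$c0)), 1e-9)
  # the inward transfer rate carries the gene-specific pool ratio
  mt <- mitotic_transfer_rates(cfg$ccp, steady_state(truth$n0, truth$c0))
  expect_equal(truth$k_f, mt$k_f, tolerance = 1e-12)
  # zero spread collapses every gene onto the medians
  cfg0 <- simulation_config(n_genes = 20, seed = 23, c0_decades = 0,
                            k_e_decades = 0, k_d_decades = 0,
                            length_sd_log10 = 0)
  t0 <- sample_gene_parameters(cfg0)
  expect_equal(diff(range(t0$k_e)), 0)
  expect_equal(diff(range(t0$k_s)), 0)
})

test_that("generator output is bit-identical per seed", {
  cfg <- simulation_config(n_genes = 50, seed = 29)
  t1 <- sample_gene_parameters(cfg)
  t2 <- sample_gene_parameters(cfg)
  expect_identical(t1, t2)
  e1 <- simulate_experiment(t1, cfg)
  e2 <- simulate_experiment(t2, cfg)
  expect_identical(e1$measurements, e2$measurements)
  expect_identical(e1$bulk, e2$bulk)
  a1 <- generate_feature_annotations(t1, cfg)
  a2 <- generate_feature_annotations(t2, cfg)
  expect_identical(a1, a2)
  # a different seed changes the draw
  t3 <- sample_gene_parameters(simulation_config(n_genes = 50, seed = 30))
  expect_false(identical(t1$k_e, t3$k_e))
})

test_that("noise-free, escape-free output equals the analytic curves", {
  cfg <- simulation_config(n_genes = 15, seed = 31, noise_cv = 0, u = 0,
                           pr = 1)  # pr = 1: every transcript captured
  truth <- sample_gene_parameters(cfg)
  ex <- simulate_experiment(truth, cfg)
  expect_equal(ex$measurements$fpkm_spikenorm,
               ex$measurements$true_unlabeled, tolerance = 1e-12)
  one <- dplyr::filter(ex$measurements, gene_id == truth$gene_id[3],
                       fraction == "nuclear", replicate == 1)
  i <- 3
  ss <- steady_state(truth$n0[i], truth$c0[i])
  rates <- kinetic_rates(truth$k_s[i], truth$k_e[i], truth$k_d[i],
                         truth$k_t[i], truth$k_f[i], truth$k_f_prime[i])
  expect_equal(one$fpkm_spikenorm,
               unlabeled_nuclear(one$time_min, ss, rates),
               tolerance = 1e-12)
  # raw fpkm put through spike normalization reproduces the true scale
  renorm <- spike_normalize(
    dplyr::select(ex$measurements, -"fpkm_spikenorm", -"true_unlabeled"),
    ex$mapped_reads)
  j <- dplyr::inner_join(
    dplyr::select(renorm, gene_id, fraction, replicate, time_min,
                  renormed = fpkm_spikenorm),
    dplyr::select(ex$measurements, gene_id, fraction, replicate, time_min,
                  original = fpkm_spikenorm),
    by = c("gene_id", "fraction", "replicate", "time_min"))
  expect_equal(j$renormed, j$original, tolerance = 1e-12)
})

test_that("replicate scatter matches the configured CV", {
  cfg <- simulation_config(n_genes = 2000, seed = 37, noise_cv = 0.2,
                           n_replicates = 2)
  truth <- sample_gene_parameters(cfg)
  ex <- simulate_experiment(truth, cfg)
  cv_hat <- ex$measurements |>
    dplyr::summarise(m = mean(fpkm_spikenorm),
                     cv = stats::sd(fpkm_spikenorm) / mean(fpkm_spikenorm),
                     .by = c(gene_id, fraction, time_min)) |>
    dplyr::filter(m > 0)
  # mean replicate CV (c4-corrected for n = 2) approximates the truth
  expect_equal(mean(cv_hat$cv) / sqrt(2 / pi), 0.2, tolerance = 0.05)
})

test_that("down-sampling is a seeded binomial thinning", {
  counts <- c(0, 4, 10, 1000, 50000)
  expect_identical(downsample_reads(counts, 1, seed = 5),
                   as.integer(counts))
  d1 <- downsample_reads(counts, 0.25, seed = 5)
  d2 <- downsample_reads(counts, 0.25, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1 <= counts))
  # moments: expected total is fraction * total within 3 binomial SDs
  set.seed(41)
  big <- rpois(20000, 30)
  thin <- downsample_reads(big, 0.25, seed = 6)
  expect_lt(abs(sum(thin) - 0.25 * sum(big)),
            3 * sqrt(sum(big) * 0.25 * 0.75))
  # a count of 4 keeps mean 1 at fraction 1/4
  many <- downsample_reads(rep(4L, 20000), 0.25, seed = 7)
  expect_true(all(many %in% 0:4))
  expect_equal(mean(many), 1, tolerance = 0.05)
  expect_error(downsample_reads(c(1.5, 2), 0.5), "round")
})

test_that("count emission and back-conversion are consistent", {
  cfg <- simulation_config(n_genes = 300, seed = 43)
  truth <- sample_gene_parameters(cfg)
  ex <- simulate_experiment(truth, cfg)
  cnt <- simulate_counts(ex$measurements, size_factor = 50, seed = 9)
  expect_true(all(cnt$count >= 0))
  back <- counts_to_abundance(cnt$count, size_factor = 50)
  keep <- cnt$fpkm > 1
  expect_equal(mean(back[keep] / cnt$fpkm[keep]), 1, tolerance = 0.05)
})

test_that("annotations carry planted effects and stay null otherwise", {
  cfg <- simulation_config(n_genes = 800, seed = 47,
                           planted_rbp = list(n = 100, fold = 2))
  truth <- sample_gene_parameters(cfg)
  ann <- generate_feature_annotations(truth, cfg)
  expect_setequal(names(ann), c("features", "labels", "states"))
  expect_equal(sum(truth$rbp_bound), 100)
  planted <- dplyr::filter(ann$labels, label == "RBP_planted")
  expect_equal(planted$bound, truth$rbp_bound)
  expect_equal(median(truth$k_d[truth$rbp_bound]) /
                 median(truth$k_d[!truth$rbp_bound]), 2, tolerance = 0.35)
  # without planting, association statistics come out null
  cfg0 <- simulation_config(n_genes = 800, seed = 48)
  truth0 <- sample_gene_parameters(cfg0)
  ann0 <- generate_feature_annotations(truth0, cfg0)
  res <- group_rate_comparison(truth0, ann0$labels)
  expect_false(any(res$significant))
  corr <- rate_feature_correlation(truth0,
                                   dplyr::select(ann0$features, gene_id,
                                                 intron_length))
  expect_lt(max(abs(corr$rho)), 0.1)
})
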