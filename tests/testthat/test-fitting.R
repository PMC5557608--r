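test_that("objective is zero at the generating parameters", {
  set.seed(11)
  for (i in 1:20) {
    gene <- make_consistent_gene(k_e = 10^runif(1, -2.6, -1.6),
                                 k_d = 10^runif(1, -2.6, -1.6),
                                 c0 = 10^runif(1, 0.5, 2.5))
    ser <- make_noisefree_series(gene)
    obj <- objective_components(
      list(k_e = gene$rates$k_e, k_d = gene$rates$k_d,
           k_t = gene$rates$k_t), ser, gene$ccp)
    expect_lt(sum(obj$theta), 1e-12)
  }
})

test_that("steady-state component vanishes on its algebraic manifold", {
  gene <- make_consistent_gene()
  ser <- make_noisefree_series(gene)
  ccp <- gene$ccp
  mt <- mitotic_transfer_rates(ccp, gene$ss)
  # pick k_d freely and set k_e to satisfy (kE+kf') N0 = (kD+kf+g) C0
  k_d <- 0.03
  k_e <- (k_d + mt$k_f + ccp$g) * gene$ss$c0 / gene$ss$n0 - mt$k_f_prime
  obj <- objective_components(list(k_e = k_e, k_d = k_d, k_t = 0.005),
                              ser, ccp)
  expect_equal(obj$theta[["steady_state"]], 0, tolerance = 1e-20)
  # turnover component vanishes when kT W0 = kD C0
  k_t <- k_d * gene$ss$c0 / gene$ss$w0
  obj2 <- objective_components(list(k_e = 0.01, k_d = k_d, k_t = k_t),
                               ser, ccp)
  expect_equal(obj2$theta[["turnover"]], 0, tolerance = 1e-20)
})

test_that("objective components match scalar hand evaluation", {
  ccp <- cell_cycle_params()
  gene <- make_consistent_gene(k_e = 0.008, k_d = 0.015, c0 = 40)
  ser <- make_noisefree_series(gene)
  trial <- list(k_e = 0.01, k_d = 0.02, k_t = 0.006)
  cv <- 0.25
  obj <- objective_components(trial, ser, ccp, constant_noise_model(cv))
  # hand-stacked arithmetic with plain exp/log scalars
  ss <- steady_state(ser$nuclear[1], ser$cytoplasmic[1])
  mt <- mitotic_transfer_rates(ccp, ss)
  rates <- kinetic_rates(0, trial$k_e, trial$k_d, trial$k_t, mt$k_f,
                         mt$k_f_prime)
  np <- unlabeled_nuclear(ser$time_min, ss, rates)
  cp <- unlabeled_cytoplasmic(ser$time_min, ss, rates)
  expect_equal(obj$theta[["nuclear"]],
               mean((cv * log(ser$nuclear / np))^2), tolerance = 1e-12)
  expect_equal(obj$theta[["cytoplasmic"]],
               mean((cv * log(ser$cytoplasmic / cp))^2), tolerance = 1e-12)
  expect_equal(obj$theta[["steady_state"]],
               log((trial$k_e + mt$k_f_prime) * ss$n0 /
                     ((trial$k_d + mt$k_f + ccp$g) * ss$c0))^2,
               tolerance = 1e-12)
  expect_equal(obj$theta[["turnover"]],
               log(trial$k_t * ss$w0 / (trial$k_d * ss$c0))^2,
               tolerance = 1e-12)
  expect_equal(sum(obj$residuals^2), sum(obj$theta), tolerance = 1e-12)
})

test_that("noise-free series are recovered to high relative accuracy", {
  gene <- make_consistent_gene(k_e = 0.0083, k_d = 0.0140, c0 = 60)
  fit <- fit_gene(make_noisefree_series(gene), gene$ccp, gene_id = "g1")
  expect_true(fit$converged)
  expect_true(fit$retained)
  expect_equal(fit$rates$k_e, 0.0083, tolerance = 1e-4)
  expect_equal(fit$rates$k_d, 0.0140, tolerance = 1e-4)
  expect_equal(fit$rates$k_t, gene$rates$k_t, tolerance = 1e-4)
  expect_equal(fit$rates$k_s, gene$rates$k_s, tolerance = 1e-4)
  expect_equal(fit$r2_nuclear, 1, tolerance = 1e-8)
  expect_equal(fit$r2_cytoplasmic, 1, tolerance = 1e-8)
  expect_lt(sum(fit$theta), 1e-12)
})

test_that("degenerate series take the failure path, not an error", {
  ser <- make_noisefree_series()
  ser$cytoplasmic <- 0
  fit <- fit_gene(ser, default_ccp, gene_id = "dead")
  expect_false(fit$converged)
  expect_false(fit$retained)
  expect_match(fit$message, "zero steady-state")
  ser2 <- make_noisefree_series()
  ser2$nuclear[3:6] <- 0
  fit2 <- fit_gene(ser2, default_ccp)
  expect_false(fit2$converged)
  expect_match(fit2$message, "zero")
  expect_equal(nrow(tidy(fit)), 0)
  expect_false(glance(fit)$converged)
})

test_that("r-squared matches its defining arithmetic", {
  gene <- make_consistent_gene()
  ser <- make_noisefree_series(gene)
  # perfect prediction
  r2 <- goodness_of_fit(ser, gene$ss, gene$rates)
  expect_equal(unname(r2), c(1, 1))
  # hand-computed 6-point example on log10 scale
  set.seed(3)
  noisy <- dplyr::mutate(ser,
                         nuclear = nuclear * exp(rnorm(6, 0, 0.2)),
                         cytoplasmic = cytoplasmic * exp(rnorm(6, 0, 0.2)))
  r2n <- goodness_of_fit(noisy, gene$ss, gene$rates)
  obs <- log10(noisy$nuclear)
  pred <- log10(unlabeled_nuclear(noisy$time_min, gene$ss, gene$rates))
  expect_equal(r2n[["r2_nuclear"]],
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  # predicting the per-series mean gives r2 = 0: construct data whose
  # fitted curve happens to equal the mean of the observations
  flat <- tibble::tibble(time_min = c(0, 100), nuclear = c(2, 2),
                         cytoplasmic = c(4, 4))
  expect_true(is.na(goodness_of_fit(
    flat, steady_state(2, 4),
    kinetic_rates(0, 0.01, 0.01, 0.005))[["r2_nuclear"]]))
})

test_that("retention requires both fractions in every replicate", {
  res <- tibble::tibble(
    gene_id = c("a", "a", "b", "b", "c", "c"),
    replicate = c(1, 2, 1, 2, 1, 2),
    r2_nuclear = c(0.95, 0.99, 0.95, 0.79, 0.9, NA),
    r2_cytoplasmic = c(0.92, 0.9, 0.9, 0.9, 0.85, 0.99))
  expect_equal(filter_retained(res), "a")
  expect_setequal(filter_retained(res, rule = "any"), c("a", "b", "c"))
  # boundary: r2 exactly at the threshold is not retained
  res2 <- tibble::tibble(gene_id = "d", replicate = 1, r2_nuclear = 0.8,
                         r2_cytoplasmic = 0.95)
  expect_length(filter_retained(res2), 0)
})

test_that("fit_dataset is deterministic and concordant on identical replicates", {
  set.seed(21)
  genes <- lapply(1:8, function(i) {
    make_consistent_gene(k_e = 10^runif(1, -2.4, -1.8),
                         k_d = 10^runif(1, -2.4, -1.6),
                         c0 = 10^runif(1, 1, 2.5))
  })
  data <- dplyr::bind_rows(lapply(seq_along(genes), function(i) {
    make_measurements(genes[[i]], cv = 0, gene_id = paste0("g", i))
  }))
  fits <- fit_dataset(data, default_ccp)
  expect_true(all(fits$rates$converged))
  expect_equal(length(fits$retained), 8)
  expect_true(all(fits$concordance$rho == 1))
  # identical inputs give bit-identical outputs
  fits2 <- fit_dataset(data, default_ccp)
  expect_identical(fits$rates, fits2$rates)
  # rate_table collapses replicates by geometric mean
  rt <- rate_table(fits)
  expect_equal(nrow(rt), 8)
  expect_equal(rt$k_d[rt$gene_id == "g3"],
               exp(mean(log(fits$rates$k_d[fits$rates$gene_id == "g3"]))))
})

test_that("simulator round trip recovers truth through the full preprocessing", {
  # noise off, carry-over and escape on: correction + fitting must invert
  cfg <- simulation_config(n_genes = 12, seed = 31, noise_cv = 0)
  truth <- sample_gene_parameters(cfg)
  ex <- simulate_experiment(truth, cfg)
  cap <- tibble::tibble(gene_id = truth$gene_id, f = truth$f)
  step1 <- correct_labeling_bias(ex$measurements, cap, cfg$ccp$g)$corrected
  step2 <- correct_labeling_bias(
    step1, tibble::tibble(gene_id = truth$gene_id, f = 1 - cfg$u),
    cfg$ccp$g)$corrected
  fits <- fit_dataset(step2, cfg$ccp)
  j <- dplyr::inner_join(dplyr::filter(fits$rates, replicate == 1), truth,
                         by = "gene_id", suffix = c("_est", "_true"))
  expect_equal(j$k_e_est, j$k_e_true, tolerance = 1e-4)
  expect_equal(j$k_d_est, j$k_d_true, tolerance = 1e-4)
  expect_equal(j$k_s_est, j$k_s_true, tolerance = 1e-4)
})
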