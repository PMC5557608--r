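test_that("variance shares sum to one and isolate the varying process", {
  g <- log(2) / 1440
  rt <- make_rate_table(500, sd_s = 1, sd_e = 0, sd_d = 0, seed = 2)
  vs <- variance_contributions(rt, g)
  expect_equal(sum(vs$share), 1, tolerance = 1e-12)
  expect_equal(vs$share[vs$component == "transcription"], 1,
               tolerance = 1e-12)
  expect_equal(vs$share[vs$component == "decay"], 0, tolerance = 1e-12)
  # shares are invariant to a global rescaling of transcription
  rt2 <- dplyr::mutate(make_rate_table(500, seed = 3), k_s = k_s * 7)
  expect_equal(variance_contributions(rt2, g)$share,
               variance_contributions(make_rate_table(500, seed = 3),
                                      g)$share,
               tolerance = 1e-12)
  expect_error(variance_contributions(rt[1:5, ], g), "10")
})

test_that("planted generative variance shares are recovered", {
  g <- log(2) / 1440
  # plant the three decomposition terms directly as independent normals
  # with variances in ratio 0.85 / 0.05 / 0.10, then invert to rates:
  # term_e = log(kE/(kE+g)) -> kE = g e^t / (1 - e^t);
  # term_d = -log(kD+g)     -> kD = e^(-t) - g.
  set.seed(4)
  n <- 5000
  total_var <- 1.5
  term_s <- rnorm(n, log(5), sqrt(0.85 * total_var))
  mu_e <- log(0.0083 / (0.0083 + g))
  term_e <- pmin(rnorm(n, mu_e, sqrt(0.05 * total_var)), -1e-9)
  term_d <- rnorm(n, -log(0.014 + g), sqrt(0.10 * total_var))
  rt <- tibble::tibble(
    gene_id = paste0("g", 1:n),
    k_s = exp(term_s),
    k_e = g * exp(term_e) / (1 - exp(term_e)),
    k_d = pmax(exp(-term_d) - g, 1e-8))
  vs <- variance_contributions(rt, g)
  expect_lt(abs(vs$share[vs$component == "transcription"] - 0.85), 0.05)
  expect_lt(abs(vs$share[vs$component == "export"] - 0.05), 0.05)
  expect_lt(abs(vs$share[vs$component == "decay"] - 0.10), 0.05)
  expect_equal(sum(vs$share), 1, tolerance = 1e-12)
})

test_that("rate-feature correlations behave at the three planted regimes", {
  rt <- make_rate_table(3000, seed = 5)
  # a feature equal to the rate correlates perfectly
  f1 <- tibble::tibble(gene_id = rt$gene_id, same = rt$k_d)
  res1 <- rate_feature_correlation(rt, f1, rate_cols = "k_d")
  expect_equal(res1$rho, 1)
  # an independent feature is near zero at n = 3000
  set.seed(6)
  f2 <- tibble::tibble(gene_id = rt$gene_id,
                       noise = exp(rnorm(3000)))
  res2 <- rate_feature_correlation(rt, f2, rate_cols = "k_d")
  expect_lt(abs(res2$rho), 0.05)
  # constant feature yields a reason-coded missing cell
  f3 <- tibble::tibble(gene_id = rt$gene_id, flat = 1)
  res3 <- rate_feature_correlation(rt, f3, rate_cols = "k_s")
  expect_true(is.na(res3$rho))
  expect_match(res3$note, "constant")
})

test_that("a planted sub-linear length dependence is measured as its slope", {
  cfg <- simulation_config(n_genes = 4000, seed = 9,
                           planted_length_effect = TRUE)
  truth <- sample_gene_parameters(cfg)
  features <- tibble::tibble(gene_id = truth$gene_id,
                             transcript_length = truth$transcript_length)
  res <- rate_feature_correlation(truth, features, rate_cols = "k_d")
  expect_equal(res$log_log_slope, 0.25, tolerance = 0.05 / 0.25)
  expect_gt(res$rho, 0.5)
  expect_lt(res$p_value, 1e-10)
})

test_that("group comparison finds planted shifts and respects Holm", {
  rt <- make_rate_table(3000, seed = 10)
  set.seed(10)
  bound <- sample(rt$gene_id, 300)
  rt$k_d[rt$gene_id %in% bound] <- rt$k_d[rt$gene_id %in% bound] * 2
  labels <- dplyr::bind_rows(
    tibble::tibble(gene_id = rt$gene_id, label = "planted",
                   bound = rt$gene_id %in% bound),
    tibble::tibble(gene_id = rt$gene_id, label = "null",
                   bound = stats::runif(3000) < 0.1))
  res <- group_rate_comparison(rt, labels, rate_cols = "k_d")
  planted <- dplyr::filter(res, label == "planted")
  expect_true(planted$significant)
  expect_equal(planted$log2_ratio, 1, tolerance = 0.25)
  expect_false(dplyr::filter(res, label == "null")$significant)
  # identical groups: ratio 0, p near 1
  labels_same <- tibble::tibble(gene_id = rt$gene_id, label = "same",
                                bound = seq_len(3000) %% 2 == 0)
  rt_flat <- dplyr::mutate(rt, k_d = 1)
  res_same <- group_rate_comparison(rt_flat, labels_same, rate_cols = "k_d")
  expect_equal(res_same$log2_ratio, 0)
  expect_gt(res_same$p_value, 0.9)
})

test_that("Holm step-down matches the textbook procedure", {
  # p = (0.001, 0.02, 0.04), m = 3, alpha = 0.05: thresholds are
  # 0.05/3, 0.05/2, 0.05 and the step-down rejects all three
  # (adjusted p = 0.003, 0.04, 0.04)
  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.04), "holm"),
               c(0.003, 0.04, 0.04))
  # the package adjusts within each rate across label sets the same way
  rt <- make_rate_table(200, seed = 11)
  set.seed(11)
  labels <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(gene_id = rt$gene_id, label = paste0("L", i),
                   bound = stats::runif(200) < 0.2)
  })
  res <- group_rate_comparison(rt, labels, rate_cols = "k_e", alpha = 0.05)
  expect_equal(res$p_adjusted, stats::p.adjust(res$p_value, "holm"))
})

test_that("set overlap is the intersection over each set size", {
  expect_equal(rbp_overlap(letters[1:4], letters[1:4]),
               list(overlap_xy = 1, overlap_yx = 1))
  x <- paste0("g", 1:100)
  y <- paste0("g", 76:125)
  expect_equal(rbp_overlap(x, y), list(overlap_xy = 0.25, overlap_yx = 0.5))
  expect_equal(rbp_overlap(c("a", "b"), c("c", "d")),
               list(overlap_xy = 0, overlap_yx = 0))
  expect_error(rbp_overlap(character(), "a"), "non-empty")
})

test_that("pausing index is the TSS-window to gene-body signal ratio", {
  expect_equal(pausing_index(5, 5), 1)
  expect_equal(pausing_index(10, 5), 2)
  expect_true(is.na(pausing_index(3, 0)))
  # uniform coverage track: ratio equals the width ratio of the regions
  gene_length <- 10000
  window <- 400      # 200 bp around the TSS on both sides
  coverage <- 2.5    # uniform
  expect_equal(pausing_index(coverage * window,
                             coverage * (gene_length - 200)),
               window / (gene_length - 200))
})

test_that("chromatin-state comparison flags only real differences", {
  set.seed(12)
  n_per <- 200
  states <- tibble::tibble(
    gene_id = paste0("g", 1:(3 * n_per)),
    state = rep(c("YELLOW", "BLUE", "BLACK"), each = n_per))
  # identical distributions: no significant pairs
  rt0 <- tibble::tibble(gene_id = states$gene_id,
                        k_s = exp(rnorm(3 * n_per, 0, 0.5)))
  cmp0 <- chromatin_state_comparison(rt0, states)
  expect_false(any(cmp0$pairs$significant))
  # one state shifted by 3 pooled SDs: all its pairs significant
  rt1 <- rt0
  shift <- 3 * 0.5 / log(10)  # log10 scale
  rt1$k_s[states$state == "BLUE"] <-
    rt1$k_s[states$state == "BLUE"] * 10^shift
  cmp1 <- chromatin_state_comparison(rt1, states)
  blue_pairs <- cmp1$pairs$state_a == "BLUE" | cmp1$pairs$state_b == "BLUE"
  expect_true(all(cmp1$pairs$significant[blue_pairs]))
  expect_false(any(cmp1$pairs$significant[!blue_pairs]))
  expect_lt(cmp1$anova_p, 1e-6)
})

test_that("two-state Tukey comparison equals the pooled t-test", {
  set.seed(13)
  states <- tibble::tibble(gene_id = paste0("g", 1:120),
                           state = rep(c("A", "B"), each = 60))
  rt <- tibble::tibble(gene_id = states$gene_id,
                       k_s = exp(rnorm(120, rep(c(0, 0.4), each = 60), 0.6)))
  cmp <- chromatin_state_comparison(rt, states)
  tt <- stats::t.test(log10(rt$k_s) ~ states$state, var.equal = TRUE)
  expect_equal(cmp$pairs$p_adjusted, tt$p.value, tolerance = 1e-8)
  # small states are merged into "other" with a warning
  states2 <- states
  states2$state[1:5] <- "TINY"
  expect_warning(chromatin_state_comparison(rt, states2), "other")
})
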