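#' Configuration of a synthetic labeling experiment
#'
#' Defines the study conditions the generator emulates: 6 labeling time
#' points (0-450 min), 2 fractions, 2 replicates, spike-in scaling,
#' mean-dependent multiplicative noise, labeling escape for uridine-poor
#' transcripts, and a global streptavidin carry-over fraction. Rate
#' distributions are log-normal with medians of 0.83 %/min (export) and
#' 1.40 %/min (decay) and 5th-95th-percentile spans of ~0.5 and ~0.9
#' decades; steady-state abundance spans ~5 decades so that derived
#' transcription rates do too.
#'
#' @param n_genes Number of genes to simulate.
#' @param times Labeling time grid in minutes (must start at 0).
#' @param n_replicates Number of biological replicates.
#' @param ccp A [cell_cycle_params()] object.
#' @param c0_median,c0_decades Median and 5th-95th decade span of the
#'   cytoplasmic steady-state abundance.
#' @param k_e_median,k_e_decades Median (min^-1) and decade span of export.
#' @param k_d_median,k_d_decades Median (min^-1) and decade span of decay.
#' @param noise_cv Function mapping mean abundance to the technical CV, or
#'   a single number for constant CV. The default decreases from ~0.3 at
#'   low abundance to ~0.1 at high abundance.
#' @param u Streptavidin carry-over fraction.
#' @param pr Per-uridine labeling probability.
#' @param nu_per_base Uridine fraction of transcript length.
#' @param length_median,length_sd_log10 Log-normal transcript length model
#'   (bases).
#' @param spike_factor_sd Log10-scale SD of per-sample spike normalization
#'   factors.
#' @param anomaly_fraction Fraction of genes planted as anomalous in the
#'   labeling-effect and fractionation comparison tables.
#' @param anomaly_offset_sd Size of the planted anomaly, in multiples of
#'   the local technical dispersion.
#' @param planted_length_effect If `TRUE`, decay rates scale with
#'   transcript length to the `planted_length_slope` power.
#' @param planted_length_slope Log-log slope of the planted decay-length
#'   dependence.
#' @param planted_rbp `NULL`, or `list(n = , fold = )` planting a bound
#'   gene set of size `n` whose decay rates are multiplied by `fold`.
#' @param planted_states `NULL`, or a named numeric vector of multipliers
#'   applied to the steady-state abundance of genes in each chromatin
#'   state (shifting derived transcription rates).
#' @param n_null_labels Number of additional unplanted (null) RBP label
#'   sets emitted by [generate_feature_annotations()].
#' @param count_size_factor Expected counts per FPKM unit used when
#'   emitting count-level data.
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 500,
                              times = c(0, 30, 90, 180, 300, 450),
                              n_replicates = 2,
                              ccp = cell_cycle_params(),
                              c0_median = 20, c0_decades = 5,
                              k_e_median = 0.0083, k_e_decades = 0.5,
                              k_d_median = 0.0140, k_d_decades = 0.9,
                              noise_cv = NULL,
                              u = 0.073, pr = 0.01, nu_per_base = 0.3,
                              length_median = 2000, length_sd_log10 = 0.35,
                              spike_factor_sd = 0.1,
                              anomaly_fraction = 0.02,
                              anomaly_offset_sd = 5,
                              planted_length_effect = FALSE,
                              planted_length_slope = 0.25,
                              planted_rbp = NULL,
                              planted_states = NULL,
                              n_null_labels = 3,
                              count_size_factor = 50,
                              seed = 1L) {
  stopifnot(n_genes >= 1, times[1] == 0, length(times) >= 4,
            n_replicates >= 1, inherits(ccp, "cell_cycle_params"),
            u >= 0, u <= 1, pr >= 0, pr <= 1)
  if (is.null(noise_cv)) {
    noise_cv <- function(m) pmin(0.3, 0.1 + 0.3 / sqrt(pmax(m, 1e-8)))
  } else if (is.numeric(noise_cv)) {
    cv_const <- noise_cv
    noise_cv <- function(m) rep(cv_const, length(m))
  }
  structure(
    list(n_genes = as.integer(n_genes), times = times,
         n_replicates = as.integer(n_replicates), ccp = ccp,
         c0_median = c0_median, c0_decades = c0_decades,
         k_e_median = k_e_median, k_e_decades = k_e_decades,
         k_d_median = k_d_median, k_d_decades = k_d_decades,
         noise_cv = noise_cv, u = u, pr = pr, nu_per_base = nu_per_base,
         length_median = length_median, length_sd_log10 = length_sd_log10,
         spike_factor_sd = spike_factor_sd,
         anomaly_fraction = anomaly_fraction,
         anomaly_offset_sd = anomaly_offset_sd,
         planted_length_effect = isTRUE(planted_length_effect),
         planted_length_slope = planted_length_slope,
         planted_rbp = planted_rbp, planted_states = planted_states,
         n_null_labels = as.integer(n_null_labels),
         count_size_factor = count_size_factor, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 5th-95th percentile decade span -> log10-scale SD of a log-normal draw.
.decades_to_sd10 <- function(decades) decades / (2 * stats::qnorm(0.95))

#' Draw ground-truth gene parameters
#'
#' Samples per-gene steady-state abundance and (export, decay) rates from
#' log-normal distributions, then derives everything else so that each gene
#' is exactly consistent with the quasi-steady-state, mitotic-exchange and
#' turnover relations: the nuclear-to-cytoplasmic ratio solves
#' `rho = (kD + g + c) / (kE + kf' - c)` with `c` the culture-level inward
#' transfer constant, after which `kf`, `kT` and `kS` follow in closed
#' form. Planted effects (length dependence of decay, a bound gene set
#' with shifted decay, chromatin states with shifted abundance) are applied
#' before the derivation so the planted truth stays self-consistent.
#'
#' @param config A [simulation_config()] object.
#' @return Tibble of class `ground_truth`, one row per gene, with the true
#'   rates, steady state, capture probability and planted annotations.
#' @export
sample_gene_parameters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ccp <- config$ccp
  g <- ccp$g
  ln10 <- log(10)
  truth <- tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    transcript_length = round(10^stats::rnorm(
      n, log10(config$length_median), config$length_sd_log10)),
    k_e = 10^stats::rnorm(n, log10(config$k_e_median),
                          .decades_to_sd10(config$k_e_decades)),
    c0 = 10^stats::rnorm(n, log10(config$c0_median),
                         .decades_to_sd10(config$c0_decades))
  )
  truth$nu <- pmax(1, round(config$nu_per_base * truth$transcript_length))
  truth$f <- capture_probability(truth$nu, config$pr)
  if (config$planted_length_effect) {
    truth$k_d <- 10^(log10(config$k_d_median) +
                       config$planted_length_slope *
                       (log10(truth$transcript_length) -
                          log10(config$length_median)) +
                       stats::rnorm(n, 0, 0.1))
  } else {
    truth$k_d <- 10^stats::rnorm(n, log10(config$k_d_median),
                                 .decades_to_sd10(config$k_d_decades))
  }
  truth$rbp_bound <- FALSE
  if (!is.null(config$planted_rbp)) {
    idx <- sample.int(n, min(config$planted_rbp$n, n))
    truth$rbp_bound[idx] <- TRUE
    truth$k_d[idx] <- truth$k_d[idx] * config$planted_rbp$fold
  }
  state_pool <- c("YELLOW", "RED", "GREEN", "BLUE", "BLACK")
  truth$tss_state <- sample(state_pool, n, replace = TRUE)
  truth$tts_state <- sample(state_pool, n, replace = TRUE)
  if (!is.null(config$planted_states)) {
    mult <- config$planted_states[truth$tss_state]
    mult[is.na(mult)] <- 1
    truth$c0 <- truth$c0 * unname(mult)
  }
  c_const <- mitotic_transfer_constant(ccp)
  k_f_prime <- 2 * (ccp$f_g1s + 2 * ccp$f_g2m - 2 * ccp$f_m) /
    ccp$doubling_time
  # rho must be positive: require kE + kf' > c (holds except in the extreme
  # low tail of kE, where kE is floored just above the constant).
  truth$k_e <- pmax(truth$k_e, 1.5 * c_const - k_f_prime)
  rho <- (truth$k_d + g + c_const) / (truth$k_e + k_f_prime - c_const)
  truth$n0 <- rho * truth$c0
  truth$w0 <- truth$n0 + truth$c0
  truth$k_f <- c_const * (1 + rho)
  truth$k_f_prime <- k_f_prime
  truth$k_t <- truth$k_d * truth$c0 / truth$w0
  truth$k_s <- (g + truth$k_e + k_f_prime) * truth$n0 - truth$k_f * truth$c0
  n_anom <- round(config$anomaly_fraction * n)
  truth$anomalous_labeling <- truth$gene_id %in%
    sample(truth$gene_id, n_anom)
  truth$anomalous_fractionation <- truth$gene_id %in%
    sample(truth$gene_id, n_anom)
  class(truth) <- c("ground_truth", class(truth))
  truth
}

# Mean-preserving multiplicative log-normal noise with sd = cv * mean.
.ln_noise <- function(mean_value, cv) {
  sdlog <- sqrt(log1p(cv^2))
  mean_value * stats::rlnorm(length(mean_value), -sdlog^2 / 2, sdlog)
}

#' Simulate a labeling experiment from ground truth
#'
#' Evaluates the noise-free unlabeled decay curves per compartment, applies
#' labeling escape and streptavidin carry-over as one effective
#' unlabeled-appearing fraction of new RNA (`q = (1 - F) + U F`, so the
#' measured series is `Xm(t) = (1 - q) Xp(t) + q X0 e^{g t}`), multiplies
#' by per-replicate log-normal noise with mean-dependent CV, and divides by
#' per-sample spike factors to emit raw FPKM alongside the spike-normalized
#' truth scale. Also emits the summed bulk series per replicate, the
#' mapped-read table consumed by [spike_normalize()], and the two outlier-
#' screening comparison tables with planted anomalous genes.
#'
#' @param truth A [sample_gene_parameters()] tibble.
#' @param config The matching [simulation_config()].
#' @return A list of class `sim_experiment` with elements `measurements`,
#'   `mapped_reads`, `bulk`, `labeling_comparison`,
#'   `fractionation_comparison`, `truth` and `config`.
#' @export
simulate_experiment <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  g <- config$ccp$g
  times <- config$times
  grid <- tidyr::expand_grid(
    gene_id = truth$gene_id,
    fraction = c("nuclear", "cytoplasmic"),
    time_min = times
  ) |>
    dplyr::left_join(truth, by = "gene_id")
  # vectorized across rows: curves depend elementwise on gene parameters
  nuc <- grid$fraction == "nuclear"
  xp <- numeric(nrow(grid))
  a_nuc <- grid$k_e + grid$k_f_prime + grid$k_f
  a_cyt <- a_nuc + grid$k_d
  xp[nuc] <- .two_exp_vec(grid$time_min[nuc], grid$n0[nuc], grid$w0[nuc],
                          a_nuc[nuc], grid$k_f[nuc], grid$k_t[nuc])
  xp[!nuc] <- .two_exp_vec(grid$time_min[!nuc], grid$c0[!nuc], grid$w0[!nuc],
                           a_cyt[!nuc], (grid$k_e + grid$k_f_prime)[!nuc],
                           grid$k_t[!nuc])
  x0 <- ifelse(nuc, grid$n0, grid$c0)
  q <- (1 - grid$f) + config$u * grid$f
  xm <- (1 - q) * xp + q * x0 * exp(g * grid$time_min)
  base <- dplyr::select(grid, "gene_id", "fraction", "time_min") |>
    dplyr::mutate(true_unlabeled = xp, expected_measured = xm)
  reps <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    dplyr::mutate(
      base, replicate = r,
      fpkm_spikenorm = .ln_noise(.data$expected_measured,
                                 config$noise_cv(.data$expected_measured)))
  })
  samples <- tidyr::expand_grid(
    fraction = c("nuclear", "cytoplasmic"),
    replicate = seq_len(config$n_replicates),
    time_min = times
  ) |>
    dplyr::mutate(
      norm_factor = 10^stats::rnorm(dplyr::n(), 0, config$spike_factor_sd),
      spike_mapped_reads = 1e5,
      host_mapped_reads = .data$norm_factor * 1e5
    )
  measurements <- reps |>
    dplyr::left_join(dplyr::select(samples, "fraction", "replicate",
                                   "time_min", "norm_factor"),
                     by = c("fraction", "replicate", "time_min")) |>
    dplyr::mutate(fpkm = .data$fpkm_spikenorm / .data$norm_factor) |>
    dplyr::select("gene_id", "fraction", "replicate", "time_min", "fpkm",
                  "fpkm_spikenorm", "true_unlabeled")
  bulk <- measurements |>
    dplyr::summarise(abundance = sum(.data$fpkm_spikenorm),
                     .by = c("replicate", "time_min")) |>
    dplyr::arrange(.data$replicate, .data$time_min)
  comparison <- function(anomalous) {
    x <- log10(truth$w0)
    disp <- config$noise_cv(truth$w0) / log(10)
    y <- x + stats::rnorm(nrow(truth), 0, disp) +
      anomalous * sample(c(-1, 1), nrow(truth), replace = TRUE) *
        config$anomaly_offset_sd * disp
    tibble::tibble(gene_id = truth$gene_id, x = x, y = y,
                   anomalous = anomalous)
  }
  labeling_comparison <- comparison(truth$anomalous_labeling)
  fractionation_comparison <- comparison(truth$anomalous_fractionation)
  structure(
    list(measurements = measurements,
         mapped_reads = dplyr::select(samples, "fraction", "replicate",
                                      "time_min", "host_mapped_reads",
                                      "spike_mapped_reads"),
         bulk = bulk,
         labeling_comparison = labeling_comparison,
         fractionation_comparison = fractionation_comparison,
         truth = truth, config = config),
    class = "sim_experiment"
  )
}

# Vectorized two-exponential curve over per-element parameters.
.two_exp_vec <- function(t, x0, w0, a, coef, k_t, tol = 1e-12) {
  degen <- abs(a - k_t) < tol
  out <- numeric(length(t))
  if (any(degen)) {
    out[degen] <- x0[degen] * exp(-a[degen] * t[degen]) +
      coef[degen] * w0[degen] * t[degen] * exp(-k_t[degen] * t[degen])
  }
  nd <- !degen
  out[nd] <- x0[nd] * exp(-a[nd] * t[nd]) +
    w0[nd] * coef[nd] / (a[nd] - k_t[nd]) *
      (exp(-k_t[nd] * t[nd]) - exp(-a[nd] * t[nd]))
  out
}

#' Emit count-level data for a simulated experiment
#'
#' Poisson counts around the FPKM-scaled expectation, enabling read-level
#' operations such as binomial down-sampling.
#'
#' @param measurements Measurement tibble from [simulate_experiment()].
#' @param size_factor Expected counts per FPKM unit.
#' @param seed Integer seed.
#' @return The measurements with a `count` column added.
#' @export
simulate_counts <- function(measurements, size_factor = 50, seed = 1L) {
  check_columns(measurements, "fpkm", "measurements")
  set.seed(as.integer(seed))
  dplyr::mutate(measurements,
                count = stats::rpois(dplyr::n(), .data$fpkm * size_factor))
}

#' Binomial down-sampling of read counts
#'
#' Thins each count to a `fraction` of the original depth by binomial
#' sampling, mimicking random read down-sampling.
#'
#' @param counts Integer vector of counts.
#' @param fraction Retained fraction in (0, 1].
#' @param seed Integer seed (deterministic thinning).
#' @return Integer vector of thinned counts.
#' @export
downsample_reads <- function(counts, fraction = 0.25, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, all(counts >= 0),
            all(counts == round(counts)))
  if (fraction == 1) return(as.integer(counts))
  set.seed(as.integer(seed))
  stats::rbinom(length(counts), size = as.integer(counts), prob = fraction)
}

#' Convert counts back to abundance after thinning
#'
#' @param counts Integer counts.
#' @param size_factor The size factor used by [simulate_counts()].
#' @param fraction The thinning fraction applied, so depth is corrected.
#' @return FPKM-scale abundances.
#' @export
counts_to_abundance <- function(counts, size_factor = 50, fraction = 1) {
  counts / (size_factor * fraction)
}

#' Generate feature and label annotations for simulated genes
#'
#' Builds the per-gene feature table (lengths and exon counts; transcript
#' length comes from the ground truth so planted length effects carry
#' through), the RBP-style label sets (the planted bound set when present,
#' plus seeded null sets), and the chromatin-state table.
#'
#' @param truth A [sample_gene_parameters()] tibble.
#' @param config The matching [simulation_config()].
#' @return A list with `features`, `labels` (tibble `gene_id`, `label`,
#'   `bound`) and `states` (tibble `gene_id`, `tss_state`, `tts_state`).
#' @export
generate_feature_annotations <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  features <- tibble::tibble(
    gene_id = truth$gene_id,
    transcript_length = truth$transcript_length,
    intron_length = round(10^stats::rnorm(n, 3, 0.6)),
    utr3_length = round(10^stats::rnorm(n, 2.5, 0.4)),
    utr5_length = round(10^stats::rnorm(n, 2.2, 0.35)),
    cds_length = pmax(150, round(0.6 * truth$transcript_length)),
    n_exons = 1 + stats::rpois(n, 3)
  )
  labels <- purrr::map_dfr(seq_len(config$n_null_labels), function(i) {
    tibble::tibble(gene_id = truth$gene_id,
                   label = sprintf("RBP_null_%02d", i),
                   bound = stats::runif(n) < 0.1)
  })
  if (!is.null(config$planted_rbp)) {
    labels <- dplyr::bind_rows(
      tibble::tibble(gene_id = truth$gene_id, label = "RBP_planted",
                     bound = truth$rbp_bound),
      labels
    )
  }
  states <- dplyr::select(truth, "gene_id", "tss_state", "tts_state")
  list(features = features, labels = labels, states = states)
}
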