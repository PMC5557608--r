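# Shared fixture builders: everything is generated in code, seeded.

default_ccp <- cell_cycle_params()

# A quasi-steady-state-consistent gene: given (k_e, k_d, c0), solve the
# self-consistent nuclear/cytoplasmic ratio (the inward mitotic rate depends
# on the total pool) and derive all remaining quantities.
make_consistent_gene <- function(k_e = 0.0083, k_d = 0.0140, c0 = 50,
                                 ccp = default_ccp) {
  cc <- mitotic_transfer_constant(ccp)
  k_f_prime <- 2 * (ccp$f_g1s + 2 * ccp$f_g2m - 2 * ccp$f_m) /
    ccp$doubling_time
  rho <- (k_d + ccp$g + cc) / (k_e + k_f_prime - cc)
  ss <- steady_state(n0 = rho * c0, c0 = c0)
  k_f <- cc * (1 + rho)
  k_t <- overall_turnover_rate(k_d, ss)
  k_s <- derive_transcription_rate(ss, k_e = k_e, k_f = k_f,
                                   k_f_prime = k_f_prime, g = ccp$g)
  list(ss = ss,
       rates = kinetic_rates(k_s = k_s, k_e = k_e, k_d = k_d, k_t = k_t,
                             k_f = k_f, k_f_prime = k_f_prime),
       ccp = ccp)
}

# Noise-free unlabeled series of a consistent gene on the standard grid.
make_noisefree_series <- function(gene = make_consistent_gene(),
                                  times = c(0, 30, 90, 180, 300, 450)) {
  tibble::tibble(
    time_min = times,
    nuclear = unlabeled_nuclear(times, gene$ss, gene$rates),
    cytoplasmic = unlabeled_cytoplasmic(times, gene$ss, gene$rates)
  )
}

# Long-format measurement table for n replicates with multiplicative
# log-normal noise of a given CV (0 = noise-free).
make_measurements <- function(gene = make_consistent_gene(), cv = 0,
                              n_replicates = 2,
                              times = c(0, 30, 90, 180, 300, 450),
                              gene_id = "g1") {
  ser <- make_noisefree_series(gene, times)
  long <- tidyr::pivot_longer(ser, c("nuclear", "cytoplasmic"),
                              names_to = "fraction",
                              values_to = "fpkm_spikenorm")
  out <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
    dplyr::mutate(long, replicate = r, gene_id = gene_id)
  }))
  if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    out$fpkm_spikenorm <- out$fpkm_spikenorm *
      stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog)
  }
  out
}

# Rates table with independently drawn components; abundances follow the
# no-mitosis closed form so decomposition targets are exact by design.
make_rate_table <- function(n, sd_s = 1, sd_e = 0.3, sd_d = 0.5, seed = 1,
                            g = log(2) / 1440) {
  set.seed(seed)
  k_s <- exp(rnorm(n, log(5), sd_s))
  k_e <- exp(rnorm(n, log(0.0083), sd_e))
  k_d <- exp(rnorm(n, log(0.014), sd_d))
  c0 <- k_s * (k_e / (k_e + g)) / (k_d + g)
  tibble::tibble(gene_id = paste0("g", seq_len(n)), k_s = k_s, k_e = k_e,
                 k_d = k_d, n0 = c0, c0 = c0, w0 = 2 * c0)
}

# Independent numerical oracle: integrate the pre-existing-RNA compartment
# ODEs with the turnover-approximated total Wp(t) = W0 exp(-kT t) as
# forcing (the same substitution the closed forms solve):
#   dNp/dt = -(kE+kf'+kf) Np + kf Wp
#   dCp/dt = -(kE+kf'+kD+kf) Cp + (kE+kf') Wp
ode_unlabeled_oracle <- function(times, ss, rates) {
  derivs <- function(t, y, parms) {
    wp <- ss$w0 * exp(-rates$k_t * t)
    list(c(
      -(rates$k_e + rates$k_f_prime + rates$k_f) * y[1] + rates$k_f * wp,
      -(rates$k_e + rates$k_f_prime + rates$k_d + rates$k_f) * y[2] +
        (rates$k_e + rates$k_f_prime) * wp
    ))
  }
  out <- deSolve::lsoda(c(np = ss$n0, cp = ss$c0), times, derivs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  list(np = out[, "np"], cp = out[, "cp"])
}
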