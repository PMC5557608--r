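#' Cell-cycle parameters of the proliferating culture
#'
#' Bundles the culture-level constants that determine the proliferation rate
#' and the effective mitotic exchange rates between nucleus and cytoplasm.
#' Defaults describe an asynchronously dividing Kc167-like culture: a 24 h
#' doubling time, 20% of the cycle in G1/S, 80% in G2/M (where cells carry
#' roughly twofold content), about 1 h of mitosis, and a nucleus-to-cell
#' diameter ratio of 4:5.
#'
#' @param doubling_time Doubling time of the culture in minutes.
#' @param f_g1s Fraction of the cycle spent in G1/S.
#' @param f_g2m Fraction of the cycle spent in G2/M. `f_g1s + f_g2m` must be 1.
#' @param f_m Fraction of the cycle spent in mitosis (`0 <= f_m <= f_g2m`).
#' @param r_nc Nucleus-to-cell diameter ratio, strictly between 0 and 1.
#'
#' @return A list of class `cell_cycle_params` with the supplied fields plus
#'   `g`, the proliferation rate `ln(2) / doubling_time` in min^-1.
#' @examples
#' ccp <- cell_cycle_params()
#' ccp$g * 100 # 0.048 % per minute
#' @export
cell_cycle_params <- function(doubling_time = 1440, f_g1s = 0.2, f_g2m = 0.8,
                              f_m = 1 / 24, r_nc = 0.8) {
  stopifnot(is.numeric(doubling_time), length(doubling_time) == 1)
  if (doubling_time <= 0) stop("`doubling_time` must be positive (minutes).")
  if (abs(f_g1s + f_g2m - 1) > 1e-9) {
    stop("`f_g1s` and `f_g2m` must sum to 1 (got ", f_g1s + f_g2m, ").")
  }
  if (f_m < 0 || f_m > f_g2m) stop("`f_m` must lie in [0, f_g2m].")
  if (r_nc <= 0 || r_nc >= 1) stop("`r_nc` must be strictly between 0 and 1.")
  structure(
    list(doubling_time = doubling_time, f_g1s = f_g1s, f_g2m = f_g2m,
         f_m = f_m, r_nc = r_nc, g = proliferation_rate(doubling_time)),
    class = "cell_cycle_params"
  )
}

#' Proliferation rate from the doubling time
#'
#' @param doubling_time Doubling time in minutes.
#' @return Proliferation rate `ln(2) / doubling_time` in min^-1
#'   (multiply by 100 for percent per minute).
#' @examples
#' proliferation_rate(1440) * 100 # 0.048 %/min for a 24 h doubling time
#' @export
proliferation_rate <- function(doubling_time) {
  if (any(is.na(doubling_time)) || any(doubling_time <= 0)) {
    stop("`doubling_time` must be positive.")
  }
  log(2) / doubling_time
}

#' Steady-state compartment abundances
#'
#' @param n0 Nuclear abundance at t = 0 (spike-normalized FPKM).
#' @param c0 Cytoplasmic abundance at t = 0 (same units).
#' @return A list of class `steady_state` with `n0`, `c0` and `w0 = n0 + c0`.
#' @export
steady_state <- function(n0, c0) {
  if (any(n0 < 0) || any(c0 < 0)) stop("steady-state abundances must be >= 0")
  structure(list(n0 = n0, c0 = c0, w0 = n0 + c0), class = "steady_state")
}

#' Per-gene kinetic rate constants
#'
#' Container for the first-order rates of one gene: transcription `k_s`
#' (spike-normalized FPKM min^-1), nuclear export `k_e`, cytoplasmic decay
#' `k_d`, overall turnover `k_t`, and the mitotic exchange rates `k_f`
#' (cytoplasm to nucleus) and `k_f_prime` (nucleus to cytoplasm), all min^-1.
#'
#' @param k_s,k_e,k_d,k_t,k_f,k_f_prime Non-negative rates (see description).
#' @return A list of class `kinetic_rates`.
#' @export
kinetic_rates <- function(k_s, k_e, k_d, k_t, k_f = 0, k_f_prime = 0) {
  vals <- c(k_s, k_e, k_d, k_t, k_f, k_f_prime)
  if (any(vals < 0)) stop("all kinetic rates must be >= 0")
  structure(list(k_s = k_s, k_e = k_e, k_d = k_d, k_t = k_t,
                 k_f = k_f, k_f_prime = k_f_prime),
            class = "kinetic_rates")
}

#' Mitotic nucleocytoplasmic exchange rates
#'
#' During mitosis the nuclear envelope breaks down and transcripts
#' redistribute between compartments. Averaged over an asynchronous culture
#' this is modeled as a pair of effective first-order exchange rates: the
#' cytoplasm-to-nucleus rate depends on the nuclear volume fraction
#' (`r_nc^3`) and, through the total pool `(N0 + C0) / C0`, is gene-specific;
#' the nucleus-to-cytoplasm rate is a culture constant.
#'
#' @param ccp A [cell_cycle_params()] object.
#' @param ss A [steady_state()] object; `ss$c0` must be positive for the
#'   inward rate to be defined.
#' @return A list with `k_f` (cytoplasm to nucleus, min^-1) and `k_f_prime`
#'   (nucleus to cytoplasm, min^-1).
#' @examples
#' mitotic_transfer_rates(cell_cycle_params(), steady_state(50, 50))
#' @export
mitotic_transfer_rates <- function(ccp, ss) {
  stopifnot(inherits(ccp, "cell_cycle_params"), inherits(ss, "steady_state"))
  if (any(ss$c0 <= 0)) {
    stop("degenerate steady state: c0 must be > 0 to define the inward rate")
  }
  d <- ccp$doubling_time
  phase <- ccp$f_g1s + 2 * ccp$f_g2m
  k_f <- 2 * ccp$r_nc^3 * ss$w0 * phase / (d * ss$c0)
  k_f_prime <- 2 * (phase - 2 * ccp$f_m) / d
  list(k_f = k_f, k_f_prime = k_f_prime)
}

#' Culture-level component of the inward mitotic transfer rate
#'
#' The gene-independent factor `2 r_nc^3 (F_G1S + 2 F_G2M) / D`, such that
#' `k_f = const * (N0 + C0) / C0`. Used by the synthetic-data generator to
#' solve for a self-consistent nuclear-to-cytoplasmic ratio.
#'
#' @param ccp A [cell_cycle_params()] object.
#' @return A rate in min^-1.
#' @export
mitotic_transfer_constant <- function(ccp) {
  stopifnot(inherits(ccp, "cell_cycle_params"))
  2 * ccp$r_nc^3 * (ccp$f_g1s + 2 * ccp$f_g2m) / ccp$doubling_time
}

#' Solve the quasi-steady state for compartment abundances
#'
#' Under quasi-steady state the per-gene pools grow exponentially at the
#' proliferation rate `g`, which pins the compartment abundances to the
#' linear system `k_s - (k_e + k_f') N0 + k_f C0 = g N0` and
#' `(k_e + k_f') N0 - (k_d + k_f) C0 = g C0`.
#'
#' @param k_s Transcription rate (abundance min^-1).
#' @param k_e,k_d,k_f,k_f_prime First-order rates in min^-1.
#' @param g Proliferation rate in min^-1.
#' @return A [steady_state()] object.
#' @examples
#' solve_steady_state(1, k_e = 0.01, k_d = 0.02) # N0 = 100, C0 = 50
#' @export
solve_steady_state <- function(k_s, k_e, k_d, k_f = 0, k_f_prime = 0, g = 0) {
  a <- rbind(c(g + k_e + k_f_prime, -k_f),
             c(k_e + k_f_prime, -(k_d + k_f + g)))
  if (abs(det(a)) < 1e-300) {
    stop("singular quasi-steady-state system (det = ", det(a),
         "); check that rates are not all zero")
  }
  sol <- solve(a, c(k_s, 0))
  steady_state(n0 = sol[1], c0 = sol[2])
}

#' Transcription rate implied by a measured steady state
#'
#' Inverts the nuclear row of the quasi-steady-state system:
#' `k_s = (g + k_e + k_f') N0 - k_f C0`. A negative result indicates that
#' the supplied rates and abundances are not mutually consistent; the value
#' is returned with a warning so the caller can flag the gene.
#'
#' @inheritParams solve_steady_state
#' @param ss A [steady_state()] object (t = 0 measurements).
#' @return Transcription rate in abundance min^-1.
#' @export
derive_transcription_rate <- function(ss, k_e, k_f = 0, k_f_prime = 0, g = 0) {
  stopifnot(inherits(ss, "steady_state"))
  k_s <- (g + k_e + k_f_prime) * ss$n0 - k_f * ss$c0
  if (any(k_s < 0)) {
    warning("inconsistent steady state: derived transcription rate < 0")
  }
  k_s
}

#' Overall turnover rate from the cytoplasmic decay rate
#'
#' Decay happens in the cytoplasm, so the whole-cell pool turns over at
#' `k_t = k_d * C0 / W0`.
#'
#' @param k_d Cytoplasmic decay rate (min^-1).
#' @param ss A [steady_state()] object with `w0 > 0`.
#' @return Overall turnover rate in min^-1.
#' @export
overall_turnover_rate <- function(k_d, ss) {
  stopifnot(inherits(ss, "steady_state"))
  if (any(ss$w0 <= 0)) stop("w0 must be > 0 to define the turnover rate")
  k_d * ss$c0 / ss$w0
}

#' Pre-existing (unlabeled) total RNA over labeling time
#'
#' @param t Time since label addition, minutes (vectorized).
#' @param w0 Total abundance at t = 0.
#' @param k_t Overall turnover rate (min^-1).
#' @return `w0 * exp(-k_t * t)`.
#' @export
unlabeled_total <- function(t, w0, k_t) {
  stopifnot(all(t >= 0))
  w0 * exp(-k_t * t)
}

# Shared two-exponential solution of dX/dt = -a X + coef * Wp(t), X(0) = x0,
# with Wp(t) = w0 exp(-k_t t). Removable singularity at a == k_t handled by
# the analytic limit coef * w0 * t * exp(-k_t t).
.two_exp_curve <- function(t, x0, w0, a, coef, k_t, tol = 1e-12) {
  if (abs(a - k_t) < tol) {
    x0 * exp(-a * t) + coef * w0 * t * exp(-k_t * t)
  } else {
    x0 * exp(-a * t) + w0 * coef / (a - k_t) * (exp(-k_t * t) - exp(-a * t))
  }
}

#' Pre-existing nuclear RNA over labeling time
#'
#' Closed-form solution of the pre-existing nuclear pool, which loses RNA by
#' export and mitotic outflow and gains the mitotic inflow `k_f * Wp(t)`:
#' `Np(t) = N0 e^{-(kE+kf'+kf) t} + W0 kf / (kE+kf'+kf-kT)
#'          (e^{-kT t} - e^{-(kE+kf'+kf) t})`.
#'
#' @param t Time in minutes (vectorized).
#' @param ss A [steady_state()] object.
#' @param rates A [kinetic_rates()] object.
#' @return Nuclear pre-existing abundance at `t`.
#' @export
unlabeled_nuclear <- function(t, ss, rates) {
  stopifnot(inherits(ss, "steady_state"), inherits(rates, "kinetic_rates"),
            all(t >= 0))
  a <- rates$k_e + rates$k_f_prime + rates$k_f
  .two_exp_curve(t, ss$n0, ss$w0, a, rates$k_f, rates$k_t)
}

#' Pre-existing cytoplasmic RNA over labeling time
#'
#' Closed-form solution of the pre-existing cytoplasmic pool:
#' `Cp(t) = C0 e^{-(kE+kf'+kD+kf) t} + W0 (kE+kf') / (kE+kf'+kD+kf-kT)
#'          (e^{-kT t} - e^{-(kE+kf'+kD+kf) t})`.
#'
#' @inheritParams unlabeled_nuclear
#' @return Cytoplasmic pre-existing abundance at `t`.
#' @export
unlabeled_cytoplasmic <- function(t, ss, rates) {
  stopifnot(inherits(ss, "steady_state"), inherits(rates, "kinetic_rates"),
            all(t >= 0))
  a <- rates$k_e + rates$k_f_prime + rates$k_d + rates$k_f
  .two_exp_curve(t, ss$c0, ss$w0, a, rates$k_e + rates$k_f_prime, rates$k_t)
}

#' Half-life of a first-order rate
#'
#' @param k First-order rate constant in min^-1 (must be > 0).
#' @return Half-life in hours, `ln(2) / (60 k)`.
#' @examples
#' half_life(0.0083) # ~1.4 h
#' half_life(0.0140) # ~0.8 h
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("`k` must be > 0 to have a finite half-life")
  log(2) / (60 * k)
}
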