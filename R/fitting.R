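#' Fitting configuration
#'
#' Collects the tunable knobs of the per-gene fit in one validated list.
#'
#' @param r2_threshold Retention threshold on the coefficient of
#'   determination (default 0.8, applied per fraction).
#' @param max_dropped Maximum zero-abundance time points dropped per
#'   fraction before a gene is declared unfittable (default 2).
#' @param weighting `"as_printed"` multiplies log-ratios by the CV weight
#'   `L(m)`; `"inverse"` divides by it.
#' @param r2_scale Scale on which r-squared is computed: `"log10"` (matches
#'   the log-ratio objective) or `"linear"`.
#' @param multi_start If `TRUE`, the optimizer is restarted from 5
#'   perturbed initializations and the best deviance wins; the default
#'   single deterministic start is used otherwise.
#' @param retention_rule How replicate/fraction r-squared values combine
#'   into the retained flag: `"all"` (every fraction of every replicate
#'   must pass) or `"any"`.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(r2_threshold = 0.8, max_dropped = 2,
                       weighting = c("as_printed", "inverse"),
                       r2_scale = c("log10", "linear"),
                       multi_start = FALSE,
                       retention_rule = c("all", "any")) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, max_dropped >= 0)
  structure(
    list(r2_threshold = r2_threshold, max_dropped = max_dropped,
         weighting = match.arg(weighting), r2_scale = match.arg(r2_scale),
         multi_start = isTRUE(multi_start),
         retention_rule = match.arg(retention_rule)),
    class = "fit_config"
  )
}

# Internal: weights applied to a log-ratio residual.
.apply_weight <- function(log_ratio, w, weighting) {
  if (weighting == "inverse") log_ratio / pmax(w, 1e-8) else w * log_ratio
}

#' Four-component fitting objective
#'
#' Evaluates the four components of the least-squares objective for a trial
#' parameter set against one gene's measured unlabeled series: (1) the
#' CV-weighted squared log-ratios of measured versus modeled nuclear
#' abundance, averaged over time points; (2) the same for the cytoplasmic
#' fraction; (3) a soft quasi-steady-state penalty
#' `[L(N0)/L(C0)] log^2((kE+kf') N0 / ((kD+kf+g) C0))`; and (4) the
#' turnover-consistency penalty `[L(W0)/L(C0)] log^2(kT W0 / (kD C0))`.
#' Zero measured abundances are dropped from components 1-2.
#'
#' @param params Named numeric vector or list with `k_e`, `k_d`, `k_t`
#'   (min^-1), all positive.
#' @param series Tibble for one gene and replicate with columns `time_min`,
#'   `nuclear`, `cytoplasmic` (measured unlabeled abundances; must include
#'   t = 0).
#' @param ccp A [cell_cycle_params()] object.
#' @param noise A `noise_model` supplying the CV weights.
#' @param config A [fit_config()] object.
#' @return A list with `theta` (the 4-vector of components), `residuals`
#'   (the stacked residual vector whose squared sum is `sum(theta)`), and
#'   `n_dropped` per fraction.
#' @export
objective_components <- function(params, series, ccp,
                                 noise = constant_noise_model(),
                                 config = fit_config()) {
  check_columns(series, c("time_min", "nuclear", "cytoplasmic"), "series")
  stopifnot(inherits(ccp, "cell_cycle_params"))
  series <- dplyr::arrange(series, .data$time_min)
  if (series$time_min[1] != 0) stop("series must include time_min == 0")
  n0 <- series$nuclear[1]
  c0 <- series$cytoplasmic[1]
  if (n0 <= 0 || c0 <= 0) {
    stop("zero steady-state abundance (N0 or C0); gene cannot be fitted")
  }
  ss <- steady_state(n0, c0)
  mt <- mitotic_transfer_rates(ccp, ss)
  k_e <- params[["k_e"]]; k_d <- params[["k_d"]]; k_t <- params[["k_t"]]
  stopifnot(k_e > 0, k_d > 0, k_t > 0)
  rates <- kinetic_rates(k_s = 0, k_e = k_e, k_d = k_d, k_t = k_t,
                         k_f = mt$k_f, k_f_prime = mt$k_f_prime)
  g <- ccp$g
  comp_resid <- function(measured, model_fn) {
    keep <- measured > 0
    mod <- model_fn(series$time_min[keep])
    w <- predict(noise, measured[keep])
    r <- .apply_weight(log(measured[keep] / mod), w, config$weighting) /
      sqrt(sum(keep))
    list(r = r, dropped = sum(!keep))
  }
  nuc <- comp_resid(series$nuclear,
                    function(t) unlabeled_nuclear(t, ss, rates))
  cyt <- comp_resid(series$cytoplasmic,
                    function(t) unlabeled_cytoplasmic(t, ss, rates))
  w_n0 <- predict(noise, n0)
  w_c0 <- predict(noise, c0)
  w_w0 <- predict(noise, ss$w0)
  r3 <- sqrt(w_n0 / pmax(w_c0, 1e-8)) *
    log((k_e + mt$k_f_prime) * n0 / ((k_d + mt$k_f + g) * c0))
  r4 <- sqrt(w_w0 / pmax(w_c0, 1e-8)) *
    log(k_t * ss$w0 / (k_d * c0))
  theta <- c(nuclear = sum(nuc$r^2), cytoplasmic = sum(cyt$r^2),
             steady_state = r3^2, turnover = r4^2)
  list(theta = theta, residuals = c(nuc$r, cyt$r, r3, r4),
       n_dropped = c(nuclear = nuc$dropped, cytoplasmic = cyt$dropped))
}

# Internal: deterministic initialization of (k_e, k_d, k_t).
.init_params <- function(series, ss, mt, g) {
  tot <- series$nuclear + series$cytoplasmic
  keep <- tot > 0
  k_t0 <- -stats::coef(stats::lm(log(tot[keep]) ~ series$time_min[keep]))[[2]]
  k_t0 <- min(max(k_t0, 1e-5), 0.2)
  k_d0 <- min(max(k_t0 * ss$w0 / ss$c0, 1e-5), 1)
  k_e0 <- (k_d0 + mt$k_f + g) * ss$c0 / ss$n0 - mt$k_f_prime
  k_e0 <- min(max(k_e0, 1e-5), 1)
  c(k_e = k_e0, k_d = k_d0, k_t = k_t0)
}

#' Fit the kinetic model to one gene's time series
#'
#' Minimizes the stacked residual vector of the four-component objective
#' over log-parameterized `(k_e, k_d, k_t)` by Levenberg-Marquardt. The
#' steady-state abundances `N0`, `C0` are pinned to the t = 0 measurements,
#' the mitotic exchange rates follow from the cell-cycle parameters, and
#' the transcription rate is derived afterwards from the quasi-steady
#' state. The initialization is deterministic: the starting turnover rate
#' comes from a log-linear regression of total abundance on time, and the
#' starting decay and export rates from the steady-state relations.
#'
#' @inheritParams objective_components
#' @param gene_id,replicate Identifiers carried into the result.
#' @return An object of class `gene_fit` carrying the fitted
#'   [kinetic_rates()], the steady state, the objective components, per-
#'   fraction r-squared, and `converged`/`retained` flags. Degenerate
#'   series (zero N0/C0, or more than `config$max_dropped` zero points per
#'   fraction) yield `converged = FALSE` with a `message`.
#' @examples
#' ccp <- cell_cycle_params()
#' ss <- steady_state(60, 40)
#' mt <- mitotic_transfer_rates(ccp, ss)
#' rates <- kinetic_rates(k_s = 0, k_e = 0.0083, k_d = 0.014,
#'                        k_t = overall_turnover_rate(0.014, ss),
#'                        k_f = mt$k_f, k_f_prime = mt$k_f_prime)
#' tt <- c(0, 30, 90, 180, 300, 450)
#' series <- tibble::tibble(time_min = tt,
#'                          nuclear = unlabeled_nuclear(tt, ss, rates),
#'                          cytoplasmic = unlabeled_cytoplasmic(tt, ss, rates))
#' fit_gene(series, ccp)
#' @export
fit_gene <- function(series, ccp, noise = constant_noise_model(),
                     config = fit_config(), gene_id = NA_character_,
                     replicate = NA_integer_) {
  check_columns(series, c("time_min", "nuclear", "cytoplasmic"), "series")
  series <- dplyr::arrange(series, .data$time_min)
  fail <- function(msg) {
    structure(
      list(gene_id = gene_id, replicate = replicate, rates = NULL,
           ss = NULL, theta = rep(NA_real_, 4), r2_nuclear = NA_real_,
           r2_cytoplasmic = NA_real_, converged = FALSE, retained = FALSE,
           message = msg, series = series, ccp = ccp),
      class = "gene_fit"
    )
  }
  if (series$time_min[1] != 0) return(fail("no t = 0 measurement"))
  n0 <- series$nuclear[1]
  c0 <- series$cytoplasmic[1]
  if (n0 <= 0 || c0 <= 0) return(fail("zero steady-state abundance"))
  dropped <- c(sum(series$nuclear == 0), sum(series$cytoplasmic == 0))
  if (any(dropped > config$max_dropped)) {
    return(fail("too many zero-abundance time points"))
  }
  ss <- steady_state(n0, c0)
  mt <- mitotic_transfer_rates(ccp, ss)
  par0 <- .init_params(series, ss, mt, ccp$g)
  # Weights depend only on measured values: precompute once, then the
  # residual evaluation inside the optimizer is pure arithmetic.
  g <- ccp$g
  keep_n <- series$nuclear > 0
  keep_c <- series$cytoplasmic > 0
  t_n <- series$time_min[keep_n]
  t_c <- series$time_min[keep_c]
  obs_n <- series$nuclear[keep_n]
  obs_c <- series$cytoplasmic[keep_c]
  w_n <- predict(noise, obs_n)
  w_c <- predict(noise, obs_c)
  w3 <- sqrt(predict(noise, n0) / pmax(predict(noise, c0), 1e-8))
  w4 <- sqrt(predict(noise, ss$w0) / pmax(predict(noise, c0), 1e-8))
  wt <- function(log_ratio, w) .apply_weight(log_ratio, w, config$weighting)
  resid_fn <- function(logpar) {
    k_e <- exp(logpar[1]); k_d <- exp(logpar[2]); k_t <- exp(logpar[3])
    a_n <- k_e + mt$k_f_prime + mt$k_f
    a_c <- a_n + k_d
    np <- .two_exp_curve(t_n, n0, ss$w0, a_n, mt$k_f, k_t)
    cp <- .two_exp_curve(t_c, c0, ss$w0, a_c, k_e + mt$k_f_prime, k_t)
    c(wt(log(obs_n / np), w_n) / sqrt(length(t_n)),
      wt(log(obs_c / cp), w_c) / sqrt(length(t_c)),
      w3 * log((k_e + mt$k_f_prime) * n0 / ((k_d + mt$k_f + g) * c0)),
      w4 * log(k_t * ss$w0 / (k_d * c0)))
  }
  starts <- list(log(par0))
  if (config$multi_start) {
    for (f in c(-1, -0.5, 0.5, 1)) {
      starts[[length(starts) + 1]] <- log(par0) + f
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) return(fail("optimizer failure"))
  converged <- best$info %in% 1:4
  p <- exp(best$par)
  names(p) <- c("k_e", "k_d", "k_t")
  k_s <- suppressWarnings(
    derive_transcription_rate(ss, k_e = p[["k_e"]], k_f = mt$k_f,
                              k_f_prime = mt$k_f_prime, g = ccp$g))
  obj <- objective_components(p, series, ccp, noise, config)
  rates <- kinetic_rates(k_s = max(k_s, 0), k_e = p[["k_e"]],
                         k_d = p[["k_d"]], k_t = p[["k_t"]],
                         k_f = mt$k_f, k_f_prime = mt$k_f_prime)
  r2 <- goodness_of_fit(series, ss, rates, scale = config$r2_scale)
  structure(
    list(gene_id = gene_id, replicate = replicate, rates = rates, ss = ss,
         theta = obj$theta, r2_nuclear = r2[["r2_nuclear"]],
         r2_cytoplasmic = r2[["r2_cytoplasmic"]], converged = converged,
         retained = converged &&
           !is.na(r2[["r2_nuclear"]]) && !is.na(r2[["r2_cytoplasmic"]]) &&
           r2[["r2_nuclear"]] > config$r2_threshold &&
           r2[["r2_cytoplasmic"]] > config$r2_threshold,
         message = if (converged) NA_character_ else
           paste0("no convergence (info ", best$info, ")"),
         series = series, ccp = ccp),
    class = "gene_fit"
  )
}

#' Goodness of fit of the kinetic curves
#'
#' Per fraction, `r^2 = 1 - SS_res / SS_tot` of the measured versus modeled
#' unlabeled abundances across the time grid, computed on log10 scale by
#' default to match the log-ratio objective. Zero measured values are
#' dropped; a fraction with zero total variance yields `NA`.
#'
#' @param series Tibble with `time_min`, `nuclear`, `cytoplasmic`.
#' @param ss A [steady_state()] object.
#' @param rates A [kinetic_rates()] object.
#' @param scale `"log10"` or `"linear"`.
#' @return Named numeric vector `c(r2_nuclear, r2_cytoplasmic)`.
#' @export
goodness_of_fit <- function(series, ss, rates,
                            scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  check_columns(series, c("time_min", "nuclear", "cytoplasmic"), "series")
  r2_one <- function(obs, pred) {
    keep <- obs > 0 & pred > 0
    obs <- obs[keep]; pred <- pred[keep]
    if (scale == "log10") {
      obs <- log10(obs); pred <- log10(pred)
    }
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((obs - pred)^2) / ss_tot
  }
  c(r2_nuclear = r2_one(series$nuclear,
                        unlabeled_nuclear(series$time_min, ss, rates)),
    r2_cytoplasmic = r2_one(series$cytoplasmic,
                            unlabeled_cytoplasmic(series$time_min, ss, rates)))
}

#' @export
print.gene_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gene_fit> ", x$gene_id, " (rep ", x$replicate, "): FAILED - ",
        x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<gene_fit> %s (rep %s): kS = %.3g, kE = %.4g, kD = %.4g, kT = %.4g /min\n  r2(nuc) = %.3f, r2(cyt) = %.3f, retained = %s\n",
    x$gene_id, x$replicate, x$rates$k_s, x$rates$k_e, x$rates$k_d,
    x$rates$k_t, x$r2_nuclear, x$r2_cytoplasmic, x$retained))
  invisible(x)
}

#' @rdname fit_gene
#' @param x A `gene_fit` object.
#' @param ... Unused.
#' @export
tidy.gene_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("k_s", "k_e", "k_d", "k_t", "k_f", "k_f_prime"),
    estimate = c(x$rates$k_s, x$rates$k_e, x$rates$k_d, x$rates$k_t,
                 x$rates$k_f, x$rates$k_f_prime)
  )
}

#' @rdname fit_gene
#' @export
glance.gene_fit <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, replicate = x$replicate,
    k_s = if (x$converged) x$rates$k_s else NA_real_,
    k_e = if (x$converged) x$rates$k_e else NA_real_,
    k_d = if (x$converged) x$rates$k_d else NA_real_,
    k_t = if (x$converged) x$rates$k_t else NA_real_,
    n0 = if (!is.null(x$ss)) x$ss$n0 else NA_real_,
    c0 = if (!is.null(x$ss)) x$ss$c0 else NA_real_,
    theta = sum(x$theta),
    r2_nuclear = x$r2_nuclear, r2_cytoplasmic = x$r2_cytoplasmic,
    converged = x$converged, retained = x$retained,
    message = x$message
  )
}

#' Plot a fitted gene
#'
#' Measured unlabeled abundances and the fitted decay curves for both
#' fractions on a log10 axis.
#'
#' @param object A converged `gene_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_fit <- function(object, ...) {
  if (!object$converged) stop("cannot plot a non-converged fit")
  tt <- seq(0, max(object$series$time_min), length.out = 200)
  curves <- dplyr::bind_rows(
    tibble::tibble(time_min = tt, fraction = "nuclear",
                   abundance = unlabeled_nuclear(tt, object$ss, object$rates)),
    tibble::tibble(time_min = tt, fraction = "cytoplasmic",
                   abundance = unlabeled_cytoplasmic(tt, object$ss,
                                                     object$rates))
  )
  pts <- tidyr::pivot_longer(object$series, c("nuclear", "cytoplasmic"),
                             names_to = "fraction", values_to = "abundance")
  ggplot2::ggplot(pts, ggplot2::aes(.data$time_min, .data$abundance,
                                    colour = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "labeling time (min)",
                  y = "unlabeled abundance (spike-normalized FPKM)",
                  title = object$gene_id) +
    ggplot2::theme_minimal()
}

#' Retained gene set under the r-squared rule
#'
#' A gene is retained when its fit quality exceeds the threshold in both
#' fractions; under the default `"all"` rule this must hold in every
#' replicate.
#'
#' @param results Tibble with columns `gene_id`, `replicate`,
#'   `r2_nuclear`, `r2_cytoplasmic` (as produced by [fit_dataset()]).
#' @param threshold Retention threshold (default 0.8).
#' @param rule `"all"` (every replicate) or `"any"` (at least one).
#' @return Character vector of retained gene ids.
#' @export
filter_retained <- function(results, threshold = 0.8,
                            rule = c("all", "any")) {
  rule <- match.arg(rule)
  check_columns(results, c("gene_id", "r2_nuclear", "r2_cytoplasmic"),
                "results")
  per_gene <- results |>
    dplyr::mutate(pass = !is.na(.data$r2_nuclear) &
                    !is.na(.data$r2_cytoplasmic) &
                    .data$r2_nuclear > threshold &
                    .data$r2_cytoplasmic > threshold) |>
    dplyr::summarise(keep = if (rule == "all") all(.data$pass)
                     else any(.data$pass),
                     .by = "gene_id")
  per_gene$gene_id[per_gene$keep]
}

#' Fit the kinetic model to every gene and replicate in a dataset
#'
#' Runs [fit_gene()] per gene x replicate, collects the per-fit summaries
#' into one rates table, applies the retention rule, and summarizes
#' replicate concordance (Spearman correlation per rate across genes
#' converged in both replicates). Per-gene failures are recorded in the
#' table, not raised.
#'
#' @param data Long tibble with `gene_id`, `fraction` (values `"nuclear"`,
#'   `"cytoplasmic"`), `replicate`, `time_min` and the abundance column
#'   named by `value`.
#' @param ccp A [cell_cycle_params()] object.
#' @param noise A `noise_model` for the fitting weights.
#' @param config A [fit_config()] object.
#' @param value Abundance column (default `fpkm_spikenorm`).
#' @return A list of class `rate_fit_set`: `rates` (one row per gene x
#'   replicate), `retained` (gene ids), `concordance` (per-rate Spearman
#'   rho between replicates 1 and 2, when present).
#' @export
fit_dataset <- function(data, ccp, noise = constant_noise_model(),
                        config = fit_config(), value = "fpkm_spikenorm") {
  check_columns(data, c("gene_id", "fraction", "replicate", "time_min", value),
                "data")
  wide <- data |>
    dplyr::select("gene_id", "fraction", "replicate", "time_min",
                  dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "fraction",
                       values_from = dplyr::all_of(value))
  check_columns(wide, c("nuclear", "cytoplasmic"), "data (pivoted)")
  rates <- wide |>
    dplyr::group_by(.data$gene_id, .data$replicate) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      glance(fit_gene(
        dplyr::select(d, "time_min", "nuclear", "cytoplasmic"),
        ccp = ccp, noise = noise, config = config,
        gene_id = d$gene_id[1], replicate = d$replicate[1]))
    }) |>
    dplyr::bind_rows()
  retained <- filter_retained(rates, threshold = config$r2_threshold,
                              rule = config$retention_rule)
  rates$retained <- rates$gene_id %in% retained
  concordance <- replicate_concordance(rates)
  structure(list(rates = rates, retained = retained,
                 concordance = concordance, config = config),
            class = "rate_fit_set")
}

#' Replicate concordance of fitted rates
#'
#' @param rates Rates table with `gene_id`, `replicate` and rate columns
#'   `k_s`, `k_e`, `k_d`.
#' @return Tibble with one row per rate: Spearman rho between the first two
#'   replicates over genes converged in both.
#' @export
replicate_concordance <- function(rates) {
  check_columns(rates, c("gene_id", "replicate", "k_s", "k_e", "k_d"),
                "rates")
  reps <- sort(unique(rates$replicate))
  if (length(reps) < 2) {
    return(tibble::tibble(rate = c("k_s", "k_e", "k_d"), rho = NA_real_))
  }
  wide <- rates |>
    dplyr::filter(.data$replicate %in% reps[1:2]) |>
    dplyr::select("gene_id", "replicate", "k_s", "k_e", "k_d") |>
    tidyr::pivot_wider(names_from = "replicate",
                       values_from = c("k_s", "k_e", "k_d")) |>
    stats::na.omit()
  purrr::map_dfr(c("k_s", "k_e", "k_d"), function(r) {
    tibble::tibble(
      rate = r,
      rho = stats::cor(wide[[paste0(r, "_", reps[1])]],
                       wide[[paste0(r, "_", reps[2])]],
                       method = "spearman"),
      n = nrow(wide))
  })
}

#' @export
print.rate_fit_set <- function(x, ...) {
  cat(sprintf(
    "<rate_fit_set> %d fits (%d genes), %d converged, %d genes retained (r2 > %.2f)\n",
    nrow(x$rates), dplyr::n_distinct(x$rates$gene_id),
    sum(x$rates$converged), length(x$retained), x$config$r2_threshold))
  if (all(is.finite(x$concordance$rho))) {
    cat("  replicate concordance (Spearman): ",
        paste(sprintf("%s %.3f", x$concordance$rate, x$concordance$rho),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_dataset
#' @param x A `rate_fit_set`.
#' @param ... Unused.
#' @export
tidy.rate_fit_set <- function(x, ...) x$rates

#' @rdname fit_dataset
#' @export
glance.rate_fit_set <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x$rates),
    n_genes = dplyr::n_distinct(x$rates$gene_id),
    n_converged = sum(x$rates$converged),
    n_retained = length(x$retained),
    median_k_e = stats::median(x$rates$k_e[x$rates$retained], na.rm = TRUE),
    median_k_d = stats::median(x$rates$k_d[x$rates$retained], na.rm = TRUE)
  )
}

#' Replicate-averaged rate table for downstream analysis
#'
#' Collapses a fitted rates table to one row per retained gene, combining
#' replicates by geometric mean (rates are log-normally distributed across
#' genes) and averaging the steady-state abundances.
#'
#' @param fits A `rate_fit_set` from [fit_dataset()], or its `rates` tibble
#'   with a `retained` column.
#' @return Tibble `gene_id`, `k_s`, `k_e`, `k_d`, `k_t`, `n0`, `c0`, `w0`.
#' @export
rate_table <- function(fits) {
  rates <- if (inherits(fits, "rate_fit_set")) fits$rates else fits
  check_columns(rates, c("gene_id", "k_s", "k_e", "k_d", "k_t", "n0", "c0",
                         "retained"), "rates")
  gm <- function(x) exp(mean(log(x)))
  rates |>
    dplyr::filter(.data$retained, .data$converged, .data$k_s > 0) |>
    dplyr::summarise(dplyr::across(c("k_s", "k_e", "k_d", "k_t"), gm),
                     dplyr::across(c("n0", "c0"), mean),
                     .by = "gene_id") |>
    dplyr::mutate(w0 = .data$n0 + .data$c0)
}
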