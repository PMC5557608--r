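#' Fit the replicate-based mean-CV noise model
#'
#' RNA-seq abundances carry over-dispersed, mean-dependent technical noise.
#' For every gene x condition (fraction x time point) the mean `m` and the
#' coefficient of variation across replicates are computed, and CV is
#' regressed on `log10(m)` by local polynomial regression (loess). The
#' resulting evaluator `L(m)` supplies the per-point weights of the fitting
#' objective. Evaluation is clamped to the fitted mean range and floored at
#' zero, so extrapolation cannot blow up.
#'
#' @param data Long tibble with `gene_id`, `fraction`, `replicate`,
#'   `time_min` and the abundance column named by `value`.
#' @param value Abundance column to use (default `fpkm_spikenorm`).
#' @param span Loess span (default 0.5).
#' @param min_points Minimum number of usable (mean, CV) points (default 100).
#' @return An object of class `noise_model`.
#' @export
fit_noise_model <- function(data, value = "fpkm_spikenorm", span = 0.5,
                            min_points = 100) {
  check_columns(data, c("gene_id", "fraction", "replicate", "time_min", value),
                "data")
  # c4 unbiasing of the sd: with few replicates E[sd] = sigma * c4(n),
  # e.g. c4(2) = sqrt(2/pi) ~ 0.80, which would deflate every CV by 20%.
  c4 <- function(n) sqrt(2 / (n - 1)) * exp(lgamma(n / 2) -
                                              lgamma((n - 1) / 2))
  pts <- data |>
    dplyr::summarise(
      m = mean(.data[[value]]),
      cv = stats::sd(.data[[value]]) / mean(.data[[value]]),
      n_rep = dplyr::n(),
      .by = c("gene_id", "fraction", "time_min")
    ) |>
    dplyr::filter(.data$n_rep >= 2, .data$m > 0, is.finite(.data$cv)) |>
    dplyr::mutate(cv = .data$cv / c4(.data$n_rep))
  if (nrow(pts) < min_points) {
    stop("only ", nrow(pts), " usable (mean, CV) points; need >= ", min_points)
  }
  pts <- dplyr::mutate(pts, log10_m = log10(.data$m))
  lo <- stats::loess(cv ~ log10_m, data = pts, span = span,
                     degree = 2, family = "gaussian")
  rng <- range(pts$log10_m)
  knots <- tibble::tibble(log10_m = seq(rng[1], rng[2], length.out = 200))
  knots$m <- 10^knots$log10_m
  knots$cv <- pmax(stats::predict(lo, newdata = knots), 0)
  structure(
    list(fit = lo, m_range = 10^rng, span = span, knots = knots,
         points = pts),
    class = "noise_model"
  )
}

#' Constant-CV noise model
#'
#' A degenerate [fit_noise_model()] object whose evaluator returns `cv`
#' for every mean. Useful as a default weight model and in simulations.
#'
#' @param cv Coefficient of variation (>= 0).
#' @return An object of class `noise_model`.
#' @export
constant_noise_model <- function(cv = 0.2) {
  stopifnot(cv >= 0)
  structure(
    list(fit = NULL, m_range = c(0, Inf), span = NA_real_,
         knots = tibble::tibble(log10_m = numeric(), m = numeric(),
                                cv = numeric()),
         constant = cv),
    class = "noise_model"
  )
}

#' Evaluate a noise model
#'
#' @param object A `noise_model`.
#' @param m Mean abundances at which to evaluate the CV mapping; values
#'   outside the fitted range are clamped to the range endpoints.
#' @param ... Unused.
#' @return Non-negative CV estimates.
#' @export
predict.noise_model <- function(object, m, ...) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, length(m)))
  }
  x <- log10(pmin(pmax(m, object$m_range[1]), object$m_range[2]))
  unname(pmax(stats::predict(object$fit,
                             newdata = data.frame(log10_m = x)), 0))
}

#' @export
print.noise_model <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<noise_model> constant CV = %.3g\n", x$constant))
  } else {
    cat(sprintf("<noise_model> loess CV ~ log10(mean), span %.2f, %d points, mean range [%.3g, %.3g]\n",
                x$span, nrow(x$points), x$m_range[1], x$m_range[2]))
  }
  invisible(x)
}

#' Plot a fitted noise model
#'
#' Per-condition (mean, CV) points with the fitted loess mapping.
#'
#' @param object A `noise_model` fitted from data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_model <- function(object, ...) {
  if (is.null(object$fit)) stop("constant noise models have nothing to plot")
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$log10_m, .data$cv)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_line(data = object$knots, colour = "red") +
    ggplot2::labs(x = "log10 mean abundance", y = "CV across replicates") +
    ggplot2::theme_minimal()
}

#' Serialize a noise model to a knot table
#'
#' @param model A `noise_model`.
#' @return Tibble of `(m, cv)` knots representing the fitted mapping.
#' @export
noise_model_knots <- function(model) {
  stopifnot(inherits(model, "noise_model"))
  if (!is.null(model$constant)) {
    return(tibble::tibble(m = c(0, Inf), cv = model$constant))
  }
  dplyr::select(model$knots, "m", "cv")
}

#' Abundance of newly synthesized (labeled) RNA over time
#'
#' With the total pool growing as `W0 exp(g t)` and pre-existing RNA
#' decaying as `W0 exp(-kT t)`, the labeled complement is
#' `W4sU(t) = W0 (exp(g t) - exp(-kT t))`.
#'
#' @param t Time in minutes (vectorized).
#' @param w0 Total abundance at t = 0.
#' @param g Proliferation rate (min^-1).
#' @param k_t Overall turnover rate (min^-1).
#' @return Labeled abundance at `t`.
#' @export
new_rna_model <- function(t, w0, g, k_t) {
  stopifnot(all(t >= 0))
  w0 * (exp(g * t) - exp(-k_t * t))
}

#' Expected measured "unlabeled" abundance with carry-over
#'
#' Incomplete streptavidin depletion leaves a fraction `U` of labeled RNA in
#' the unlabeled pool, so the measured series plateaus instead of decaying
#' to zero: `W(t) = W0 exp(-kT t) + U * W0 (exp(g t) - exp(-kT t))`. As
#' `t` grows, `W(t) / (W0 exp(g t))` approaches `U`.
#'
#' @inheritParams new_rna_model
#' @param u Carry-over fraction in `[0, 1]`.
#' @return Expected measured unlabeled abundance at `t`.
#' @export
measured_unlabeled_model <- function(t, w0, g, k_t, u) {
  stopifnot(all(u >= 0), all(u <= 1))
  unlabeled_total(t, w0, k_t) + u * new_rna_model(t, w0, g, k_t)
}

#' Estimate the global streptavidin carry-over fraction
#'
#' Fits `W(t) = W0 exp(-kT t) + U W0 (exp(g t) - exp(-kT t))` to a bulk
#' (summed over genes) unlabeled time series by Levenberg-Marquardt,
#' minimizing `d = (1/n) sum_i (L(Wm(t_i)) * log(Wm(t_i) / W(t_i)))^2`
#' over `(U, kT)` with `U` constrained to `[0, 1]`. `W0` is pinned to the
#' measurement at t = 0.
#'
#' @param bulk Tibble with columns `time_min` and `abundance` (one bulk
#'   series; >= 4 time points including t = 0).
#' @param g Proliferation rate (min^-1).
#' @param noise A [fit_noise_model()] (or [constant_noise_model()]) object
#'   supplying the weights `L`.
#' @param weighting `"as_printed"` multiplies the log-ratio by `L(Wm)`;
#'   `"inverse"` divides by it (the conventional inverse-variance choice).
#' @return An object of class `contamination_model` with elements `u`,
#'   `k_t_bulk`, `d` (the achieved loss), `w0` and the optimizer `info`.
#' @export
estimate_contamination <- function(bulk, g, noise,
                                   weighting = c("as_printed", "inverse")) {
  weighting <- match.arg(weighting)
  check_columns(bulk, c("time_min", "abundance"), "bulk")
  stopifnot(inherits(noise, "noise_model"))
  bulk <- dplyr::arrange(bulk, .data$time_min)
  if (nrow(bulk) < 4) stop("need >= 4 time points to estimate carry-over")
  if (bulk$time_min[1] != 0) stop("bulk series must include time_min == 0")
  w0 <- bulk$abundance[1]
  if (w0 <= 0) stop("bulk abundance at t = 0 must be positive")
  keep <- bulk$abundance > 0
  tt <- bulk$time_min[keep]
  wm <- bulk$abundance[keep]
  lw <- predict(noise, wm)
  wts <- if (weighting == "as_printed") lw else 1 / pmax(lw, 1e-8)
  n <- length(tt)
  # crude initial turnover from the early log-slope
  early <- tt <= stats::median(tt)
  k0 <- max(1e-5, -stats::coef(stats::lm(log(wm[early]) ~ tt[early]))[[2]])
  resid_fn <- function(par) {
    w_model <- measured_unlabeled_model(tt, w0, g, par[["k_t"]], par[["u"]])
    wts * log(wm / w_model) / sqrt(n)
  }
  fit <- minpack.lm::nls.lm(
    par = c(u = 0.05, k_t = k0), fn = resid_fn,
    lower = c(0, 1e-7), upper = c(1, 1),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!fit$info %in% 1:4) {
    stop("carry-over fit did not converge (nls.lm info = ", fit$info,
         ": ", fit$message, ")")
  }
  structure(
    list(u = unname(fit$par[["u"]]), k_t_bulk = unname(fit$par[["k_t"]]),
         d = sum(fit$fvec^2), w0 = w0, weighting = weighting, info = fit$info),
    class = "contamination_model"
  )
}

#' @export
print.contamination_model <- function(x, ...) {
  cat(sprintf(
    "<contamination_model> U = %.2f%%  kT(bulk) = %.4g /min  loss d = %.3g\n",
    100 * x$u, x$k_t_bulk, x$d))
  invisible(x)
}
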