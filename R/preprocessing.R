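#' Spike-in normalization of abundance tables
#'
#' Each sample received a fixed amount of foreign (yeast) RNA, so the ratio
#' of host-mapped to spike-mapped reads converts FPKM into a relative
#' abundance comparable across time points and fractions: per sample,
#' `factor = host_mapped_reads / spike_mapped_reads` and
#' `fpkm_spikenorm = fpkm * factor`.
#'
#' @param abundance Long tibble with columns `gene_id`, `fraction`,
#'   `replicate`, `time_min`, `fpkm`.
#' @param mapped_reads One row per sample: `fraction`, `replicate`,
#'   `time_min`, `host_mapped_reads`, `spike_mapped_reads` (spike reads must
#'   be positive).
#' @return The input tibble with columns `norm_factor` and `fpkm_spikenorm`
#'   added.
#' @export
spike_normalize <- function(abundance, mapped_reads) {
  req <- c("fraction", "replicate", "time_min")
  check_columns(abundance, c("gene_id", req, "fpkm"), "abundance")
  check_columns(mapped_reads, c(req, "host_mapped_reads", "spike_mapped_reads"),
                "mapped_reads")
  bad <- dplyr::filter(mapped_reads, .data$spike_mapped_reads <= 0)
  if (nrow(bad) > 0) {
    stop("zero spike-in reads in sample(s): ",
         paste(bad$fraction, bad$replicate, bad$time_min, sep = "/",
               collapse = ", "))
  }
  mapped_reads |>
    dplyr::mutate(norm_factor = .data$host_mapped_reads /
                    .data$spike_mapped_reads) |>
    dplyr::select(dplyr::all_of(req), "norm_factor") |>
    dplyr::right_join(abundance, by = req) |>
    dplyr::mutate(fpkm_spikenorm = .data$fpkm * .data$norm_factor) |>
    dplyr::relocate("gene_id") |>
    tibble::as_tibble()
}

#' Fit the abundance-dependent dispersion cutoff
#'
#' When two transcriptomes are compared on a log10 scale (e.g. with and
#' without 4sU, or unfractionated total versus the nuclear + cytoplasmic
#' sum), technical dispersion around the diagonal shrinks with abundance.
#' The dispersion profile is summarized by `f(x) = m + n * exp(-p * x)`:
#' the x axis is divided into `n_bins` equal-width intervals, the standard
#' deviation of `y` is computed per interval, and the non-negative
#' parameters `(m, n, p)` are fitted by Levenberg-Marquardt least squares.
#'
#' @param data Data frame holding the two log10 abundance columns.
#' @param x,y Column names (tidy-eval) of the two transcriptomes being
#'   compared, on log10 scale.
#' @param n_bins Number of equal-width intervals along `x`.
#' @param min_bin_n Bins with fewer points than this are dropped.
#' @return An object of class `cutoff_model` with elements `m`, `n`, `p`,
#'   the per-bin summary `bins`, and the underlying `nls` fit.
#' @examples
#' d <- tibble::tibble(x = runif(2000, 0, 4))
#' d$y <- d$x + rnorm(2000, sd = 0.1 + 0.5 * exp(-d$x))
#' fit_cutoff_model(d, x, y, n_bins = 50)
#' @export
fit_cutoff_model <- function(data, x, y, n_bins = 1000, min_bin_n = 5) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 finite (x, y) pairs")
  breaks <- seq(min(xv), max(xv), length.out = n_bins + 1)
  bin <- cut(xv, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bins <- tibble::tibble(bin = bin, x = xv, y = yv) |>
    dplyr::summarise(mid = mean(.data$x), sd_y = stats::sd(.data$y),
                     n = dplyr::n(), .by = "bin") |>
    dplyr::filter(.data$n >= min_bin_n, is.finite(.data$sd_y)) |>
    dplyr::arrange(.data$mid)
  if (nrow(bins) < 3) {
    stop("fewer than 3 usable bins (", nrow(bins),
         "); decrease `n_bins` or supply more data")
  }
  m0 <- max(min(bins$sd_y), 1e-4)
  n0 <- max(max(bins$sd_y) - m0, 1e-4)
  fits <- list()
  for (p0 in c(0.3, 1, 3)) {
    f <- try(minpack.lm::nlsLM(
      sd_y ~ m + n * exp(-p * mid), data = bins,
      start = list(m = m0, n = n0, p = p0),
      lower = c(0, 0, 0), control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
  }
  if (length(fits) == 0) stop("cutoff model fit did not converge")
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  cf <- stats::coef(fit)
  structure(
    list(m = unname(cf["m"]), n = unname(cf["n"]), p = unname(cf["p"]),
         bins = bins, fit = fit),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf(
    "<cutoff_model> f(x) = %.4g + %.4g * exp(-%.4g x)  [%d bins]\n",
    x$m, x$n, x$p, nrow(x$bins)))
  invisible(x)
}

#' Evaluate a fitted dispersion cutoff
#'
#' @param object A `cutoff_model`.
#' @param x Log10 abundances at which to evaluate `f(x) = m + n exp(-p x)`.
#' @param ... Unused.
#' @return Dispersion estimates, same length as `x`.
#' @export
predict.cutoff_model <- function(object, x, ...) {
  object$m + object$n * exp(-object$p * x)
}

#' Plot a fitted dispersion cutoff
#'
#' Per-bin dispersion estimates with the fitted `f(x) = m + n exp(-p x)`.
#'
#' @param object A `cutoff_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutoff_model <- function(object, ...) {
  grid <- tibble::tibble(
    mid = seq(min(object$bins$mid), max(object$bins$mid), length.out = 200))
  grid$sd_y <- predict(object, grid$mid)
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$mid, .data$sd_y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "log10 abundance (bin center)",
                  y = "dispersion sd") +
    ggplot2::theme_minimal()
}

#' Flag genes exceeding twice the technical dispersion
#'
#' A gene is an outlier in an (x, y) transcriptome comparison if it lies
#' more than twice the local dispersion away from the diagonal in either
#' direction: `y > x + 2 f(x)` or `x > y + 2 f(y)`.
#'
#' @inheritParams fit_cutoff_model
#' @param model A fitted [fit_cutoff_model()] object.
#' @return The input data with a logical `outlier` column added.
#' @export
flag_outliers <- function(data, x, y, model) {
  stopifnot(inherits(model, "cutoff_model"))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  out <- yv > xv + 2 * predict(model, xv) | xv > yv + 2 * predict(model, yv)
  dplyr::mutate(data, outlier = out)
}

#' Probability that a new transcript carries at least one 4sU
#'
#' With a per-uridine labeling probability `pr`, a transcript with `nu`
#' uridines escapes labeling with probability `(1 - pr)^nu`, so its capture
#' probability is `F = 1 - (1 - pr)^nu`, computed via `expm1`/`log1p` for
#' numerical stability at large `nu`.
#'
#' @param nu Integer uridine count per transcript (vectorized).
#' @param pr Per-uridine labeling probability, default 0.01.
#' @return Capture probabilities in `[0, 1]`.
#' @examples
#' capture_probability(69)   # ~0.5 at the default pr = 0.01
#' @export
capture_probability <- function(nu, pr = 0.01) {
  stopifnot(all(nu >= 0), all(pr >= 0), all(pr <= 1))
  n <- max(length(nu), length(pr))
  nu <- rep_len(nu, n)
  pr <- rep_len(pr, n)
  out <- -expm1(nu * log1p(-pr))
  # log1p(-1) is -Inf, and 0 * -Inf must still give F = 0 at nu = 0
  out[pr >= 1] <- as.numeric(nu[pr >= 1] > 0)
  out
}

#' Correct measured unlabeled abundances for labeling escape
#'
#' A fraction `1 - F` of newly synthesized transcripts carries no 4sU and
#' contaminates the "unlabeled" pool. Under quasi-steady state each
#' compartment pool grows as `X0 * exp(g t)`, so the measurement decomposes
#' as `Xm(t) = F * Xp(t) + (1 - F) * X0 * exp(g t)` and inverts exactly to
#' `Xp(t) = (Xm(t) - (1 - F) * X0 * exp(g t)) / F`. Genes with capture
#' probability at or below `f_min` are excluded rather than corrected
#' (the `1/F` variance amplification becomes extreme); negative corrected
#' values are clamped to zero and counted.
#'
#' The same inversion absorbs a global streptavidin carry-over fraction `U`
#' by passing the effective capture probability `F * (1 - U)` (see the
#' methods vignette).
#'
#' @param series Long tibble with `gene_id`, `fraction`, `replicate`,
#'   `time_min` and an abundance column named by `value`; must contain
#'   `time_min == 0` for every (gene, fraction, replicate).
#' @param capture Per-gene tibble `gene_id`, `f` (capture probability).
#' @param g Proliferation rate in min^-1.
#' @param value Name of the abundance column to correct (default
#'   `fpkm_spikenorm`).
#' @param f_min Genes with `f <= f_min` are excluded (default 0.2).
#' @return A list with `corrected` (same shape as `series`, abundances
#'   replaced), `excluded` (tibble `gene_id`, `reason`), and `n_clamped`,
#'   the number of negative corrected values clamped to zero.
#' @export
correct_labeling_bias <- function(series, capture, g, value = "fpkm_spikenorm",
                                  f_min = 0.2) {
  check_columns(series, c("gene_id", "fraction", "replicate", "time_min", value),
                "series")
  check_columns(capture, c("gene_id", "f"), "capture")
  excluded <- capture |>
    dplyr::filter(.data$f <= f_min) |>
    dplyr::transmute(gene_id = .data$gene_id, reason = "uncorrectable-bias")
  keep <- dplyr::semi_join(series,
                           dplyr::filter(capture, .data$f > f_min),
                           by = "gene_id")
  base <- keep |>
    dplyr::filter(.data$time_min == 0) |>
    dplyr::select("gene_id", "fraction", "replicate", x0 = dplyr::all_of(value))
  if (nrow(dplyr::anti_join(
    dplyr::distinct(keep, .data$gene_id, .data$fraction, .data$replicate),
    base, by = c("gene_id", "fraction", "replicate"))) > 0) {
    stop("every (gene, fraction, replicate) series needs a time_min == 0 row")
  }
  corrected <- keep |>
    dplyr::left_join(base, by = c("gene_id", "fraction", "replicate")) |>
    dplyr::left_join(dplyr::select(capture, "gene_id", "f"), by = "gene_id") |>
    dplyr::mutate(.corr = (.data[[value]] -
                             (1 - .data$f) * .data$x0 * exp(g * .data$time_min)) /
                    .data$f)
  n_clamped <- sum(corrected$.corr < 0)
  corrected[[value]] <- pmax(corrected$.corr, 0)
  corrected <- dplyr::select(corrected, -".corr", -"x0", -"f")
  if (n_clamped > 0) {
    warning(n_clamped, " corrected abundance value(s) clamped to zero")
  }
  list(corrected = tibble::as_tibble(corrected), excluded = excluded,
       n_clamped = n_clamped)
}
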