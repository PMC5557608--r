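#' Read a schema-checked TSV table
#'
#' Thin wrapper around [readr::read_tsv()] that validates the declared
#' header and numeric columns, naming the offending column and line in its
#' errors. All package tables are TSV: UTF-8, `.` decimal, no thousands
#' separators.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers.
#' @return A tibble.
#' @export
read_tsv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(x))) {
    if (!is.numeric(x[[col]])) {
      as_num <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(is.na(as_num) & !is.na(x[[col]]))
      if (length(bad) > 0) {
        stop("schema error in ", path, ": column `", col,
             "` is not numeric (first bad data line: ", bad[1], ")")
      }
      x[[col]] <- as_num
    }
  }
  x
}

#' Abundance-table I/O
#'
#' The canonical long abundance dialect: `gene_id`, `fraction`,
#' `replicate`, `time_min`, `fpkm`, `fpkm_spikenorm`.
#'
#' @param path File path.
#' @return `read_abundance_table()` returns the validated tibble;
#'   `write_abundance_table()` returns `path` invisibly.
#' @export
read_abundance_table <- function(path) {
  read_tsv_checked(
    path,
    required = c("gene_id", "fraction", "replicate", "time_min", "fpkm",
                 "fpkm_spikenorm"),
    numeric_cols = c("replicate", "time_min", "fpkm", "fpkm_spikenorm"))
}

#' @rdname read_abundance_table
#' @param x Abundance tibble to write.
#' @export
write_abundance_table <- function(x, path) {
  check_columns(x, c("gene_id", "fraction", "replicate", "time_min", "fpkm",
                     "fpkm_spikenorm"), "x")
  readr::write_tsv(x[, c("gene_id", "fraction", "replicate", "time_min",
                         "fpkm", "fpkm_spikenorm")], path)
  invisible(path)
}

# External (supplementary-style) column names of the rates table.
.rates_export_names <- c(
  k_s = "transcription_rate_fpkm_per_min", k_e = "export_rate_per_min",
  k_d = "decay_rate_per_min", k_t = "turnover_rate_per_min")

#' Rates-table I/O in the supplementary-table dialect
#'
#' One row per gene x replicate with descriptive column names
#' (`transcription_rate_fpkm_per_min`, `export_rate_per_min`,
#' `decay_rate_per_min`, `turnover_rate_per_min`, per-fraction r-squared
#' and the retained flag). Internally the compact `k_s`/`k_e`/`k_d`/`k_t`
#' names are used; the readers/writers translate.
#'
#' @param path File path.
#' @return `read_rates_table()` returns a tibble with internal column
#'   names; `write_rates_table()` returns `path` invisibly.
#' @export
read_rates_table <- function(path) {
  x <- read_tsv_checked(
    path,
    required = c("gene_id", "replicate", unname(.rates_export_names),
                 "r2_nuclear", "r2_cytoplasmic", "retained"),
    numeric_cols = c("replicate", unname(.rates_export_names),
                     "r2_nuclear", "r2_cytoplasmic"))
  for (i in seq_along(.rates_export_names)) {
    names(x)[names(x) == .rates_export_names[i]] <-
      names(.rates_export_names)[i]
  }
  x$retained <- as.logical(x$retained)
  x
}

#' @rdname read_rates_table
#' @param x Rates tibble (internal names) to write.
#' @export
write_rates_table <- function(x, path) {
  check_columns(x, c("gene_id", "replicate", names(.rates_export_names),
                     "r2_nuclear", "r2_cytoplasmic", "retained"), "x")
  out <- x[, c("gene_id", "replicate", names(.rates_export_names),
               "r2_nuclear", "r2_cytoplasmic", "retained")]
  names(out)[match(names(.rates_export_names), names(out))] <-
    unname(.rates_export_names)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Summarize a deposited-style rates table
#'
#' Computes the headline statistics of a per-gene rates table: median
#' export and decay rates (in percent per minute), the corresponding
#' half-lives in hours, and the number of genes retained at the r-squared
#' threshold (both fractions, every replicate).
#'
#' @param rates A rates tibble as returned by [read_rates_table()] or
#'   [fit_dataset()]`$rates`.
#' @param r2_threshold Retention threshold (default 0.8).
#' @return One-row tibble with `median_export_pct_per_min`,
#'   `median_decay_pct_per_min`, `export_half_life_h`, `decay_half_life_h`,
#'   `n_retained`.
#' @export
summarize_rate_table <- function(rates, r2_threshold = 0.8) {
  check_columns(rates, c("gene_id", "k_e", "k_d", "r2_nuclear",
                         "r2_cytoplasmic"), "rates")
  retained_ids <- filter_retained(rates, threshold = r2_threshold)
  kept <- dplyr::filter(rates, .data$gene_id %in% .env$retained_ids)
  med_ke <- stats::median(kept$k_e, na.rm = TRUE)
  med_kd <- stats::median(kept$k_d, na.rm = TRUE)
  tibble::tibble(
    median_export_pct_per_min = 100 * med_ke,
    median_decay_pct_per_min = 100 * med_kd,
    export_half_life_h = half_life(med_ke),
    decay_half_life_h = half_life(med_kd),
    n_retained = length(retained_ids)
  )
}

#' Pipeline configuration
#'
#' @param sim A [simulation_config()] describing the synthetic experiment
#'   to generate when no input is supplied.
#' @param fit A [fit_config()].
#' @param f_min Minimum capture probability below which genes are excluded
#'   instead of bias-corrected.
#' @param contamination_correction If `TRUE` (default) the globally
#'   estimated carry-over `U` is folded into the bias correction via the
#'   effective capture probability `F (1 - U)`.
#' @param cutoff_bins Bin count for the outlier-screen dispersion fit;
#'   `NULL` scales it with the gene count (about 10 genes per bin, capped
#'   at 1000).
#' @param noise_span Loess span of the noise model.
#' @param top_fraction,alpha Association-analysis settings.
#' @param associations Run the association stage (default `TRUE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            fit = fit_config(),
                            f_min = 0.2,
                            contamination_correction = TRUE,
                            cutoff_bins = NULL,
                            noise_span = 0.5,
                            top_fraction = 0.7,
                            alpha = 0.01,
                            associations = TRUE) {
  stopifnot(inherits(sim, "sim_config"), inherits(fit, "fit_config"))
  structure(
    list(sim = sim, fit = fit, f_min = f_min,
         contamination_correction = isTRUE(contamination_correction),
         cutoff_bins = cutoff_bins, noise_span = noise_span,
         top_fraction = top_fraction, alpha = alpha,
         associations = isTRUE(associations)),
    class = "pipeline_config"
  )
}

#' Run the full inference pipeline
#'
#' Orchestrates `simulate -> preprocess -> fit -> associate -> report`:
#' generates (or accepts) an experiment, excludes outlier genes from the
#' labeling-effect and fractionation screens, fits the mean-CV noise
#' model, estimates the global carry-over fraction from the bulk series,
#' applies the labeling-bias correction, fits the kinetic model per gene
#' and replicate, applies the retention rule, and (optionally) runs the
#' association analyses. Every exclusion is reason-coded and the report's
#' gene counts are non-increasing along the filter chain.
#'
#' @param config A [pipeline_config()].
#' @param experiment Optional [simulate_experiment()]-shaped input; when
#'   `NULL` a synthetic experiment is generated from `config$sim`.
#' @return An object of class `pipeline_run` with elements `report` (gene
#'   counts, carry-over estimate, concordance, variance shares),
#'   `exclusions`, `noise`, `contamination`, `fits`, `rates` (replicate-
#'   averaged rate table), `associations` and `experiment`.
#' @export
run_pipeline <- function(config = pipeline_config(), experiment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(experiment)) {
    truth <- sample_gene_parameters(config$sim)
    experiment <- simulate_experiment(truth, config$sim)
  }
  meas <- experiment$measurements
  n_detected <- dplyr::n_distinct(meas$gene_id)
  bins <- config$cutoff_bins %||%
    max(10, min(1000, floor(n_detected / 10)))
  screen <- function(cmp, reason) {
    model <- fit_cutoff_model(cmp, x, y, n_bins = bins)
    flagged <- flag_outliers(cmp, x, y, model)
    list(model = model,
         excluded = tibble::tibble(
           gene_id = flagged$gene_id[flagged$outlier], reason = reason))
  }
  lab <- screen(experiment$labeling_comparison, "4su-affected")
  frac <- screen(experiment$fractionation_comparison,
                 "fractionation-inconsistent")
  excl <- dplyr::bind_rows(lab$excluded, frac$excluded)
  meas <- dplyr::filter(meas, !.data$gene_id %in% excl$gene_id)
  n_after_labeling <- n_detected - dplyr::n_distinct(lab$excluded$gene_id)
  n_after_screens <- dplyr::n_distinct(meas$gene_id)
  noise <- fit_noise_model(meas, span = config$noise_span)
  g <- config$sim$ccp$g
  # Pass 1: invert the per-gene labeling escape. The F-corrected series of
  # every gene then follows the global carry-over model
  # X(t) = (1 - U) Xp(t) + U X0 e^{g t} regardless of its F, so the summed
  # corrected series is the right input for the carry-over fit.
  capture <- experiment$truth |>
    dplyr::transmute(.data$gene_id,
                     f = capture_probability(.data$nu, config$sim$pr))
  bc <- correct_labeling_bias(meas, capture, g = g, f_min = config$f_min)
  excl <- dplyr::bind_rows(excl, bc$excluded)
  corrected <- bc$corrected
  bulk_corr <- corrected |>
    dplyr::summarise(abundance = sum(.data$fpkm_spikenorm),
                     .by = c("replicate", "time_min")) |>
    dplyr::summarise(abundance = mean(.data$abundance), .by = "time_min")
  contamination <- estimate_contamination(bulk_corr, g, noise,
                                          weighting = config$fit$weighting)
  # Pass 2: remove the globally estimated carry-over, formally another
  # escape inversion with capture probability 1 - U.
  if (config$contamination_correction && contamination$u > 0) {
    ones <- tibble::tibble(gene_id = unique(corrected$gene_id),
                           f = 1 - contamination$u)
    corrected <- correct_labeling_bias(corrected, ones, g = g,
                                       f_min = 0)$corrected
  }
  bc <- list(corrected = corrected)
  n_after_bias <- dplyr::n_distinct(bc$corrected$gene_id)
  fits <- fit_dataset(bc$corrected, ccp = config$sim$ccp, noise = noise,
                      config = config$fit)
  n_fitted <- dplyr::n_distinct(fits$rates$gene_id[fits$rates$converged])
  rates <- rate_table(fits)
  report <- list(
    counts = c(detected = n_detected,
               after_labeling_screen = n_after_labeling,
               after_fractionation_screen = n_after_screens,
               after_bias_correction = n_after_bias,
               fitted = n_fitted,
               retained = length(fits$retained)),
    u = contamination$u,
    concordance = fits$concordance,
    variance_shares = if (nrow(rates) >= 10) {
      variance_contributions(rates, config$sim$ccp$g)
    } else NULL
  )
  associations <- NULL
  if (config$associations && nrow(rates) >= 20 &&
      inherits(experiment$truth, "ground_truth")) {
    ann <- generate_feature_annotations(experiment$truth, config$sim)
    associations <- list(
      feature_correlations = rate_feature_correlation(rates, ann$features),
      group_comparisons = group_rate_comparison(
        rates, ann$labels, top_fraction = config$top_fraction,
        alpha = config$alpha),
      tss_states = try(chromatin_state_comparison(
        rates, dplyr::rename(ann$states, state = "tss_state"),
        alpha = config$alpha), silent = TRUE)
    )
  }
  structure(
    list(report = report, exclusions = excl, noise = noise,
         contamination = contamination, fits = fits, rates = rates,
         associations = associations, experiment = experiment,
         config = config),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n  gene counts along the filter chain:\n")
  for (nm in names(x$report$counts)) {
    cat(sprintf("    %-28s %d\n", nm, x$report$counts[[nm]]))
  }
  cat(sprintf("  carry-over U = %.2f%%\n", 100 * x$report$u))
  if (!is.null(x$report$variance_shares)) {
    vs <- x$report$variance_shares
    cat("  variance shares: ",
        paste(sprintf("%s %.1f%%", vs$component, 100 * vs$share),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
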