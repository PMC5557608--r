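#' Variance decomposition of steady-state abundance
#'
#' In the no-mitosis closed form the steady-state cytoplasmic abundance
#' factorizes as `log C0 = log kS + log(kE / (kE + g)) - log(kD + g)`, an
#' exact additive decomposition into a transcription, an export and a decay
#' term. The share of each process in the genome-wide variance of steady-
#' state abundance is its covariance share,
#' `share_j = cov(log C0, term_j) / var(log C0)`; the shares sum to one by
#' construction.
#'
#' @param rates Rate table with columns `k_s`, `k_e`, `k_d` (one row per
#'   gene, >= 10 genes, positive rates).
#' @param g Proliferation rate (min^-1).
#' @return Tibble with `component` (`transcription`, `export`, `decay`) and
#'   `share`.
#' @export
variance_contributions <- function(rates, g) {
  check_columns(rates, c("k_s", "k_e", "k_d"), "rates")
  rates <- dplyr::filter(rates, .data$k_s > 0, .data$k_e > 0, .data$k_d > 0)
  if (nrow(rates) < 10) stop("need >= 10 genes with positive rates")
  terms <- cbind(
    transcription = log(rates$k_s),
    export = log(rates$k_e / (rates$k_e + g)),
    decay = -log(rates$k_d + g)
  )
  log_c0 <- rowSums(terms)
  v <- stats::var(log_c0)
  if (v == 0) stop("zero variance of log steady-state abundance")
  shares <- apply(terms, 2, function(term) stats::cov(log_c0, term) / v)
  tibble::tibble(component = names(shares), share = unname(shares))
}

#' Rank correlations between kinetic rates and transcript features
#'
#' For every (rate, feature) pair: Spearman correlation with a two-sided
#' p-value, plus the slope of a linear regression in log10-log10 space
#' (computed over genes where both quantities are positive). Constant
#' features produce an `NA` row with a reason.
#'
#' @param rates Rate table with `gene_id` and the columns named in
#'   `rate_cols`.
#' @param features Feature table with `gene_id` and numeric feature
#'   columns.
#' @param rate_cols Rate columns to correlate (default kS, kE, kD).
#' @return Tibble `rate`, `feature`, `rho`, `p_value`, `log_log_slope`,
#'   `n`, `note`.
#' @export
rate_feature_correlation <- function(rates, features,
                                     rate_cols = c("k_s", "k_e", "k_d")) {
  check_columns(rates, c("gene_id", rate_cols), "rates")
  check_columns(features, "gene_id", "features")
  feat_cols <- setdiff(names(features), "gene_id")
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(rates), "gene_id",
                  dplyr::all_of(rate_cols)),
    dplyr::select(tibble::as_tibble(features), "gene_id",
                  dplyr::all_of(feat_cols)),
    by = "gene_id")
  grid <- tidyr::expand_grid(rate = rate_cols, feature = feat_cols)
  purrr::pmap_dfr(grid, function(rate, feature) {
    d <- tibble::tibble(r = joined[[rate]], f = joined[[feature]]) |>
      dplyr::filter(is.finite(.data$r), is.finite(.data$f))
    if (nrow(d) < 10) {
      return(tibble::tibble(rate = rate, feature = feature, rho = NA_real_,
                            p_value = NA_real_, log_log_slope = NA_real_,
                            n = nrow(d), note = "fewer than 10 pairs"))
    }
    if (stats::sd(d$f) == 0) {
      return(tibble::tibble(rate = rate, feature = feature, rho = NA_real_,
                            p_value = NA_real_, log_log_slope = NA_real_,
                            n = nrow(d), note = "constant feature"))
    }
    ct <- suppressWarnings(
      stats::cor.test(d$r, d$f, method = "spearman", exact = FALSE))
    pos <- d$r > 0 & d$f > 0
    slope <- if (sum(pos) >= 10) {
      stats::coef(stats::lm(log10(r) ~ log10(f), data = d[pos, ]))[[2]]
    } else NA_real_
    tibble::tibble(rate = rate, feature = feature,
                   rho = unname(ct$estimate), p_value = ct$p.value,
                   log_log_slope = slope, n = nrow(d), note = NA_character_)
  })
}

#' Compare kinetic rates between bound and unbound gene sets
#'
#' For each label set (e.g. the targets of one RNA-binding protein) and
#' each rate: the log2 ratio of the bound-group median to the unbound-group
#' median, with a two-sided Wilcoxon rank-sum p-value (normal approximation
#' with tie correction), Holm-Bonferroni adjusted across label sets within
#' each rate. The analysis is restricted to the `top_fraction` highest-
#' expressed genes because binding calls are unreliable for weakly
#' expressed transcripts.
#'
#' @param rates Rate table with `gene_id`, the columns in `rate_cols`, and
#'   the expression column named by `expression`.
#' @param labels Tibble `gene_id`, `label` (label-set name), `bound`
#'   (logical).
#' @param rate_cols Rate columns to test (default kS, kE, kD).
#' @param expression Column used to rank expression (default `w0`, total
#'   steady-state abundance).
#' @param top_fraction Fraction of highest-expressed genes analyzed
#'   (default 0.7).
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return Tibble `label`, `rate`, `n_bound`, `n_unbound`, `log2_ratio`,
#'   `p_value`, `p_adjusted`, `significant`. Label sets with an empty group
#'   are skipped with a warning.
#' @export
group_rate_comparison <- function(rates, labels,
                                  rate_cols = c("k_s", "k_e", "k_d"),
                                  expression = "w0", top_fraction = 0.7,
                                  alpha = 0.01) {
  check_columns(rates, c("gene_id", rate_cols, expression), "rates")
  check_columns(labels, c("gene_id", "label", "bound"), "labels")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  cutoff <- stats::quantile(rates[[expression]], 1 - top_fraction)
  kept <- dplyr::filter(rates, .data[[expression]] >= cutoff)
  res <- purrr::map_dfr(unique(labels$label), function(lab) {
    bound_ids <- labels$gene_id[labels$label == lab & labels$bound]
    d <- dplyr::mutate(kept, bound = .data$gene_id %in% bound_ids)
    if (sum(d$bound) == 0 || sum(!d$bound) == 0) {
      warning("label set '", lab, "' has an empty group after the ",
              "expression filter; skipped")
      return(NULL)
    }
    purrr::map_dfr(rate_cols, function(rc) {
      x <- d[[rc]][d$bound]
      y <- d[[rc]][!d$bound]
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE))
      # all-tie degenerate case: zero rank variance is no evidence at all
      p <- if (is.na(wt$p.value)) 1 else wt$p.value
      tibble::tibble(label = lab, rate = rc,
                     n_bound = length(x), n_unbound = length(y),
                     log2_ratio = log2(stats::median(x) / stats::median(y)),
                     p_value = p)
    })
  })
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(label = character(), rate = character(),
                          n_bound = integer(), n_unbound = integer(),
                          log2_ratio = numeric(), p_value = numeric(),
                          p_adjusted = numeric(), significant = logical()))
  }
  res |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, "holm"),
                  .by = "rate") |>
    dplyr::mutate(significant = .data$p_adjusted < alpha)
}

#' Pairwise overlap of two gene sets
#'
#' `Overlap(X, Y) = |X intersect Y| / |X|` and symmetrically for Y.
#'
#' @param set_x,set_y Non-empty character vectors of gene ids.
#' @return List with `overlap_xy` and `overlap_yx`.
#' @export
rbp_overlap <- function(set_x, set_y) {
  set_x <- unique(set_x)
  set_y <- unique(set_y)
  if (length(set_x) == 0 || length(set_y) == 0) {
    stop("both gene sets must be non-empty")
  }
  inter <- length(intersect(set_x, set_y))
  list(overlap_xy = inter / length(set_x),
       overlap_yx = inter / length(set_y))
}

#' Pol II pausing index
#'
#' Ratio of polymerase signal in a window around the TSS to the signal over
#' the remaining gene body. Genes with non-positive body signal yield `NA`.
#'
#' @param signal_tss_window Signal within the TSS window (vectorized).
#' @param signal_body Signal over the gene body.
#' @return Pausing indices.
#' @export
pausing_index <- function(signal_tss_window, signal_body) {
  ifelse(signal_body > 0, signal_tss_window / signal_body, NA_real_)
}

#' Compare a kinetic rate across chromatin states
#'
#' One-way ANOVA of the log10 rate across per-gene chromatin states (at one
#' anchor, TSS or TTS), followed by all pairwise Tukey honest-significant-
#' difference comparisons. States with fewer than `min_genes` members are
#' merged into `"other"`.
#'
#' @param rates Rate table with `gene_id` and the column named by
#'   `rate_col`.
#' @param states Tibble `gene_id`, `state` (one state per gene).
#' @param rate_col Which rate to compare (default `k_s`).
#' @param min_genes Minimum genes per state (default 10).
#' @param alpha Significance level on the Tukey-adjusted p (default 0.01).
#' @return A list of class `state_comparison`: `anova_p`, `pairs` (tibble
#'   `state_a`, `state_b`, `diff_log10`, `p_adjusted`, `significant`) and
#'   the per-state summary `groups`.
#' @export
chromatin_state_comparison <- function(rates, states, rate_col = "k_s",
                                       min_genes = 10, alpha = 0.01) {
  check_columns(rates, c("gene_id", rate_col), "rates")
  check_columns(states, c("gene_id", "state"), "states")
  d <- dplyr::inner_join(rates, states, by = "gene_id") |>
    dplyr::filter(.data[[rate_col]] > 0)
  counts <- table(d$state)
  small <- names(counts)[counts < min_genes]
  if (length(small) > 0) {
    warning("state(s) below ", min_genes, " genes merged into 'other': ",
            paste(small, collapse = ", "))
    d$state[d$state %in% small] <- "other"
  }
  d <- dplyr::filter(d, .data$state %in%
                       names(table(d$state))[table(d$state) >= min_genes])
  if (dplyr::n_distinct(d$state) < 2) {
    stop("need >= 2 chromatin states with >= ", min_genes, " genes each")
  }
  d$log_rate <- log10(d[[rate_col]])
  d$state <- factor(d$state)
  fit <- stats::aov(log_rate ~ state, data = d)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$state
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble::tibble(
    state_a = vapply(pair_names, `[`, character(1), 1),
    state_b = vapply(pair_names, `[`, character(1), 2),
    diff_log10 = tk[, "diff"],
    p_adjusted = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  groups <- d |>
    dplyr::summarise(n = dplyr::n(),
                     median_rate = stats::median(.data[[rate_col]]),
                     .by = "state")
  structure(list(anova_p = anova_p, pairs = pairs, groups = groups,
                 rate_col = rate_col),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf(
    "<state_comparison> %s across %d states: ANOVA p = %.3g, %d/%d significant pairs\n",
    x$rate_col, nrow(x$groups), x$anova_p, sum(x$pairs$significant),
    nrow(x$pairs)))
  invisible(x)
}

#' Plot replicate concordance of fitted rates
#'
#' Scatter of replicate 1 versus replicate 2 estimates per rate on log10
#' axes, with the identity line.
#'
#' @param rates Rates table (`gene_id`, `replicate`, `k_s`, `k_e`, `k_d`).
#' @return A ggplot object.
#' @export
plot_rate_concordance <- function(rates) {
  check_columns(rates, c("gene_id", "replicate", "k_s", "k_e", "k_d"),
                "rates")
  reps <- sort(unique(rates$replicate))[1:2]
  long <- rates |>
    dplyr::filter(.data$replicate %in% reps) |>
    tidyr::pivot_longer(c("k_s", "k_e", "k_d"), names_to = "rate") |>
    tidyr::pivot_wider(id_cols = c("gene_id", "rate"),
                       names_from = "replicate", names_prefix = "rep_") |>
    stats::na.omit()
  ggplot2::ggplot(long, ggplot2::aes(.data[[paste0("rep_", reps[1])]],
                                     .data[[paste0("rep_", reps[2])]])) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~rate, scales = "free") +
    ggplot2::labs(x = "replicate 1", y = "replicate 2") +
    ggplot2::theme_minimal()
}
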