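#' Ordinary least-squares agreement regression
#'
#' Regresses one method on the other; reports the squared Pearson correlation
#' and the F-test p-value of the slope.
#'
#' @param x,y Numeric vectors of paired measurements (n >= 3; `x` must vary).
#' @return One-row tibble: `r2`, `slope`, `intercept`, `p`.
#' @export
linear_regression_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Regression needs at least 3 pairs.")
  if (stats::var(x) == 0) {
    abort("Degenerate regressor: `x` is constant.",
          class = "pvloopr_degenerate_regressor")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  tibble(
    r2 = sm$r.squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  )
}

#' Percent-difference Bland-Altman statistics
#'
#' Per-pair percent difference relative to the pairwise mean,
#' \eqn{d_i = 100 (a_i - b_i) / ((a_i + b_i)/2)}; bias is the mean of the
#' \eqn{d_i} and the limits of agreement are bias +/- 1.96 sample SD. With
#' `denominator = "reference"` the percent difference is taken relative to
#' `b` instead of the pairwise mean.
#'
#' @param a,b Numeric vectors (method A and reference method B).
#' @param denominator `"mean"` (standard Bland-Altman, default) or
#'   `"reference"`.
#' @return One-row tibble: `bias_pct`, `loa_low_pct`, `loa_high_pct`, `sd_pct`.
#' @export
bland_altman_percent <- function(a, b, denominator = c("mean", "reference")) {
  denominator <- match.arg(denominator)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2L) abort("Bland-Altman needs at least 2 pairs.")
  denom <- switch(denominator, mean = (a + b) / 2, reference = b)
  if (any(denom <= 0)) {
    abort("All pairwise denominators must be positive.",
          class = "pvloopr_domain")
  }
  d <- 100 * (a - b) / denom
  bias <- mean(d)
  s <- stats::sd(d)
  tibble(bias_pct = bias, loa_low_pct = bias - 1.96 * s,
         loa_high_pct = bias + 1.96 * s, sd_pct = s)
}

#' Paired t-test between two methods
#'
#' Classic paired t statistic with a two-sided p-value. Identical arrays
#' (zero-variance differences) return `t = 0`, `p = 1` by convention rather
#' than erroring.
#'
#' @param a,b Numeric vectors of paired measurements.
#' @return One-row tibble: `t`, `p`, `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2L) abort("Paired t-test needs at least 2 pairs.")
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate difference variance: identical arrays are "no difference";
    # a constant non-zero shift is detected with certainty in the limit
    if (all(d == 0)) return(tibble(t = 0, p = 1, df = length(d) - 1))
    return(tibble(t = sign(d[1]) * Inf, p = 0, df = length(d) - 1))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter))
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute agreement
#'
#' Single-measures absolute-agreement ICC from the two-way ANOVA mean squares
#' of an n-subject by k-rater table,
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + k (MSC - MSE)/n},}
#' reported here for the two-rater case (k = 2).
#'
#' @param a,b Numeric vectors: the two raters' (methods') values per subject.
#' @return The ICC (dimensionless, in \[-1, 1\]).
#' @export
icc_absolute_agreement <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 3L) abort("ICC needs at least 3 subjects.")
  x <- cbind(a, b)
  k <- 2L
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) {
    abort("ICC undefined: zero total variance.", class = "pvloopr_undefined_icc")
  }
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' End-diastolic pressure sensitivity sweep
#'
#' Recomputes the full non-invasive metric set across a grid of assumed
#' end-diastolic pressures. The default grid spans an extremely wide range of
#' possible filling pressures; the 7.5 mmHg row reproduces the default
#' pipeline exactly.
#'
#' @param vol A [volume_curve()].
#' @param bp A [brachial_bp()].
#' @param edp_grid EDP values (mmHg), each below `lvp_systole(bp)`. Default
#'   `c(3, 7.5, 10, 16, 25, 40)`.
#' @param elastance Normalized elastance shape (default packaged curve).
#' @return A tibble with one metric row per grid value, first column `edp`.
#' @export
edp_sensitivity_sweep <- function(vol, bp, edp_grid = c(3, 7.5, 10, 16, 25, 40),
                                  elastance = default_elastance()) {
  lvp <- lvp_systole(bp)
  if (any(edp_grid >= lvp)) {
    abort("Every EDP in the grid must be below LVPsystole.",
          class = "pvloopr_pressure_ordering")
  }
  purrr::map(edp_grid, function(edp) {
    m <- compute_all_metrics(
      compute_noninvasive_loop(vol, bp, edp = edp, elastance = elastance)
    )
    dplyr::bind_cols(tibble(edp = edp), as_tibble(m))
  }) |> purrr::list_rbind()
}

#' Method agreement for one metric across paired datasets
#'
#' Composes [linear_regression_r2()], [bland_altman_percent()],
#' [paired_t_test()] and [icc_absolute_agreement()] for a named metric over a
#' cohort of paired non-invasive (method A) and reference (method B) metric
#' sets.
#'
#' @param pairs A data frame with one row per dataset and columns
#'   `<metric>_a` and `<metric>_b` (as produced by [pair_metrics()]), or a
#'   list with elements `method_a` and `method_b`, each a metrics tibble with
#'   matched rows.
#' @param metric_name Name of the metric column to compare (e.g. `"sw"`).
#' @param denominator Bland-Altman denominator convention; see
#'   [bland_altman_percent()].
#' @return A `pv_agreement` one-row tibble: `metric`, `n`, `r2`, `slope`,
#'   `intercept`, `p_regression`, `bias_pct`, `loa_low_pct`, `loa_high_pct`,
#'   `t_paired_p`, `icc`.
#' @export
compare_methods <- function(pairs, metric_name, denominator = "mean") {
  if (is.data.frame(pairs)) {
    a <- pairs[[paste0(metric_name, "_a")]]
    b <- pairs[[paste0(metric_name, "_b")]]
  } else {
    a <- pairs$method_a[[metric_name]]
    b <- pairs$method_b[[metric_name]]
  }
  if (is.null(a) || is.null(b)) {
    abort(sprintf("Metric `%s` not found in both methods.", metric_name))
  }
  if (length(a) < 3L) abort("Method comparison needs at least 3 datasets.")
  reg <- linear_regression_r2(b, a)
  ba <- bland_altman_percent(a, b, denominator = denominator)
  tt <- paired_t_test(a, b)
  icc <- icc_absolute_agreement(a, b)
  new_tibble(
    tibble(
      metric = metric_name, n = length(a), r2 = reg$r2, slope = reg$slope,
      intercept = reg$intercept, p_regression = reg$p,
      bias_pct = ba$bias_pct, loa_low_pct = ba$loa_low_pct,
      loa_high_pct = ba$loa_high_pct, t_paired_p = tt$p, icc = icc
    ),
    class = "pv_agreement"
  )
}

#' Pair two cohorts of metric sets for comparison
#'
#' @param method_a,method_b Metrics tibbles (e.g. rows of
#'   [compute_all_metrics()] output) with matched dataset ordering.
#' @param labels Optional dataset identifiers.
#' @return A tibble with columns `label` and, for every shared numeric
#'   metric, `<metric>_a` and `<metric>_b`.
#' @export
pair_metrics <- function(method_a, method_b, labels = NULL) {
  if (nrow(method_a) != nrow(method_b)) {
    abort("Both methods need the same number of datasets.")
  }
  if (nrow(method_a) < 3L) abort("Pairing needs at least 3 datasets.")
  shared <- intersect(names(method_a), names(method_b))
  shared <- shared[vapply(method_a[shared], is.numeric, logical(1))]
  out <- tibble(label = labels %||% paste0("dataset_", seq_len(nrow(method_a))))
  for (nm in shared) {
    out[[paste0(nm, "_a")]] <- method_a[[nm]]
    out[[paste0(nm, "_b")]] <- method_b[[nm]]
  }
  out
}

#' Agreement across the seven loop-derived metrics
#'
#' @param pairs Output of [pair_metrics()].
#' @param metrics Metric names to compare; defaults to the seven loop-derived
#'   haemodynamic metrics.
#' @param denominator Bland-Altman denominator convention.
#' @return A tibble with one `pv_agreement` row per metric.
#' @export
compare_all_metrics <- function(pairs,
                                metrics = c("sw", "pe", "espvr", "ve", "ea",
                                            "mep_w", "epev"),
                                denominator = "mean") {
  purrr::map(metrics, function(m) {
    as_tibble(compare_methods(pairs, m, denominator = denominator))
  }) |> purrr::list_rbind()
}

#' @method tidy pv_agreement
#' @export
tidy.pv_agreement <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -c("metric", "n"),
                      names_to = "statistic", values_to = "value")
}

#' @method glance pv_agreement
#' @export
glance.pv_agreement <- function(x, ...) as_tibble(x)
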