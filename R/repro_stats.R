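#' Subject-by-session repeated measures
#'
#' @param values Numeric matrix, subjects in rows, sessions in columns;
#'   the first column is the baseline. Missing cells are allowed (NA) and
#'   excluded pairwise per lag.
#' @param measurand,units Metadata labels.
#' @return An object of class `repeated_measures`.
#' @export
repeated_measures <- function(values, measurand = "measurand",
                              units = "a.u.") {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, ncol(values) >= 2)
  if (is.null(colnames(values)))
    colnames(values) <- c("baseline", paste0("lag", seq_len(ncol(values) - 1)))
  structure(list(values = values, subjects = rownames(values),
                 sessions = colnames(values), measurand = measurand,
                 units = units),
            class = "repeated_measures")
}

# Pairwise-complete baseline/repeat pair extraction.
complete_pairs <- function(baseline, repeated) {
  ok <- is.finite(baseline) & is.finite(repeated)
  list(b = baseline[ok], r = repeated[ok], n = sum(ok))
}

#' Baseline-versus-repeat linear regression
#'
#' Ordinary least squares of the repeated measurement on the baseline
#' measurement; R^2 is the squared correlation and the p-value comes from
#' the slope t-test.
#'
#' @param baseline,repeated Paired numeric vectors (NA pairs dropped).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_pairs`.
#' @export
pair_regression <- function(baseline, repeated) {
  cp <- complete_pairs(baseline, repeated)
  if (cp$n < 3) stop("need at least 3 complete pairs")
  if (stats::var(cp$b) == 0) stop("degenerate regressor: zero baseline variance")
  fit <- stats::lm(r ~ b, data = list(b = cp$b, r = cp$r))
  # exact affine data is legitimate here; silence the perfect-fit notice
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n_pairs = cp$n)
}

#' Bland-Altman bias and limit of agreement
#'
#' Differences d = repeat - baseline; bias is their mean and the limit of
#' agreement is 1.96 times their sample standard deviation (n - 1
#' denominator).
#'
#' @param baseline,repeated Paired numeric vectors.
#' @return List with `bias`, `loa`, `sd_diff`, `n_pairs`.
#' @export
bland_altman <- function(baseline, repeated) {
  cp <- complete_pairs(baseline, repeated)
  if (cp$n < 2) stop("need at least 2 complete pairs")
  d <- cp$r - cp$b
  sd_d <- stats::sd(d)
  list(bias = mean(d), loa = 1.96 * sd_d, sd_diff = sd_d, n_pairs = cp$n)
}

#' Within-subject coefficient of variation
#'
#' Root-mean-square paired-difference estimator: the within-subject SD is
#' sqrt(mean(d^2)/2) and CoV_ws is that SD as a percentage of the grand
#' mean of all measurements in the pair set.
#'
#' @param baseline,repeated Paired numeric vectors.
#' @return CoV_ws in percent.
#' @export
cov_ws <- function(baseline, repeated) {
  cp <- complete_pairs(baseline, repeated)
  if (cp$n < 2) stop("need at least 2 complete pairs")
  gm <- mean(c(cp$b, cp$r))
  if (gm == 0) stop("undefined CoV: zero grand mean")
  d <- cp$r - cp$b
  100 * sqrt(mean(d^2) / 2) / gm
}

#' Paired bias test
#'
#' Two-sided paired t-test on the differences. Identical vectors (zero
#' differences) return p = 1 under the convention of zero bias; zero
#' variance with a nonzero mean difference returns the sentinel 1e-16.
#'
#' @param baseline,repeated Paired numeric vectors.
#' @return Two-sided p-value.
#' @export
paired_bias_test <- function(baseline, repeated) {
  cp <- complete_pairs(baseline, repeated)
  if (cp$n < 3) stop("need at least 3 complete pairs")
  d <- cp$r - cp$b
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 1e-16)
  stats::t.test(d)$p.value
}

#' Assemble a reproducibility table
#'
#' One row per non-baseline session: baseline-versus-session regression,
#' Bland-Altman bias and limit of agreement, within-subject CoV and the
#' paired bias test, with pairwise-complete handling per lag. Lags with
#' too few complete pairs are emitted as flagged rows rather than errors.
#'
#' @param rm A [repeated_measures()] object.
#' @param baseline Baseline column name (default: first session).
#' @return Data frame with columns `measurand`, `lag`, `n_pairs`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `bias`, `loa`, `cov_ws`,
#'   `bias_p`, `flagged`.
#' @export
build_repro_table <- function(rm, baseline = NULL) {
  stopifnot(inherits(rm, "repeated_measures"))
  if (is.null(baseline)) baseline <- rm$sessions[1]
  stopifnot(baseline %in% rm$sessions)
  b <- rm$values[, baseline]
  lags <- setdiff(rm$sessions, baseline)
  rows <- lapply(lags, function(lag) {
    r <- rm$values[, lag]
    row <- data.frame(measurand = rm$measurand, lag = lag,
                      n_pairs = complete_pairs(b, r)$n,
                      slope = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, p_value = NA_real_,
                      bias = NA_real_, loa = NA_real_, cov_ws = NA_real_,
                      bias_p = NA_real_, flagged = FALSE,
                      stringsAsFactors = FALSE)
    reg <- tryCatch(pair_regression(b, r), error = function(e) NULL)
    if (!is.null(reg)) {
      row$slope <- reg$slope; row$intercept <- reg$intercept
      row$r_squared <- reg$r_squared; row$p_value <- reg$p_value
    } else row$flagged <- TRUE
    ba <- tryCatch(bland_altman(b, r), error = function(e) NULL)
    if (!is.null(ba)) { row$bias <- ba$bias; row$loa <- ba$loa }
    else row$flagged <- TRUE
    cv <- tryCatch(cov_ws(b, r), error = function(e) NULL)
    if (!is.null(cv)) row$cov_ws <- cv else row$flagged <- TRUE
    pt <- tryCatch(paired_bias_test(b, r), error = function(e) NULL)
    if (!is.null(pt)) row$bias_p <- pt
    row
  })
  do.call(rbind, rows)
}
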