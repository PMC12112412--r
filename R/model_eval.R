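#' Observed-versus-predicted goodness-of-fit statistics
#'
#' Computes the standard crop-model evaluation metrics for a paired
#' observed/predicted series: absolute and normalized root mean square
#' error, mean absolute error, Willmott's index of agreement,
#'
#' \deqn{WI = 1 - \frac{\sum (E_i - O_i)^2}{\sum (|E_i - \bar O| + |O_i - \bar O|)^2},}
#'
#' the slope/intercept/r-squared of the regression of predicted on
#' observed, and the two-sided p-value of Welch's unequal-variance t-test
#' of the two means. MAE is reported as a magnitude (it cannot carry the
#' direction of error); the signed mean bias `mean(E - O)` is reported
#' separately so over- or underestimation is recoverable.
#'
#' @param pairs A `paired_series` from [align_observed_predicted()], or a
#'   list with elements `observed` and `predicted`.
#' @return A one-row tibble: `n`, `mean_obs`, `mean_pred`, `sd_obs`,
#'   `cv_obs`, `bias`, `mae`, `rmse_a`, `rmse_n`, `wi`, `slope`,
#'   `intercept`, `r2`, `p_welch`. `rmse_n` and `cv_obs` are percentages
#'   of the observed mean (`NA` if that mean is zero); the regression and
#'   `r2` are `NA` with a warning when the observed values are constant.
#' @export
evaluate_pairs <- function(pairs) {
  o <- pairs$observed
  e <- pairs$predicted
  stopifnot(length(o) == length(e))
  ok <- is.finite(o) & is.finite(e)
  o <- o[ok]; e <- e[ok]
  n <- length(o)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)

  o_bar <- mean(o)
  rmse_a <- sqrt(mean((o - e)^2))
  mae <- mean(abs(e - o))
  bias <- mean(e - o)
  pot <- sum((abs(e - o_bar) + abs(o - o_bar))^2)
  wi <- if (pot == 0) 1 else 1 - sum((e - o)^2) / pot

  if (o_bar > 0) {
    rmse_n <- 100 * rmse_a / o_bar
    cv_obs <- 100 * sd(o) / o_bar
  } else {
    warning("observed mean is not positive; rmse_n and cv_obs undefined",
            call. = FALSE)
    rmse_n <- NA_real_
    cv_obs <- NA_real_
  }

  if (sd(o) > 0) {
    reg <- lm(e ~ o)
    slope <- unname(coef(reg)[2])
    intercept <- unname(coef(reg)[1])
    tss <- sum((e - mean(e))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(reg$residuals^2) / tss
  } else {
    warning("observed values are constant; regression undefined",
            call. = FALSE)
    slope <- intercept <- r2 <- NA_real_
  }

  tibble::tibble(
    n = n, mean_obs = o_bar, mean_pred = mean(e), sd_obs = sd(o),
    cv_obs = cv_obs, bias = bias, mae = mae, rmse_a = rmse_a,
    rmse_n = rmse_n, wi = wi, slope = slope, intercept = intercept,
    r2 = r2, p_welch = welch_t(pairs)$p.value
  )
}

#' Welch's t-test on a paired series
#'
#' Two-sided t-test of equal means assuming unequal variances
#' (Welch-Satterthwaite degrees of freedom) between the observed and
#' predicted sides of a paired series; a paired t-test is available as an
#' option.
#'
#' @param pairs A `paired_series` or list with `observed` and `predicted`.
#' @param paired Use the paired test instead of Welch's unpaired test.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
welch_t <- function(pairs, paired = FALSE) {
  o <- pairs$observed
  e <- pairs$predicted
  ok <- is.finite(o) & is.finite(e)
  o <- o[ok]; e <- e[ok]
  if (length(o) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (sd(o) == 0 && sd(e) == 0) {
    # degenerate: no variance on either side
    if (isTRUE(all.equal(mean(o), mean(e)))) {
      return(list(statistic = 0, df = NA_real_, p.value = 1))
    }
    return(list(statistic = Inf, df = NA_real_, p.value = 0))
  }
  tt <- t.test(e, o, var.equal = FALSE, paired = paired)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}
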