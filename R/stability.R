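#' Per-treatment yield summaries for stability analysis
#'
#' For each treatment (row of a treatment-by-environment yield matrix)
#' computes the environment count `n`, mean, sample standard deviation
#' (n - 1 denominator), variance, plain CV (%), and the base-10 logs
#' `m = log10(mean)` and `v = log10(variance)` that enter the Taylor
#' power-law regression behind the adjusted CV.
#'
#' @param mat Treatment-by-environment matrix of mean yields (Mg/ha), as
#'   returned by [pivot_matrix()]. `NA` cells are ignored.
#' @param on_zero_variance What to do with a treatment whose yields are
#'   constant (log10 of zero variance is undefined): `"error"` (default)
#'   or `"drop"` with a warning.
#' @return A tibble with columns `treatment_id`, `n`, `mean`, `sd`,
#'   `variance`, `cv`, `m`, `v`.
#' @export
summarize_treatments <- function(mat, on_zero_variance = c("error", "drop")) {
  on_zero_variance <- match.arg(on_zero_variance)
  stopifnot(is.matrix(mat))
  n <- rowSums(!is.na(mat))
  if (any(n < 2)) {
    stop("treatment(s) with fewer than 2 environments: ",
         paste(rownames(mat)[n < 2], collapse = ", "), call. = FALSE)
  }
  mu <- rowMeans(mat, na.rm = TRUE)
  if (any(mu <= 0)) {
    stop("nonpositive mean yield for treatment(s): ",
         paste(rownames(mat)[mu <= 0], collapse = ", "), call. = FALSE)
  }
  s <- apply(mat, 1, sd, na.rm = TRUE)
  zero <- s == 0
  if (any(zero)) {
    if (on_zero_variance == "error") {
      stop("zero yield variance for treatment(s): ",
           paste(rownames(mat)[zero], collapse = ", "),
           "; stability measures on the log scale are undefined",
           call. = FALSE)
    }
    warning("dropping zero-variance treatment(s): ",
            paste(rownames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  keep <- !zero
  mu <- unname(mu[keep])
  s <- unname(s[keep])
  tibble::tibble(
    treatment_id = rownames(mat)[keep],
    n = as.integer(unname(n[keep])),
    mean = mu,
    sd = s,
    variance = s^2,
    cv = 100 * s / mu,
    m = log10(mu),
    v = log10(s^2)
  )
}

#' Build treatment summaries from published means and SDs
#'
#' Convenience for working with printed summary tables (mean and SD per
#' treatment) when the underlying yearly yields are unavailable.
#'
#' @param treatment_id Treatment labels.
#' @param mean,sd Per-treatment mean and sample SD of yield (Mg/ha).
#' @param n Environment counts (years), recycled if scalar.
#' @return A tibble in the same layout as [summarize_treatments()].
#' @export
summaries_from_moments <- function(treatment_id, mean, sd, n = NA_integer_) {
  stopifnot(length(mean) == length(treatment_id),
            length(sd) == length(treatment_id))
  if (any(mean <= 0)) stop("means must be positive", call. = FALSE)
  if (any(sd <= 0)) stop("SDs must be positive", call. = FALSE)
  tibble::tibble(
    treatment_id = as.character(treatment_id),
    n = as.integer(rep_len(n, length(mean))),
    mean = mean, sd = sd, variance = sd^2,
    cv = 100 * sd / mean, m = log10(mean), v = log10(sd^2)
  )
}

#' Fit the Taylor power-law (log-variance on log-mean) regression
#'
#' Ordinary least squares of `v = log10(variance)` on `m = log10(mean)`
#' across treatments: `log10(sigma^2) = a + b * log10(mean)`. The slope
#' `b` is the mean-variance scaling exponent used by the adjusted CV;
#' `b = 2` corresponds to a constant-CV family.
#'
#' @param summaries Treatment summaries ([summarize_treatments()]).
#' @return A list of class `taylor_fit`: `a`, `b`, `r2`, `m_bar` (mean of
#'   the `m_i`), and `group` (the treatment ids entering the fit).
#' @export
fit_taylor <- function(summaries) {
  if (nrow(summaries) < 3) {
    stop("Taylor regression needs at least 3 treatments", call. = FALSE)
  }
  if (!all(is.finite(summaries$m)) || !all(is.finite(summaries$v))) {
    stop("non-finite log-mean or log-variance in summaries", call. = FALSE)
  }
  if (length(unique(summaries$m)) == 1) {
    stop("all treatment means identical; Taylor regression is singular",
         call. = FALSE)
  }
  fit <- lm(v ~ m, data = summaries)
  tss <- sum((summaries$v - mean(summaries$v))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  structure(list(
    a = unname(coef(fit)[1]),
    b = unname(coef(fit)[2]),
    r2 = r2,
    m_bar = mean(summaries$m),
    group = summaries$treatment_id
  ), class = "taylor_fit")
}

#' Adjusted coefficient of variation
#'
#' The CV corrected for the systematic mean-variance relationship (Doering
#' & Reckling's aCV): each treatment's log-variance is shifted along the
#' fitted Taylor power law to the common mean log-yield `m_bar` before
#' being re-expressed as a CV, so that stability comparisons are not
#' confounded by yield level. With slope `b`,
#' `aCV_i = 100 / mean_i * sqrt(10^(v_i + (2 - b) * (m_i - m_bar)))`.
#' At `b = 2`, and for any treatment with `m_i = m_bar`, this reduces to
#' the plain CV. Higher aCV means lower yield stability.
#'
#' @param summaries Treatment summaries.
#' @param fit A `taylor_fit` from the same grouping of treatments.
#' @param strict If `TRUE` (default), error when a summary row was not part
#'   of the fit's group.
#' @return Numeric vector of aCV values (%), named by treatment.
#' @export
adjusted_cv <- function(summaries, fit, strict = TRUE) {
  stopifnot(inherits(fit, "taylor_fit"))
  outside <- setdiff(summaries$treatment_id, fit$group)
  if (strict && length(outside) > 0) {
    stop("treatment(s) not in the Taylor fit group: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  expo <- summaries$v + (2 - fit$b) * (summaries$m - fit$m_bar)
  setNames(100 / summaries$mean * sqrt(10^expo), summaries$treatment_id)
}

#' Sustainable yield index
#'
#' `SYI = (mean - sd) / y_max`, where `y_max` is the maximum yield over
#' all years and treatments in the group being compared. Values near 1
#' indicate sustainable (high and steady) yields; values near 0 indicate
#' unsustainable ones.
#'
#' @param mean,sd Per-treatment mean and SD of yield (Mg/ha).
#' @param y_max Maximum yield in all years and treatments (Mg/ha).
#' @return Numeric vector of SYI values.
#' @export
sustainable_yield_index <- function(mean, sd, y_max) {
  if (!is.finite(y_max) || y_max <= 0) {
    stop("y_max must be a positive number", call. = FALSE)
  }
  (mean - sd) / y_max
}

#' Finlay-Wilkinson regression
#'
#' Regresses each treatment's yields on the environment index
#' `omega_j` = mean yield of environment `j` over all treatments:
#' `yield_ij = beta_i + alpha_i * omega_j`. The slope `alpha_i` measures
#' environmental sensitivity (small values = stable response; values > 1
#' amplify environmental differences). On a complete matrix the slopes
#' average exactly 1.
#'
#' @param mat Treatment-by-environment matrix of mean yields.
#' @return A list of class `fw_fit`: `environment_means` (the
#'   `omega_j`) and `coefficients`, a tibble with `treatment_id`, `slope`,
#'   `intercept`, `resid_sd` and `n_env`. Treatments with fewer than 3
#'   non-missing environments are skipped with a warning.
#' @export
finlay_wilkinson <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 3) {
    stop("Finlay-Wilkinson regression needs at least 3 environments",
         call. = FALSE)
  }
  omega <- colMeans(mat, na.rm = TRUE)
  rows <- lapply(rownames(mat), function(trt) {
    y <- mat[trt, ]
    ok <- !is.na(y)
    if (sum(ok) < 3) {
      warning("skipping treatment '", trt,
              "' with fewer than 3 environments", call. = FALSE)
      return(NULL)
    }
    if (sd(y[ok]) == 0) {
      # constant response: slope 0, intercept the constant
      return(tibble::tibble(treatment_id = trt, slope = 0,
                            intercept = unname(y[ok][1]), resid_sd = 0,
                            n_env = sum(ok)))
    }
    f <- lm(y[ok] ~ omega[ok])
    tibble::tibble(
      treatment_id = trt,
      slope = unname(coef(f)[2]),
      intercept = unname(coef(f)[1]),
      resid_sd = sqrt(sum(f$residuals^2) / f$df.residual),
      n_env = sum(ok)
    )
  })
  structure(list(environment_means = omega,
                 coefficients = dplyr::bind_rows(rows)),
            class = "fw_fit")
}

#' Full stability table for a yield panel
#'
#' Combines all stability measures per treatment and per source: mean, SD,
#' CV, adjusted CV (with a Taylor regression fitted within each
#' (dataset, source) group), SYI (with `y_max` the maximum
#' replicate-averaged cell yield within the same group, unless supplied),
#' and Finlay-Wilkinson slope and intercept.
#'
#' @param panel A `yield_panel`.
#' @param dataset Dataset identifier; defaults to the panel's single one.
#' @param y_max Optional named list/vector giving `y_max` per source;
#'   by default the per-source maximum cell yield is used.
#' @param on_zero_variance Passed to [summarize_treatments()]; the default
#'   here is `"drop"` so a constant treatment does not abort the table.
#' @return A tibble with one row per (source, treatment): `dataset_id`,
#'   `source`, `treatment_id`, `n`, `mean`, `sd`, `cv`, `acv`, `syi`,
#'   `fw_slope`, `fw_intercept`, ordered by source then treatment.
#' @export
stability_table <- function(panel, dataset = NULL, y_max = NULL,
                            on_zero_variance = "drop") {
  stopifnot(inherits(panel, "yield_panel"))
  df <- tibble::as_tibble(panel)
  dataset <- dataset %||% unique(df$dataset_id)
  if (length(dataset) != 1) {
    stop("panel holds multiple datasets; name one via `dataset`",
         call. = FALSE)
  }
  sources <- intersect(c("observed", "predicted"),
                       unique(df$source[df$dataset_id == dataset]))
  out <- lapply(sources, function(src) {
    mat <- pivot_matrix(panel, source = src, dataset = dataset)
    summ <- summarize_treatments(mat, on_zero_variance = on_zero_variance)
    tfit <- fit_taylor(summ)
    acv <- adjusted_cv(summ, tfit)
    ym <- if (!is.null(y_max)) {
      as.numeric(y_max[[src]] %||% y_max)
    } else {
      max(mat, na.rm = TRUE)
    }
    syi <- sustainable_yield_index(summ$mean, summ$sd, ym)
    fw <- finlay_wilkinson(mat)$coefficients
    res <- tibble::tibble(dataset_id = dataset, source = src,
                          treatment_id = summ$treatment_id, n = summ$n,
                          mean = summ$mean, sd = summ$sd, cv = summ$cv,
                          acv = unname(acv), syi = syi)
    dplyr::left_join(res, fw[c("treatment_id", "slope", "intercept")],
                     by = "treatment_id") |>
      dplyr::rename(fw_slope = "slope", fw_intercept = "intercept")
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$source, .data$treatment_id)
}
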