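#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurement series with the identity line,
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' using population (1/n) moment estimators per Lin's original
#' definition. The CCC factors as `CCC = r * Cb` where `r` is the Pearson
#' correlation and `Cb` in (0, 1] is the bias-correction factor penalizing
#' location and scale shifts (`Cb = 1` means no bias). `r` is kept signed;
#' `Cb` is therefore always positive and `|CCC| <= |r|`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A list of class `concordance_result`: `n`, `r` (signed
#'   Pearson), `r_abs`, `ccc`, `cb`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  # population (1/n) moments
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 || sy2 == 0) {
    stop("zero variance in one of the vectors; concordance undefined",
         call. = FALSE)
  }
  r <- sxy / sqrt(sx2 * sy2)
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  structure(list(n = n, r = r, r_abs = abs(r), ccc = ccc, cb = ccc / r),
            class = "concordance_result")
}

#' Agreement table between observed and predicted stability measures
#'
#' For each requested measure and each group (the pooled `"All"` rows plus
#' every level of the grouping factors), computes Pearson r, Lin's CCC and
#' the bias-correction factor between the observed and predicted columns.
#' Groups with fewer than 3 treatments are skipped with a warning.
#'
#' @param wide A data frame with, for each measure `<m>`, paired columns
#'   `<m>_obs` and `<m>_pred` (the layout of [load_lte_stability()]).
#' @param measures Character vector of measure stems, e.g.
#'   `c("acv", "syi")`.
#' @param group_vars Optional character vector of factor columns in `wide`
#'   whose levels define subgroups in addition to `"All"`.
#' @return A tibble with columns `group`, `measure`, `n`, `r` (signed),
#'   `r_abs`, `ccc`, `cb`.
#' @export
agreement_from_wide <- function(wide, measures = c("acv", "syi"),
                                group_vars = NULL) {
  wide <- tibble::as_tibble(wide)
  for (m in measures) {
    need <- paste0(m, c("_obs", "_pred"))
    if (!all(need %in% names(wide))) {
      stop("missing paired columns for measure '", m, "': ",
           paste(setdiff(need, names(wide)), collapse = ", "),
           call. = FALSE)
    }
  }
  groups <- list(All = rep(TRUE, nrow(wide)))
  for (gv in group_vars) {
    for (lev in unique(wide[[gv]])) {
      groups[[as.character(lev)]] <- wide[[gv]] == lev
    }
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- wide[groups[[g]], , drop = FALSE]
    for (m in measures) {
      x <- sub[[paste0(m, "_obs")]]
      y <- sub[[paste0(m, "_pred")]]
      if (sum(is.finite(x) & is.finite(y)) < 3) {
        warning("group '", g, "' has fewer than 3 pairs for measure '", m,
                "'; skipped", call. = FALSE)
        next
      }
      cc <- lin_ccc(x, y)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, measure = m, n = cc$n, r = cc$r, r_abs = cc$r_abs,
        ccc = cc$ccc, cb = cc$cb)
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname agreement_from_wide
#' @param obs,pred Stability tables (as from [stability_table()]) for the
#'   observed and predicted source, each with `treatment_id` and the
#'   measure columns; treatments are matched by id and must coincide.
#' @param groups Optional data frame mapping `treatment_id` to factor
#'   columns used for subgrouping.
#' @export
stability_agreement <- function(obs, pred,
                                measures = c("acv", "syi", "fw_slope"),
                                groups = NULL) {
  if (!setequal(obs$treatment_id, pred$treatment_id)) {
    stop("observed and predicted tables cover different treatments",
         call. = FALSE)
  }
  keep <- c("treatment_id", intersect(measures, names(obs)))
  wide <- dplyr::inner_join(obs[keep], pred[keep], by = "treatment_id",
                            suffix = c("_obs", "_pred"))
  group_vars <- NULL
  if (!is.null(groups)) {
    wide <- dplyr::left_join(wide, groups, by = "treatment_id")
    group_vars <- setdiff(names(groups), "treatment_id")
  }
  agreement_from_wide(wide, measures = intersect(measures, names(obs)),
                      group_vars = group_vars)
}
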