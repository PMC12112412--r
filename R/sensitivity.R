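#' Variance-based sensitivity indices by Saltelli's method
#'
#' Monte-Carlo estimation of the main-effect and total-effect variance
#' decomposition indices
#' \deqn{S_i = \frac{Var\{E(f(X) \mid x_i)\}}{Var\{f(X)\}}, \qquad
#'       ST_i = 1 - \frac{Var\{E(f(X) \mid x_{-i})\}}{Var\{f(X)\}}}
#' using the A/B/AB radial scheme on a Sobol' base sample: the
#' Saltelli-2010 estimator for `S_i` and the Jansen estimator for `ST_i`.
#' `ST_i - S_i` measures a parameter's involvement in interactions.
#' Negative estimates (Monte-Carlo noise around zero) are reported as-is,
#' not clipped.
#'
#' The model function is evaluated `n_base * (k + 2)` times per context.
#' Runs for which the model returns a missing value (e.g. simulated crop
#' failure) are discarded block-wise via [discard_failed()] before
#' estimation.
#'
#' @param model Function `(point, context) -> named numeric outputs`,
#'   where `point` is a named vector of parameter values; return `NA` (or
#'   any vector containing `NA`) to flag a failed run. Must be
#'   deterministic given `(point, context)`.
#' @param specs A `param_ranges` table defining the k parameters.
#' @param n_base Base sample size (>= 64); estimator error scales as
#'   `1/sqrt(n_base)`.
#' @param seed Optional integer; applies a seeded Cranley-Patterson
#'   rotation (random mod-1 shift) to the Sobol' base sample so replicate
#'   runs differ while retaining low discrepancy. `NULL` gives the raw
#'   sequence.
#' @param contexts Vector of context labels (e.g. simulation years) passed
#'   through to `model`; indices are estimated per context. Default: one
#'   unnamed context.
#' @return A tibble with one row per (context, output, parameter):
#'   `context`, `output`, `parameter`, `s_i`, `st_i`, `var_f`,
#'   `n_effective`, `n_discarded`.
#' @export
saltelli_indices <- function(model, specs, n_base, seed = NULL,
                             contexts = NULL) {
  stopifnot(inherits(specs, "param_ranges"), is.function(model))
  if (n_base < 64) stop("n_base must be at least 64", call. = FALSE)
  k <- nrow(specs)
  unit <- sobol_sequence(n_base, 2 * k, skip = 1L)
  if (!is.null(seed)) {
    shift <- with_seed(seed, runif(2 * k))
    unit <- (unit + matrix(shift, n_base, 2 * k, byrow = TRUE)) %% 1
  }
  scale_pts <- function(u) {
    s <- sweep(u, 2, specs$max - specs$min, `*`)
    sweep(s, 2, specs$min, `+`)
  }
  A <- scale_pts(unit[, seq_len(k), drop = FALSE])
  B <- scale_pts(unit[, k + seq_len(k), drop = FALSE])
  colnames(A) <- colnames(B) <- specs$name

  contexts <- contexts %||% "1"
  eval_rows <- function(mat, ctx) {
    res <- lapply(seq_len(nrow(mat)), function(i) model(mat[i, ], ctx))
    nm <- NULL
    for (r in res) {
      if (!is.null(names(r)) && !anyNA(r)) { nm <- names(r); break }
    }
    if (is.null(nm)) nm <- paste0("y", seq_along(res[[1]]))
    out <- matrix(NA_real_, nrow(mat), length(nm), dimnames = list(NULL, nm))
    for (i in seq_along(res)) {
      r <- res[[i]]
      if (length(r) == length(nm) && !anyNA(r)) out[i, ] <- as.numeric(r)
    }
    out
  }

  all_rows <- list()
  for (ctx in contexts) {
    fA <- eval_rows(A, ctx)
    fB <- eval_rows(B, ctx)
    fAB <- lapply(seq_len(k), function(i) {
      ABi <- A
      ABi[, i] <- B[, i]
      eval_rows(ABi, ctx)
    })
    flt <- discard_failed(fA, fB, fAB)
    for (out_name in colnames(flt$fA)) {
      a <- flt$fA[, out_name]
      b <- flt$fB[, out_name]
      n_eff <- length(a)
      vf <- mean((c(a, b) - mean(c(a, b)))^2)
      if (vf == 0) {
        stop("zero output variance for '", out_name,
             "'; indices undefined", call. = FALSE)
      }
      for (i in seq_len(k)) {
        abi <- flt$fAB[[i]][, out_name]
        s_i <- mean(b * (abi - a)) / vf
        st_i <- mean((a - abi)^2) / (2 * vf)
        all_rows[[length(all_rows) + 1]] <- tibble::tibble(
          context = as.character(ctx), output = out_name,
          parameter = specs$name[i], s_i = s_i, st_i = st_i, var_f = vf,
          n_effective = n_eff, n_discarded = flt$n_discarded)
      }
    }
  }
  dplyr::bind_rows(all_rows)
}

#' Discard failed runs block-wise from a Saltelli evaluation
#'
#' A sample block couples one row of the A matrix with the matching rows
#' of B and of every AB_i matrix; a missing output anywhere in the block
#' invalidates the whole block, so the paired estimators stay consistent.
#' Aborts when more than half of the blocks fail (estimates would be
#' unreliable).
#'
#' @param fA,fB Numeric run-output matrices (runs x outputs); `NA` rows
#'   mark failed runs.
#' @param fAB List of k matrices like `fA`, one per parameter.
#' @return A list `fA`, `fB`, `fAB` (filtered), `n_discarded`, `fraction`.
#' @export
discard_failed <- function(fA, fB, fAB) {
  n <- nrow(fA)
  bad <- rowSums(is.na(fA)) > 0 | rowSums(is.na(fB)) > 0
  for (m in fAB) bad <- bad | rowSums(is.na(m)) > 0
  frac <- mean(bad)
  if (frac > 0.5) {
    stop(sprintf(paste0("%.0f%% of sample blocks failed (> 50%%); ",
                        "sensitivity estimates would be unreliable"),
                 100 * frac), call. = FALSE)
  }
  keep <- !bad
  list(fA = fA[keep, , drop = FALSE], fB = fB[keep, , drop = FALSE],
       fAB = lapply(fAB, function(m) m[keep, , drop = FALSE]),
       n_discarded = sum(bad), fraction = frac)
}

#' Distribution summaries of sensitivity indices across contexts
#'
#' Tukey boxplot statistics (median, quartiles, 1.5 IQR whiskers and
#' outliers) of the per-context `S_i` and `ST_i` values for each
#' (output, parameter) combination, mirroring the usual per-year boxplot
#' presentation of index distributions.
#'
#' @param results Output of [saltelli_indices()] over at least 2 contexts.
#' @return A tibble with columns `output`, `parameter`, `index`
#'   (`"s_i"`/`"st_i"`), `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high` and the list-column `outliers`.
#' @export
summarize_indices <- function(results) {
  if (length(unique(results$context)) < 2) {
    stop("need results from at least 2 contexts", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    results[c("context", "output", "parameter", "s_i", "st_i")],
    cols = c("s_i", "st_i"), names_to = "index", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$output, .data$parameter, .data$index),
    n = dplyr::n(),
    median = median(.data$value),
    q1 = quantile(.data$value, 0.25, names = FALSE),
    q3 = quantile(.data$value, 0.75, names = FALSE),
    iqr = .data$q3 - .data$q1,
    whisker_low = min(.data$value[.data$value >= .data$q1 - 1.5 * .data$iqr]),
    whisker_high = max(.data$value[.data$value <= .data$q3 + 1.5 * .data$iqr]),
    outliers = list(.data$value[.data$value < .data$q1 - 1.5 * .data$iqr |
                                  .data$value > .data$q3 + 1.5 * .data$iqr]),
    .groups = "drop")
}
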