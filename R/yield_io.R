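#' Yield panel data model and tabular I/O
#'
#' A yield panel is a long ("tidy") table of grain-yield records keyed by
#' `(dataset_id, source, treatment_id, environment_id, replicate)`, the
#' universal input to the stability and model-evaluation chains. `source`
#' distinguishes field observations (`"observed"`) from crop-model output
#' (`"predicted"`); `environment_id` identifies a year or a year-by-season
#' combination. Yields are in Mg per hectare and must be non-negative;
#' missing yields are explicit `NA` markers, never zeros (a zero is a valid
#' crop-failure yield).
#'
#' @param records A data frame with at least the mandatory columns
#'   `dataset_id`, `source`, `treatment_id`, `environment_id`,
#'   `grain_yield`. Optional columns: `replicate`, `biomass`, plus free
#'   factor columns (e.g. `n_rate`, `season`, `residue`).
#' @param factors Optional character vector naming the factor columns that
#'   every record must carry (the declared factor schema). Defaults to any
#'   non-reserved columns present.
#'
#' @return A tibble of class `yield_panel` with attribute `factors`.
#' @export
yield_panel <- function(records, factors = NULL) {
  records <- tibble::as_tibble(records)
  mandatory <- c("dataset_id", "source", "treatment_id", "environment_id",
                 "grain_yield")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("yield panel is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(records)) records$replicate <- NA_character_
  records$replicate <- as.character(records$replicate)
  if (!"biomass" %in% names(records)) records$biomass <- NA_real_

  if (!is.numeric(records$grain_yield)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$grain_yield))) &
                   !is.na(records$grain_yield))
    stop("non-numeric grain_yield at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (col in c("grain_yield", "biomass")) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad) > 0) {
      stop(col, " must be non-negative and finite; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad_src <- setdiff(unique(records$source), c("observed", "predicted"))
  if (length(bad_src) > 0) {
    stop("source must be 'observed' or 'predicted'; found: ",
         paste(bad_src, collapse = ", "), call. = FALSE)
  }

  key <- paste(records$dataset_id, records$source, records$treatment_id,
               records$environment_id, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate record key(s), e.g. (",
         paste(dup$dataset_id[1], dup$source[1], dup$treatment_id[1],
               dup$environment_id[1], dup$replicate[1], sep = ", "),
         ")", call. = FALSE)
  }

  reserved <- c(mandatory, "replicate", "biomass")
  factors <- factors %||% setdiff(names(records), reserved)
  missing_fac <- setdiff(factors, names(records))
  if (length(missing_fac) > 0) {
    stop("declared factor column(s) absent: ",
         paste(missing_fac, collapse = ", "), call. = FALSE)
  }
  structure(records, class = c("yield_panel", class(records)),
            factors = factors)
}

#' Read a yield panel from a delimited file
#'
#' Files are comma-delimited UTF-8 with a required header and decimal
#' points. The header must contain `dataset_id`, `source`, `treatment_id`,
#' `environment_id` and `grain_yield`; `replicate`, `biomass` and factor
#' columns are optional.
#'
#' @param path Path to a CSV file.
#' @param factors Optional declared factor schema (see [yield_panel()]).
#' @return A validated `yield_panel`.
#' @export
read_yield_table <- function(path, factors = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("dataset_id", "source", "treatment_id", "environment_id",
                 "grain_yield")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("grain_yield", "biomass"), names(raw))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      stop("non-numeric ", col, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- num
  }
  yield_panel(raw, factors = factors)
}

#' Write a yield panel to a delimited file
#'
#' @param panel A `yield_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(panel, path) {
  stopifnot(inherits(panel, "yield_panel"))
  readr::write_csv(tibble::as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Align observed and predicted records into a paired series
#'
#' Inner-joins the two sources of one dataset on
#' `(treatment_id, environment_id, replicate)` and returns the paired
#' observed/predicted yields, ordered by sorted key so the pairing is
#' deterministic. Keys present on only one side are dropped and reported
#' via a message.
#'
#' @param panel A `yield_panel` holding both sources.
#' @param dataset Dataset identifier; defaults to the panel's single
#'   dataset.
#' @param variable Which value column to pair, `"grain_yield"` (default)
#'   or `"biomass"`.
#' @return A list of class `paired_series` with elements `keys` (tibble),
#'   `observed`, `predicted` and `n`.
#' @export
align_observed_predicted <- function(panel, dataset = NULL,
                                     variable = "grain_yield") {
  stopifnot(inherits(panel, "yield_panel"))
  df <- tibble::as_tibble(panel)
  dataset <- dataset %||% unique(df$dataset_id)
  if (length(dataset) != 1) {
    stop("panel holds multiple datasets; name one via `dataset`",
         call. = FALSE)
  }
  df <- df[df$dataset_id == dataset & !is.na(df[[variable]]), , drop = FALSE]
  keycols <- c("treatment_id", "environment_id", "replicate")
  obs <- df[df$source == "observed", c(keycols, variable)]
  prd <- df[df$source == "predicted", c(keycols, variable)]
  if (nrow(obs) == 0 || nrow(prd) == 0) {
    stop("panel must hold both observed and predicted records for dataset '",
         dataset, "'", call. = FALSE)
  }
  names(obs)[4] <- "observed"
  names(prd)[4] <- "predicted"
  joined <- dplyr::inner_join(obs, prd, by = keycols)
  if (nrow(joined) == 0) {
    stop("no overlapping (treatment, environment, replicate) keys between ",
         "observed and predicted records", call. = FALSE)
  }
  n_extra <- (nrow(obs) - nrow(joined)) + (nrow(prd) - nrow(joined))
  if (n_extra > 0) {
    message(n_extra, " unmatched record(s) dropped while pairing dataset '",
            dataset, "'")
  }
  joined <- dplyr::arrange(joined, .data$treatment_id, .data$environment_id,
                           .data$replicate)
  structure(list(keys = joined[keycols], observed = joined$observed,
                 predicted = joined$predicted, n = nrow(joined)),
            class = "paired_series")
}

#' Pivot a yield panel to a treatment-by-environment matrix
#'
#' Cell values are arithmetic means over replicates. Missing cells are
#' `NA`; a treatment absent from more than half of the environments raises
#' a warning and an entirely empty treatment row is an error.
#'
#' @param panel A `yield_panel`.
#' @param source `"observed"` or `"predicted"`.
#' @param dataset Dataset identifier; defaults to the panel's single one.
#' @param variable Value column, default `"grain_yield"`.
#' @return A numeric matrix, treatments in rows, environments in columns,
#'   both in sorted label order.
#' @export
pivot_matrix <- function(panel, source = "observed", dataset = NULL,
                         variable = "grain_yield") {
  stopifnot(inherits(panel, "yield_panel"),
            source %in% c("observed", "predicted"))
  df <- tibble::as_tibble(panel)
  dataset <- dataset %||% unique(df$dataset_id)
  if (length(dataset) != 1) {
    stop("panel holds multiple datasets; name one via `dataset`",
         call. = FALSE)
  }
  df <- df[df$dataset_id == dataset & df$source == source, , drop = FALSE]
  if (nrow(df) == 0) stop("no records for source '", source, "'", call. = FALSE)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$treatment_id, .data$environment_id),
    value = mean(.data[[variable]], na.rm = TRUE), .groups = "drop")
  agg$value[is.nan(agg$value)] <- NA_real_
  trt <- sort(unique(agg$treatment_id))
  env <- sort(unique(agg$environment_id))
  mat <- matrix(NA_real_, length(trt), length(env),
                dimnames = list(trt, env))
  mat[cbind(match(agg$treatment_id, trt), match(agg$environment_id, env))] <-
    agg$value
  empty <- rowSums(!is.na(mat)) == 0
  if (any(empty)) {
    stop("treatment(s) with no data: ",
         paste(trt[empty], collapse = ", "), call. = FALSE)
  }
  sparse <- rowMeans(is.na(mat)) > 0.5
  if (any(sparse)) {
    warning("treatment(s) missing from >50% of environments: ",
            paste(trt[sparse], collapse = ", "), call. = FALSE)
  }
  mat
}

#' Read a sensitivity-parameter range table
#'
#' Expects columns `name`, `min`, `max` (and optionally `unit`), one row
#' per model parameter, as used to build sensitivity designs.
#'
#' @param path CSV path.
#' @return A tibble of class `param_ranges`, ordered as in the file.
#' @export
read_parameter_ranges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  parameter_ranges(df)
}

#' Construct a validated parameter-range table
#'
#' @param df Data frame with columns `name`, `min`, `max` and optionally
#'   `unit`.
#' @return A tibble of class `param_ranges`.
#' @export
parameter_ranges <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("name", "min", "max")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$min <- as.numeric(df$min)
  df$max <- as.numeric(df$max)
  if (!"unit" %in% names(df)) df$unit <- NA_character_
  if (anyDuplicated(df$name)) {
    stop("duplicate parameter name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$min < df$max))
  if (length(bad) > 0) {
    stop("min must be strictly less than max for parameter(s): ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(df[c("name", "min", "max", "unit")],
            class = c("param_ranges", class(df)))
}

#' Bundled long-term-experiment fixtures
#'
#' Accessors for the summary tables shipped with the package: per-treatment
#' stability summaries (mean, SD, adjusted CV and sustainable yield index
#' for both observed and model-predicted grain yields) for the Sadore
#' pearl-millet and Ndiaye rice long-term experiments, and the parameter
#' ranges used for the crop-model sensitivity designs.
#'
#' @param dataset `"ndiaye_rice"` or `"sadore_millet"`.
#' @return `load_lte_stability()`: a tibble with one row per treatment and
#'   columns `n`, `mean_obs`, `sd_obs`, `mean_pred`, `sd_pred`, `acv_obs`,
#'   `acv_pred`, `syi_obs`, `syi_pred` plus design factors.
#' @export
load_lte_stability <- function(dataset = c("ndiaye_rice", "sadore_millet")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_stability.csv"),
                      package = "yieldstab", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname load_lte_stability
#' @param crop `"rice"` or `"millet"`.
#' @return `load_crop_parameter_ranges()`: a `param_ranges` tibble.
#' @export
load_crop_parameter_ranges <- function(crop = c("rice", "millet")) {
  crop <- match.arg(crop)
  path <- system.file("extdata", paste0(crop, "_parameter_ranges.csv"),
                      package = "yieldstab", mustWork = TRUE)
  read_parameter_ranges(path)
}
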