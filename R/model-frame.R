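#' Prepare a standardized model frame for the regressions
#'
#' Applies the transformations used throughout the analyses: natural-log
#' transform of positive continuous variables, absolute values of the
#' latitudinal and longitudinal midpoints, and z-score standardization
#' (mean 0, sd 1) of predictors so effect sizes are comparable. Transformed
#' columns are renamed `log_*` / `abs_*`; a full transform manifest is kept
#' in the `"transforms"` attribute. The island/continent setting becomes a
#' 0/1 `island` column (and the original factor column is carried along).
#'
#' @param data Species data frame (row names or `tip` column = tip labels).
#' @param log_columns Columns to natural-log transform (must be positive).
#' @param abs_columns Columns replaced by absolute values.
#' @param standardize Character vector of output columns to z-score, or
#'   `TRUE` to standardize all transformed continuous predictors (the
#'   response, if named in `response`, is never standardized).
#' @param response Response column name, exempt from standardization.
#' @param setting_column Name of the island/continent column (skipped when
#'   absent).
#' @return Data frame with transformed columns plus untouched ones;
#'   attribute `transforms` records what was done to each column.
#' @export
prepare_model_frame <- function(data,
                                log_columns = c("range_size", "shape_index",
                                                "body_mass", "hwi", "dr"),
                                abs_columns = c("lat_midpoint",
                                                "lon_midpoint"),
                                standardize = TRUE,
                                response = "log_dr",
                                setting_column = "setting") {
  if (!"tip" %in% names(data) && !is.null(rownames(data)))
    data$tip <- rownames(data)
  log_columns <- intersect(log_columns, names(data))
  abs_columns <- intersect(abs_columns, names(data))
  out <- data
  manifest <- list()
  for (cl in log_columns) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("non-positive value in '", cl, "' for species: ",
           paste(utils::head(data$tip[bad], 5), collapse = ", "))
    nm <- paste0("log_", cl)
    out[[nm]] <- log(v)
    manifest[[nm]] <- list(source = cl, transform = "natural log")
  }
  for (cl in abs_columns) {
    nm <- paste0("abs_", sub("_midpoint$", "", cl))
    out[[nm]] <- abs(data[[cl]])
    manifest[[nm]] <- list(source = cl, transform = "absolute value")
  }
  if (setting_column %in% names(data)) {
    out$island <- as.numeric(data[[setting_column]] == "island")
    manifest$island <- list(source = setting_column,
                            transform = "indicator (island = 1)")
  }
  cand <- c(names(manifest))
  targets <- if (isTRUE(standardize)) setdiff(cand, c(response, "island"))
             else intersect(standardize %||% character(0), names(out))
  for (nm in targets) {
    v <- out[[nm]]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("cannot standardize constant '", nm, "'")
    out[[nm]] <- (v - m) / s
    manifest[[nm]]$standardized <- c(center = m, scale = s)
  }
  attr(out, "transforms") <- manifest
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model frame as CSV with a transform-manifest sidecar
#'
#' The frame goes to `<path>.csv` and the transform metadata (source
#' column, transform applied, standardization center/scale) to
#' `<path>_transforms.json`.
#'
#' @param frame Output of [prepare_model_frame()].
#' @param path Output path stem (no extension).
#' @return Invisibly, the two file paths.
#' @export
write_model_frame <- function(frame, path) {
  csv <- paste0(path, ".csv")
  man <- paste0(path, "_transforms.json")
  utils::write.csv(frame, csv, row.names = FALSE)
  jsonlite::write_json(attr(frame, "transforms") %||% list(), man,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(frame = csv, manifest = man))
}
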