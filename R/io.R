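# Text-format I/O: visit panels as CSV/TSV with empty fields for missing
# values; axis models, transform specs and clinical references as versioned
# JSON with loadings at full precision.

#' Read a cohort visit panel from CSV/TSV
#'
#' @param path file path; tab-delimited when the extension is .tsv.
#' @param markers optional expected marker columns; unknown extra marker-like
#'   columns only produce a warning.
#' @return validated \code{cohort_panel} data.frame; attribute
#'   \code{io_summary} carries row and missingness counts.
#' @export
read_panel <- function(path, markers = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  panel <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  req <- c("cohort", "subject", "visit", "age", "sex")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel schema error: missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  validate_panel(panel)
  if (!is.null(markers)) {
    known <- c(req, "death_age", "censor_age", "frailty", "comorbidity", "diabetes",
               "race", "education", "village", markers)
    extra <- setdiff(names(panel), known)
    if (length(extra)) warning("unknown column(s): ", paste(extra, collapse = ", "))
  }
  mk <- intersect(marker_reference()$marker, names(panel))
  attr(panel, "io_summary") <- list(
    rows = nrow(panel),
    individuals = length(unique(paste(panel$cohort, panel$subject))),
    missing_cells = if (length(mk)) sum(is.na(panel[, mk])) else 0L)
  class(panel) <- c("cohort_panel", "data.frame")
  panel
}

#' Write a cohort panel as CSV (missing values as empty fields)
#' @param panel data.frame.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize an axis model to versioned JSON
#' @param model \code{axis_model}.
#' @param path output path.
#' @export
write_axis_model <- function(model, path) {
  stopifnot(inherits(model, "axis_model"))
  obj <- list(format = "albunemia/axis_model", version = "1",
              markers = model$markers,
              loadings = apply(model$loadings, 2L, identity, simplify = FALSE),
              eigenvalues = model$eigenvalues, var_fraction = model$var_fraction,
              center = model$center, scale = model$scale,
              orientation = model$orientation, source = model$source, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an axis model from JSON
#' @param path file written by \code{\link{write_axis_model}}.
#' @return \code{axis_model}.
#' @export
read_axis_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "albunemia/axis_model"))
    stop("not an axis model file: ", path, call. = FALSE)
  L <- do.call(cbind, obj$loadings)
  rownames(L) <- obj$markers
  orientation <- lapply(seq_len(ncol(L)), function(k) {
    o <- obj$orientation[k, ]
    list(reference = o$reference, flipped = o$flipped)
  })
  structure(list(markers = obj$markers, loadings = L,
                 eigenvalues = obj$eigenvalues, var_fraction = obj$var_fraction,
                 center = stats::setNames(obj$center, obj$markers),
                 scale = stats::setNames(obj$scale, obj$markers),
                 orientation = orientation, source = obj$source, n = obj$n),
            class = "axis_model")
}

#' Serialize a transform spec to versioned JSON
#' @param spec \code{transform_spec}.
#' @param path output path.
#' @export
write_transform_spec <- function(spec, path) {
  stopifnot(inherits(spec, "transform_spec"))
  obj <- list(format = "albunemia/transform_spec", version = spec$version,
              markers = spec$markers, sex_stratified = spec$sex_stratified,
              table = spec$table)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a transform spec from JSON
#' @param path file written by \code{\link{write_transform_spec}}.
#' @return \code{transform_spec}.
#' @export
read_transform_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "albunemia/transform_spec"))
    stop("not a transform spec file: ", path, call. = FALSE)
  structure(list(table = as.data.frame(obj$table), markers = obj$markers,
                 sex_stratified = as.character(obj$sex_stratified %||% character()),
                 version = obj$version),
            class = "transform_spec")
}

#' Serialize a clinical scoring reference (model + spec + training scores)
#' @param reference \code{clinical_reference}.
#' @param path output path.
#' @export
write_clinical_reference <- function(reference, path) {
  stopifnot(inherits(reference, "clinical_reference"))
  obj <- list(format = "albunemia/clinical_reference", version = "1",
              markers = reference$markers,
              model = list(markers = reference$model$markers,
                           loadings = apply(reference$model$loadings, 2L, identity, simplify = FALSE),
                           eigenvalues = reference$model$eigenvalues,
                           var_fraction = reference$model$var_fraction,
                           center = reference$model$center, scale = reference$model$scale,
                           orientation = reference$model$orientation,
                           source = reference$model$source, n = reference$model$n),
              spec = list(version = reference$spec$version, markers = reference$spec$markers,
                          sex_stratified = reference$spec$sex_stratified,
                          table = reference$spec$table),
              training_scores = reference$training_scores)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a clinical scoring reference from JSON
#' @param path file written by \code{\link{write_clinical_reference}}.
#' @return \code{clinical_reference}.
#' @export
read_clinical_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "albunemia/clinical_reference"))
    stop("not a clinical reference file: ", path, call. = FALSE)
  L <- do.call(cbind, obj$model$loadings)
  rownames(L) <- obj$model$markers
  model <- structure(list(markers = obj$model$markers, loadings = L,
                          eigenvalues = obj$model$eigenvalues,
                          var_fraction = obj$model$var_fraction,
                          center = stats::setNames(obj$model$center, obj$model$markers),
                          scale = stats::setNames(obj$model$scale, obj$model$markers),
                          orientation = lapply(seq_len(ncol(L)), function(k)
                            list(reference = obj$model$orientation[k, ]$reference,
                                 flipped = obj$model$orientation[k, ]$flipped)),
                          source = obj$model$source, n = obj$model$n),
                     class = "axis_model")
  spec <- structure(list(table = as.data.frame(obj$spec$table), markers = obj$spec$markers,
                         sex_stratified = as.character(obj$spec$sex_stratified %||% character()),
                         version = obj$spec$version),
                    class = "transform_spec")
  structure(list(model = model, spec = spec, markers = obj$markers,
                 training_scores = obj$training_scores),
            class = "clinical_reference")
}

#' Export an importance profile as CSV (descending weight order)
#' @param profile \code{importance_profile}.
#' @param path output path.
#' @export
write_importance <- function(profile, path) {
  utils::write.csv(data.frame(marker = names(profile), weight = as.numeric(profile)),
                   path, row.names = FALSE)
  invisible(path)
}
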