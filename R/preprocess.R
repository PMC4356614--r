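# Transformation protocol: per-cohort normality transforms (identity / log /
# sqrt chosen by skewness minimization), sex-stratified standardization for
# flagged markers (estradiol by default), z-standardization, and complete-case
# extraction. Transforms are fitted separately within each cohort because
# native units and scales differ across cohorts.

#' Choose a normality transform for one marker sample
#'
#' Picks the family among identity, log(x + shift) and sqrt(x + shift) that
#' minimizes absolute sample skewness. The shift is \code{max(0, eps -
#' min(x))} with \code{eps = 1e-6 * sd(x)}, just enough to make all values
#' strictly positive. Ties favor the least aggressive family
#' (identity, then sqrt, then log).
#'
#' @param values numeric vector in native units (NAs dropped); needs >= 10
#'   non-missing, non-constant values.
#' @return list with \code{family} ("identity"/"log"/"sqrt") and \code{shift}.
#' @export
choose_transform <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) stop("need at least 10 non-missing values to choose a transform", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant input: no transform can be chosen", call. = FALSE)
  shift <- max(0, 1e-6 * stats::sd(x) - min(x))
  cand <- c(identity = abs(sample_skewness(x)),
            sqrt = abs(sample_skewness(sqrt(x + shift))),
            log = abs(sample_skewness(log(x + shift))))
  fam <- names(cand)[which.min(cand)]  # which.min keeps first on ties: identity < sqrt < log
  list(family = fam, shift = if (fam == "identity") 0 else shift)
}

apply_family <- function(x, family, shift) {
  switch(family,
    identity = x,
    log = log(x + shift),
    sqrt = sqrt(x + shift),
    stop("unknown transform family: ", family, call. = FALSE)
  )
}

#' Fit a per-cohort transformation and standardization spec
#'
#' For every (cohort, marker) pair: chooses the normality transform on the
#' pooled cohort values, then computes centers and scales of the transformed
#' values — within sex strata for flagged markers (estradiol by default), so
#' each individual is scored relative to members of their sex. Scales use the
#' n-1 denominator.
#'
#' @param panel cohort panel data.frame (columns \code{cohort}, \code{sex},
#'   markers in native units).
#' @param markers character vector of marker columns to fit.
#' @param sex_stratified markers standardized within sex.
#' @return object of class \code{transform_spec}: a table with one row per
#'   (cohort, marker, stratum) holding family, shift, center and scale.
#' @export
fit_transform_spec <- function(panel, markers = intersect(marker_reference()$marker, names(panel)),
                               sex_stratified = "estradiol") {
  absent <- setdiff(markers, names(panel))
  if (length(absent)) stop("marker(s) absent from panel: ", paste(absent, collapse = ", "), call. = FALSE)
  sex_stratified <- intersect(sex_stratified, markers)
  rows <- list()
  for (co in unique(panel$cohort)) {
    sub <- panel[panel$cohort == co, , drop = FALSE]
    for (mk in markers) {
      tr <- choose_transform(sub[[mk]])
      strata <- if (mk %in% sex_stratified) {
        lv <- unique(sub$sex[!is.na(sub[[mk]])])
        if (!length(lv)) stop("no usable sex stratum for flagged marker '", mk,
                              "' in cohort '", co, "'", call. = FALSE)
        sort(lv)
      } else "all"
      for (st in strata) {
        v <- if (st == "all") sub[[mk]] else sub[[mk]][sub$sex == st]
        tv <- apply_family(v[is.finite(v)], tr$family, tr$shift)
        if (length(tv) < 2L || stats::sd(tv) == 0)
          stop("cannot standardize marker '", mk, "' in cohort '", co,
               "', stratum '", st, "': degenerate values", call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = co, marker = mk, family = tr$family, shift = tr$shift,
          stratum = st, center = mean(tv), scale = stats::sd(tv),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(list(table = out, markers = markers, sex_stratified = sex_stratified,
                 version = "1"), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec> ", length(x$markers), " markers, ",
      length(unique(x$table$cohort)), " cohort(s); sex-stratified: ",
      if (length(x$sex_stratified)) paste(x$sex_stratified, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Standardize a panel with a fitted spec
#'
#' Maps each native value to \code{(f(x + shift) - center) / scale} using the
#' cohort- and stratum-appropriate parameters; missing values stay missing.
#' On the fitting data every (cohort, marker) column has mean 0 and SD 1.
#'
#' @param panel cohort panel data.frame.
#' @param spec a \code{\link{fit_transform_spec}} result.
#' @return object of class \code{standardized_matrix}: list with \code{values}
#'   (numeric observation x marker matrix), \code{meta} (the panel's
#'   non-marker columns), \code{markers}, and the \code{spec}.
#' @export
standardize <- function(panel, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  mk <- spec$markers
  absent <- setdiff(mk, names(panel))
  if (length(absent)) stop("marker(s) absent from panel: ", paste(absent, collapse = ", "), call. = FALSE)
  tab <- spec$table
  vals <- matrix(NA_real_, nrow(panel), length(mk), dimnames = list(NULL, mk))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    sel <- panel$cohort == r$cohort &
      (r$stratum == "all" | panel$sex == r$stratum)
    x <- panel[[r$marker]][sel]
    ok <- is.finite(x)
    if (r$family == "log" && any(x[ok] <= -r$shift))
      stop("non-positive value under log transform for marker '", r$marker,
           "' in cohort '", r$cohort, "'", call. = FALSE)
    if (r$family == "sqrt" && any(x[ok] < -r$shift)) {
      # new data below the fitted sqrt domain become missing (and are then
      # dropped by complete-case extraction) rather than silent NaN
      n_bad <- sum(x[ok] < -r$shift)
      warning(n_bad, " value(s) below the sqrt-transform domain for marker '",
              r$marker, "' in cohort '", r$cohort, "' set missing", call. = FALSE)
      ok <- ok & x >= -r$shift
    }
    z <- rep(NA_real_, length(x))
    z[ok] <- (apply_family(x[ok], r$family, r$shift) - r$center) / r$scale
    vals[sel, r$marker] <- z
  }
  meta <- panel[, setdiff(names(panel), mk), drop = FALSE]
  structure(list(values = vals, meta = meta, markers = mk, spec = spec),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("<standardized_matrix> ", nrow(x$values), " observations x ",
      ncol(x$values), " markers (", sum(!stats::complete.cases(x$values)),
      " incomplete rows)\n", sep = "")
  invisible(x)
}

#' Extract complete cases for a marker subset
#'
#' Principal components cannot be computed with missing cells, so analyses
#' retain only rows complete on the markers they use.
#'
#' @param sm a \code{standardized_matrix}.
#' @param markers marker subset (default: all markers of \code{sm}).
#' @return list with \code{matrix} (the filtered \code{standardized_matrix},
#'   restricted to \code{markers}) and \code{counts} (per-cohort individuals
#'   and visits retained).
#' @export
complete_cases <- function(sm, markers = sm$markers) {
  stopifnot(inherits(sm, "standardized_matrix"))
  bad <- setdiff(markers, sm$markers)
  if (length(bad)) stop("marker(s) not in matrix: ", paste(bad, collapse = ", "), call. = FALSE)
  v <- sm$values[, markers, drop = FALSE]
  keep <- stats::complete.cases(v)
  if (!any(keep)) stop("no complete observations for the requested markers; PCA impossible", call. = FALSE)
  meta <- sm$meta[keep, , drop = FALSE]
  counts <- do.call(rbind, lapply(split(meta, meta$cohort), function(d) {
    data.frame(cohort = d$cohort[1], individuals = length(unique(d$subject)),
               visits = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  out <- structure(list(values = v[keep, , drop = FALSE], meta = meta,
                        markers = markers, spec = sm$spec),
                   class = "standardized_matrix")
  list(matrix = out, counts = counts)
}

subset_rows <- function(sm, idx) {
  structure(list(values = sm$values[idx, , drop = FALSE],
                 meta = sm$meta[idx, , drop = FALSE],
                 markers = sm$markers, spec = sm$spec),
            class = "standardized_matrix")
}
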