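# Principal-axis engine. The decomposition is computed via the singular value
# decomposition of the (re-centered, unit-scaled) standardized matrix, which
# is the correlation-scale PCA; tests cross-check it against an explicit
# eigendecomposition of the sample correlation matrix. Axis signs from the
# solver are made deterministic by forcing the largest-|loading| marker
# positive; scientific orientation (scores increasing with age) is applied
# separately by orient_axis().

#' Fit principal axes of a standardized marker matrix
#'
#' @param sm complete-case \code{standardized_matrix}.
#' @return object of class \code{axis_model}: ordered \code{markers},
#'   orthonormal \code{loadings} (markers x axes), \code{eigenvalues},
#'   \code{var_fraction} (eigenvalue / number of markers), fit-time column
#'   \code{center}/\code{scale} (applied before projection so that
#'   self-projection reproduces fit-time scores exactly), an
#'   \code{orientation} record per axis, \code{source} label and \code{n}.
#' @export
fit_axes <- function(sm, source = "fit") {
  stopifnot(inherits(sm, "standardized_matrix"))
  X <- sm$values
  if (anyNA(X)) stop("matrix has missing cells; extract complete cases first", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 rows to fit axes", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  sv <- svd(Xs, nu = 0)
  eig <- sv$d^2 / (nrow(X) - 1L)
  L <- sv$v
  dimnames(L) <- list(colnames(X), paste0("axis", seq_len(ncol(L))))
  # deterministic sign: largest-|loading| marker positive
  orientation <- vector("list", ncol(L))
  for (k in seq_len(ncol(L))) {
    top <- which.max(abs(L[, k]))
    if (L[top, k] < 0) L[, k] <- -L[, k]
    orientation[[k]] <- list(reference = "sign-rule", flipped = FALSE)
  }
  structure(list(markers = colnames(X), loadings = L, eigenvalues = eig,
                 var_fraction = eig / ncol(X), center = ctr, scale = sds,
                 orientation = orientation, source = source, n = nrow(X),
                 spec_version = sm$spec$version %||% NA_character_),
            class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat("<axis_model> '", x$source, "': ", length(x$markers), " markers, n = ", x$n,
      "\n  variance fractions: ",
      paste(sprintf("%.3f", utils::head(x$var_fraction, 4)), collapse = ", "),
      ", ...\n", sep = "")
  invisible(x)
}

#' Project a matrix onto a fitted axis
#'
#' Scores are the inner products of (fit-time centered and scaled) rows with
#' the axis loadings. Projecting the fitting matrix reproduces the fit-time
#' scores; projecting another dataset re-applies the loadings to new data
#' (cross-population replication).
#'
#' @param model \code{axis_model}.
#' @param sm complete-case \code{standardized_matrix} whose marker set matches
#'   the model's by name (any order).
#' @param axis axis index.
#' @return object of class \code{axis_scores}: numeric \code{score} vector
#'   plus the row \code{meta}, the model \code{source} and the \code{axis}.
#' @export
project <- function(model, sm, axis = 1L) {
  stopifnot(inherits(model, "axis_model"), inherits(sm, "standardized_matrix"))
  d1 <- setdiff(model$markers, sm$markers); d2 <- setdiff(sm$markers, model$markers)
  if (length(d1) || length(d2))
    stop("marker sets differ; model-only: {", paste(d1, collapse = ", "),
         "}, matrix-only: {", paste(d2, collapse = ", "), "}", call. = FALSE)
  X <- sm$values[, model$markers, drop = FALSE]
  if (anyNA(X)) stop("matrix has missing cells; extract complete cases first", call. = FALSE)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  s <- drop(Xs %*% model$loadings[, axis])
  structure(list(score = s, meta = sm$meta, source = model$source, axis = axis),
            class = "axis_scores")
}

#' Orient an axis so scores increase with age
#'
#' Flips the axis sign iff the Pearson correlation between the scores and age
#' is negative. When ages are absent or the correlation is indistinguishable
#' from zero (|r| < 1e-6), falls back to making the largest-|loading| marker
#' positive. Idempotent.
#'
#' @param model \code{axis_model}.
#' @param scores optional \code{axis_scores} for the same axis.
#' @param ages ages aligned with \code{scores} (default: the scores' meta age).
#' @param axis axis index.
#' @return the (possibly sign-flipped) model with its orientation record updated.
#' @export
orient_axis <- function(model, scores = NULL, ages = NULL, axis = 1L) {
  stopifnot(inherits(model, "axis_model"))
  flip <- FALSE; ref <- "sign-rule"
  if (!is.null(scores)) {
    s <- if (inherits(scores, "axis_scores")) scores$score else as.numeric(scores)
    if (is.null(ages) && inherits(scores, "axis_scores")) ages <- scores$meta$age
    if (!is.null(ages)) {
      if (length(ages) != length(s)) stop("scores and ages differ in length", call. = FALSE)
      r <- stats::cor(s, ages)
      if (is.finite(r) && abs(r) >= 1e-6) {
        flip <- r < 0
        ref <- "age-correlation"
      }
    }
  }
  if (ref == "sign-rule") {
    top <- which.max(abs(model$loadings[, axis]))
    flip <- model$loadings[top, axis] < 0
  }
  if (flip) model$loadings[, axis] <- -model$loadings[, axis]
  model$orientation[[axis]] <- list(reference = ref, flipped = flip)
  model
}

#' Loading-importance profile of an axis
#'
#' Importance of marker m on axis k is |loading_mk| divided by the sum of the
#' absolute values of all loadings on axis k: non-negative weights summing to
#' one, returned in descending order.
#'
#' @param model \code{axis_model}.
#' @param axis axis index.
#' @return object of class \code{importance_profile}: named numeric vector of
#'   weights (descending) with attribute \code{axis}.
#' @export
importance <- function(model, axis = 1L) {
  stopifnot(inherits(model, "axis_model"))
  if (axis < 1L || axis > ncol(model$loadings)) stop("invalid axis index", call. = FALSE)
  l <- model$loadings[, axis]
  w <- abs(l) / sum(abs(l))
  w <- sort(w, decreasing = TRUE)
  structure(w, axis = axis, class = c("importance_profile", "numeric"))
}

#' Informativeness of an axis relative to the equal-share threshold
#'
#' An axis is conventionally called informative when it explains more variance
#' than any single standardized marker, i.e. more than 1/p of the total. This
#' returns the ratio of the axis's variance fraction to that threshold (e.g. a
#' fraction of 0.101 over 43 markers is 4.3 times the threshold).
#'
#' @param var_fraction variance fraction (or an \code{axis_model}).
#' @param n_markers marker count p (ignored when a model is given).
#' @param axis axis index when a model is given.
#' @return ratio of the variance fraction to 1/p.
#' @export
informative_ratio <- function(var_fraction, n_markers = NULL, axis = 1L) {
  if (inherits(var_fraction, "axis_model")) {
    m <- var_fraction
    return(m$var_fraction[axis] * length(m$markers))
  }
  var_fraction * n_markers
}

#' Convenience: fit, age-orient and score one axis
#'
#' @param sm complete-case \code{standardized_matrix}.
#' @param axis axis index.
#' @param source label recorded on the model.
#' @return list with \code{model} (oriented) and \code{scores} on \code{sm}.
#' @export
principal_axis <- function(sm, axis = 1L, source = "fit") {
  m <- fit_axes(sm, source = source)
  s <- project(m, sm, axis)
  m <- orient_axis(m, s, sm$meta$age, axis = axis)
  list(model = m, scores = project(m, sm, axis))
}

#' First-axis summary of the anemia marker cluster
#'
#' Runs a PCA restricted to the anemia-related markers and returns oriented
#' first-axis scores, a single variable summarizing the strongly correlated
#' red-cell/iron markers.
#'
#' @param sm \code{standardized_matrix} containing the anemia markers
#'   (incomplete rows on those markers are dropped).
#' @param markers anemia marker names present in \code{sm}.
#' @return \code{axis_scores} on the complete-case rows.
#' @export
anemia_subaxis <- function(sm, markers = intersect(anemia_markers(), sm$markers)) {
  if (!length(markers)) stop("empty anemia marker set", call. = FALSE)
  cc <- complete_cases(sm, markers)
  principal_axis(cc$matrix, source = "anemia-subaxis")$scores
}

#' Greedy reduction of an axis to a small clinical marker set
#'
#' Backward elimination: repeatedly refits the PCA without each candidate
#' marker, orients the refit axis to correlate positively with the full-axis
#' scores, and drops the marker whose removal least reduces |r|, until the
#' target size is reached. Required markers are never dropped; forbidden
#' markers are dropped first, regardless of cost.
#'
#' @param model full \code{axis_model} (used for its axis-1 scores).
#' @param sm the complete-case \code{standardized_matrix} the model was fit on.
#' @param required markers that must stay.
#' @param forbidden markers that must go.
#' @param target_size number of markers to keep (>= 2).
#' @return list with \code{model} (refit, oriented \code{axis_model} on the
#'   reduced set), \code{r} (Pearson correlation of reduced-axis scores with
#'   the full-axis scores), and \code{path} (markers in drop order).
#' @export
reduce_axis <- function(model, sm, required = character(), forbidden = character(),
                        target_size = 14L) {
  stopifnot(inherits(model, "axis_model"), inherits(sm, "standardized_matrix"))
  if (length(intersect(required, forbidden)))
    stop("required and forbidden marker sets overlap", call. = FALSE)
  if (target_size < 2L) stop("target size must be >= 2", call. = FALSE)
  if (target_size < length(required))
    stop("target size smaller than the required marker set", call. = FALSE)
  full <- project(model, sm, 1L)$score
  keep <- model$markers
  path <- character()
  score_r <- function(markers) {
    sub <- structure(list(values = sm$values[, markers, drop = FALSE], meta = sm$meta,
                          markers = markers, spec = sm$spec), class = "standardized_matrix")
    m <- fit_axes(sub, source = "reduced")
    s <- project(m, sub, 1L)$score
    r <- stats::cor(s, full)
    if (r < 0) { m$loadings[, 1L] <- -m$loadings[, 1L]; s <- -s; r <- -r
                 m$orientation[[1L]] <- list(reference = "full-axis", flipped = TRUE) }
    list(model = m, r = r)
  }
  for (f in intersect(forbidden, keep)) { keep <- setdiff(keep, f); path <- c(path, f) }
  while (length(keep) > target_size) {
    cand <- setdiff(keep, required)
    if (!length(cand)) break
    rs <- vapply(cand, function(mk) score_r(setdiff(keep, mk))$r, 0)
    drop_mk <- cand[which.max(rs)]
    keep <- setdiff(keep, drop_mk)
    path <- c(path, drop_mk)
  }
  fin <- score_r(keep)
  list(model = fin$model, r = fin$r, path = path)
}

#' Build a clinical scoring reference
#'
#' Pools all cohorts into one population (cohort label "all"), fits the
#' transformation spec and the PCA on the given marker set, and orients the
#' first axis with age. The result is a self-contained reference that can
#' score new individuals from native-unit measurements.
#'
#' @param panel cohort panel data.frame in native units.
#' @param markers marker set (default the 14-marker clinical set).
#' @return object of class \code{clinical_reference}: \code{model}
#'   (axis_model), \code{spec} (transform_spec), \code{markers}, and
#'   \code{training_scores} (reference distribution for interpretation).
#' @export
clinical_reference <- function(panel, markers = marker_set("clinical-14")) {
  pooled <- panel
  pooled$cohort <- "all"
  spec <- fit_transform_spec(pooled, markers = markers)
  sm <- standardize(pooled, spec)
  cc <- complete_cases(sm, markers)
  pa <- principal_axis(cc$matrix, source = "clinical-reference")
  structure(list(model = pa$model, spec = spec, markers = markers,
                 training_scores = pa$scores$score),
            class = "clinical_reference")
}

#' Score individuals from native-unit measurements
#'
#' Transforms each measurement with the stored spec and projects on the stored
#' reduced axis. All reference markers are required: no partial scores.
#'
#' @param measurements named numeric vector (one individual) or data.frame
#'   with one column per reference marker.
#' @param reference a \code{\link{clinical_reference}}.
#' @return numeric score(s), one per individual.
#' @export
clinical_score <- function(measurements, reference) {
  stopifnot(inherits(reference, "clinical_reference"))
  df <- if (is.data.frame(measurements)) measurements
        else as.data.frame(as.list(measurements))
  missing_mk <- setdiff(reference$markers, names(df))
  if (length(missing_mk))
    stop("missing marker(s): ", paste(missing_mk, collapse = ", "), call. = FALSE)
  vals <- df[, reference$markers, drop = FALSE]
  if (anyNA(vals) || !all(vapply(vals, is.numeric, TRUE))) {
    bad <- reference$markers[vapply(vals, function(x) anyNA(x) || !is.numeric(x), TRUE)]
    stop("missing marker(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pan <- cbind(data.frame(cohort = "all", subject = sprintf("p%03d", seq_len(nrow(vals))),
                          visit = 1L, age = NA_real_, sex = NA_character_,
                          stringsAsFactors = FALSE), vals)
  sm <- standardize(pan, reference$spec)
  drop(project(reference$model, sm, 1L)$score)
}
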