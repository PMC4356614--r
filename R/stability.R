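# Axis stability across populations, demographic subsets, and random
# mutually exclusive partitions. Each subset's axis is refit, independently
# age-oriented, and re-projected onto the full matrix, so pairwise score
# correlations are well defined even across disjoint subsets. The same-axis
# rule: versions correlating above 0.9 are treated as measuring one
# phenomenon.

#' Demographic subset scheme
#'
#' Partitions observations by the level combinations of the requested
#' variables. Ages are banded at <65, 65-80, 80+ when "age" is requested.
#'
#' @param meta data.frame of row metadata (e.g. \code{sm$meta}).
#' @param variables column names; "age" is banded automatically.
#' @param min_size subsets smaller than this are flagged (downstream PCA skips
#'   them rather than failing: demographic strata can be tiny).
#' @return object of class \code{subset_scheme}: \code{labels} (per row),
#'   \code{sizes}, \code{kind}, \code{seed}, \code{warnings}.
#' @export
demographic_subsets <- function(meta, variables, min_size = NULL) {
  absent <- setdiff(variables, c(names(meta), "age"))
  if (length(absent)) stop("variable(s) absent: ", paste(absent, collapse = ", "), call. = FALSE)
  cols <- lapply(variables, function(v) {
    if (v == "age") as.character(cut(meta$age, breaks = c(-Inf, 65, 80, Inf),
                                     labels = c("<65", "65-80", "80+"), right = FALSE))
    else as.character(meta[[v]])
  })
  labels <- do.call(paste, c(cols, sep = ":"))
  sizes <- table(labels)
  if (length(sizes) < 2L)
    stop("variable(s) yield fewer than 2 non-empty levels", call. = FALSE)
  warn <- character()
  if (!is.null(min_size)) {
    small <- names(sizes)[sizes < min_size]
    if (length(small))
      warn <- paste0("subset(s) smaller than ", min_size, ": ", paste(small, collapse = ", "))
  }
  structure(list(name = paste(variables, collapse = "+"), labels = labels,
                 sizes = c(sizes), kind = "demographic", seed = NA_integer_,
                 warnings = warn),
            class = "subset_scheme")
}

#' Random mutually exclusive subsets
#'
#' Uniformly random partition of n observations into k groups whose sizes
#' differ by at most one; reproducible under the seed.
#'
#' @param n_obs number of observations.
#' @param k number of groups (>= 2).
#' @param seed integer seed.
#' @return \code{subset_scheme} with kind "random-exclusive".
#' @export
random_exclusive_subsets <- function(n_obs, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n_obs) stop("k exceeds the number of observations", call. = FALSE)
  base <- n_obs %/% k; extra <- n_obs %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  lab <- sprintf("s%02d", seq_len(k))
  labels <- with_seed(seed, sample(rep(lab, times = sizes)))
  structure(list(name = sprintf("random-%d", k), labels = labels,
                 sizes = stats::setNames(sizes, lab), kind = "random-exclusive",
                 seed = as.integer(seed), warnings = character()),
            class = "subset_scheme")
}

#' Fit an axis within every subset and re-project onto the full matrix
#'
#' @param sm complete-case \code{standardized_matrix}.
#' @param scheme \code{subset_scheme} aligned with the rows of \code{sm}.
#' @param axis axis index.
#' @return list with \code{models}, \code{scores} (each an
#'   \code{axis_scores} on the full matrix), and \code{skipped} (named reasons
#'   for subsets too small to fit: fewer rows than markers + 1).
#' @export
replicate_axes <- function(sm, scheme, axis = 1L) {
  stopifnot(inherits(sm, "standardized_matrix"), inherits(scheme, "subset_scheme"))
  if (length(scheme$labels) != nrow(sm$values))
    stop("scheme does not align with the matrix rows", call. = FALSE)
  p <- length(sm$markers)
  models <- list(); scores <- list(); skipped <- character()
  for (lab in names(scheme$sizes)) {
    idx <- which(scheme$labels == lab)
    if (length(idx) < p + 1L) {
      skipped[lab] <- sprintf("%d rows < %d markers + 1", length(idx), p)
      next
    }
    sub <- subset_rows(sm, idx)
    m <- fit_axes(sub, source = lab)
    s_sub <- project(m, sub, axis)
    m <- orient_axis(m, s_sub, sub$meta$age, axis = axis)
    models[[lab]] <- m
    scores[[lab]] <- project(m, sm, axis)
  }
  if (!length(models)) stop("no subset large enough to fit an axis", call. = FALSE)
  list(models = models, scores = scores, skipped = skipped)
}

#' Pairwise correlations among axis versions
#'
#' @param scores list of \code{axis_scores} (or numeric vectors) computed on
#'   the same rows, each already oriented.
#' @param threshold same-axis threshold recorded in the report.
#' @return object of class \code{stability_report}: the symmetric correlation
#'   \code{matrix}, \code{summary} (mean, min, interquartile range of the
#'   strict upper triangle), \code{n_pairs}, \code{threshold}, \code{sizes}.
#' @export
pairwise_axis_correlations <- function(scores, threshold = 0.9) {
  v <- lapply(scores, function(s) if (inherits(s, "axis_scores")) s$score else as.numeric(s))
  if (length(v) < 2L) stop("need at least 2 score vectors", call. = FALSE)
  n <- lengths(v)
  if (length(unique(n)) != 1L) stop("score vectors differ in length (row mismatch)", call. = FALSE)
  M <- stats::cor(do.call(cbind, v))
  labs <- names(scores) %||% paste0("v", seq_along(v))
  dimnames(M) <- list(labs, labs)
  off <- M[upper.tri(M)]
  structure(list(matrix = M,
                 summary = list(mean = mean(off), min = min(off),
                                iqr = stats::quantile(off, c(0.25, 0.75), names = FALSE)),
                 n_pairs = length(off), threshold = threshold,
                 sizes = stats::setNames(n, labs)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d versions, %d pairs; mean r = %.3f, min r = %.3f, IQR %.3f-%.3f\n",
              ncol(x$matrix), x$n_pairs, x$summary$mean, x$summary$min,
              x$summary$iqr[1], x$summary$iqr[2]))
  invisible(x)
}

#' Same-axis verdict
#'
#' TRUE iff every off-diagonal correlation exceeds the threshold — the
#' operational criterion that the versions measure one phenomenon.
#'
#' @param report \code{stability_report}.
#' @param threshold correlation threshold (default 0.9).
#' @return logical.
#' @export
same_axis <- function(report, threshold = 0.9) {
  stopifnot(inherits(report, "stability_report"))
  all(report$matrix[upper.tri(report$matrix)] > threshold)
}

#' Random-exclusive-subset stability null
#'
#' For each replicate: partition the rows into k random exclusive subsets, fit
#' the axis in each, re-project all versions onto the full matrix, and record
#' the mean, minimum and interquartile range of the pairwise correlations.
#' Characterizes how much axis versions can differ through sampling alone.
#'
#' @param sm complete-case \code{standardized_matrix}.
#' @param k subsets per replicate.
#' @param reps replicates.
#' @param seed integer seed; the whole summary is deterministic under it.
#' @param axis axis index.
#' @return object of class \code{null_distribution_summary}: per-replicate
#'   \code{mean}/\code{min}/\code{iqr_lo}/\code{iqr_hi} and grand summaries
#'   \code{mean_of_means}, \code{mean_of_minima}, \code{mean_iqr}.
#' @export
null_distribution <- function(sm, k = 10L, reps = 100L, seed = 1L, axis = 1L) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  seeds <- child_seeds(seed, reps)
  per <- lapply(seq_len(reps), function(i) {
    scheme <- random_exclusive_subsets(nrow(sm$values), k, seed = seeds[i])
    rep_ax <- tryCatch(replicate_axes(sm, scheme, axis = axis),
                       error = function(e) stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE))
    rp <- pairwise_axis_correlations(rep_ax$scores)
    c(mean = rp$summary$mean, min = rp$summary$min,
      iqr_lo = rp$summary$iqr[1], iqr_hi = rp$summary$iqr[2])
  })
  tab <- do.call(rbind, per)
  structure(list(replicates = reps, k = k, seed = as.integer(seed),
                 per_replicate = as.data.frame(tab),
                 mean_of_means = mean(tab[, "mean"]),
                 mean_of_minima = mean(tab[, "min"]),
                 mean_iqr = c(mean(tab[, "iqr_lo"]), mean(tab[, "iqr_hi"]))),
            class = "null_distribution_summary")
}

#' @export
print.null_distribution_summary <- function(x, ...) {
  cat(sprintf("<null_distribution_summary> %d replicates of %d exclusive subsets\n", x$replicates, x$k))
  cat(sprintf("  mean of means %.3f; mean of minima %.3f; mean IQR %.3f-%.3f\n",
              x$mean_of_means, x$mean_of_minima, x$mean_iqr[1], x$mean_iqr[2]))
  invisible(x)
}

#' Stability of loading-importance profiles
#'
#' @param profiles list of \code{\link{importance}} profiles over the same
#'   marker set.
#' @return list with \code{mean_abs_diff} (mean over version pairs of the mean
#'   per-marker |weight difference|) and \code{mean_rank_cor} (mean Spearman
#'   rank correlation of the weights).
#' @export
importance_stability <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  mk <- sort(names(profiles[[1L]]))
  for (p in profiles)
    if (!identical(sort(names(p)), mk)) stop("profiles cover different marker sets", call. = FALSE)
  W <- vapply(profiles, function(p) as.numeric(p[mk]), numeric(length(mk)))
  pairs <- utils::combn(ncol(W), 2L)
  dif <- apply(pairs, 2L, function(ij) mean(abs(W[, ij[1]] - W[, ij[2]])))
  rho <- apply(pairs, 2L, function(ij) stats::cor(W[, ij[1]], W[, ij[2]], method = "spearman"))
  list(mean_abs_diff = mean(dif), mean_rank_cor = mean(rho))
}
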