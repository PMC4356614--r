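# Age trajectories of axis scores: fixed linear/quadratic effects of age with
# a subject-level random intercept (random slopes/quadratics are deliberately
# not offered). Estimation is REML via nlme::lme with likelihood-based 95%
# intervals; populations where every subject contributes a single visit fall
# back to an ordinary cross-sectional least-squares fit, with the method
# recorded on the result.

#' Fit a population age trajectory of axis scores
#'
#' @param scores numeric axis scores (or an \code{axis_scores} object).
#' @param ages visit ages in years, aligned with scores.
#' @param subjects subject identifiers, aligned with scores.
#' @param form "quadratic" (default) or "linear".
#' @param age_range optional length-2 window; observations outside it are
#'   dropped before fitting (e.g. a young-age linear re-fit).
#' @return object of class \code{trajectory_fit}: \code{fixed} (data.frame of
#'   term, estimate, lower, upper), \code{ranint_sd} (estimate, lower, upper),
#'   \code{sigma}, \code{vcov_fixed}, \code{n_obs}, \code{n_subjects},
#'   \code{method}, \code{form}, \code{age_range}, \code{degraded} (TRUE when
#'   a mixed fit fell back to fixed effects only).
#' @export
fit_trajectory <- function(scores, ages, subjects, form = c("quadratic", "linear"),
                           age_range = NULL) {
  form <- match.arg(form)
  s <- if (inherits(scores, "axis_scores")) scores$score else as.numeric(scores)
  if (length(s) != length(ages) || length(s) != length(subjects))
    stop("scores, ages and subjects must align", call. = FALSE)
  if (!all(is.finite(ages))) stop("ages must be finite", call. = FALSE)
  d <- data.frame(score = s, age = ages, age2 = ages^2,
                  subject = as.character(subjects), stringsAsFactors = FALSE)
  if (!is.null(age_range)) d <- d[d$age >= age_range[1] & d$age <= age_range[2], ]
  if (nrow(d) < 4L) stop("too few observations to fit a trajectory", call. = FALSE)
  fixed <- if (form == "quadratic") score ~ age + age2 else score ~ age
  longitudinal <- any(duplicated(d$subject))
  fit <- NULL; degraded <- FALSE
  if (longitudinal) {
    fit <- tryCatch(nlme::lme(fixed, random = ~ 1 | subject, data = d, method = "REML"),
                    error = function(e) NULL)
    if (is.null(fit)) degraded <- TRUE
  }
  if (is.null(fit)) {
    lmfit <- stats::lm(fixed, data = d)
    ci <- stats::confint(lmfit)
    est <- stats::coef(lmfit)
    fixed_tab <- data.frame(term = names(est), estimate = unname(est),
                            lower = ci[, 1], upper = ci[, 2], row.names = NULL)
    out <- list(fixed = fixed_tab,
                ranint_sd = c(estimate = 0, lower = NA_real_, upper = NA_real_),
                sigma = stats::sigma(lmfit), vcov_fixed = stats::vcov(lmfit),
                n_obs = nrow(d), n_subjects = length(unique(d$subject)),
                method = if (longitudinal) "least squares (mixed fit degraded)"
                         else "least squares (cross-sectional)",
                form = form, age_range = range(d$age), degraded = degraded)
    return(structure(out, class = "trajectory_fit"))
  }
  iv_f <- nlme::intervals(fit, which = "fixed")$fixed
  fixed_tab <- data.frame(term = rownames(iv_f), estimate = iv_f[, "est."],
                          lower = iv_f[, "lower"], upper = iv_f[, "upper"],
                          row.names = NULL)
  re_sd <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
  re_iv <- tryCatch({
    iv <- nlme::intervals(fit, which = "var-cov")$reStruct$subject
    c(estimate = iv[1, "est."], lower = iv[1, "lower"], upper = iv[1, "upper"])
  }, error = function(e) c(estimate = re_sd, lower = NA_real_, upper = NA_real_))
  structure(list(fixed = fixed_tab, ranint_sd = re_iv, sigma = fit$sigma,
                 vcov_fixed = stats::vcov(fit), n_obs = nrow(d),
                 n_subjects = length(unique(d$subject)),
                 method = "REML mixed model (nlme::lme)", form = form,
                 age_range = range(d$age), degraded = FALSE),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> ", x$form, " fixed effects, ", x$method, "\n", sep = "")
  print(x$fixed, digits = 4)
  cat(sprintf("  random-intercept SD %.3f; n = %d obs / %d subjects\n",
              x$ranint_sd[["estimate"]], x$n_obs, x$n_subjects))
  invisible(x)
}

#' Table 3-style export of a trajectory fit
#'
#' @param x \code{trajectory_fit}.
#' @param ... unused.
#' @return one-row data.frame with fixed intercept/slope/quadratic estimates
#'   and 95% bounds plus the random-intercept SD and its bounds.
#' @export
as.data.frame.trajectory_fit <- function(x, ...) {
  g <- function(term, col) {
    i <- match(term, x$fixed$term)
    if (is.na(i)) NA_real_ else x$fixed[[col]][i]
  }
  data.frame(
    intercept = g("(Intercept)", "estimate"), intercept_lci = g("(Intercept)", "lower"),
    intercept_uci = g("(Intercept)", "upper"),
    slope = g("age", "estimate"), slope_lci = g("age", "lower"), slope_uci = g("age", "upper"),
    quadratic = g("age2", "estimate"), quadratic_lci = g("age2", "lower"),
    quadratic_uci = g("age2", "upper"),
    ranint_sd = x$ranint_sd[["estimate"]], ranint_sd_lci = x$ranint_sd[["lower"]],
    ranint_sd_uci = x$ranint_sd[["upper"]],
    n_obs = x$n_obs, n_subjects = x$n_subjects, method = x$method,
    stringsAsFactors = FALSE
  )
}

#' Mean trajectory curve with a 95% band
#'
#' Draws fixed-effect parameter vectors from the normal approximation to the
#' fit, evaluates the trajectory on the age grid, and reports the pointwise
#' mean with the 2.5th/97.5th percentile band.
#'
#' @param fit \code{trajectory_fit}.
#' @param age_grid ages at which to evaluate; values outside the fit's age
#'   range are flagged with a warning (extrapolation).
#' @param n_draws parameter draws (warning below 100).
#' @param seed integer seed (band is deterministic under it).
#' @return data.frame: \code{age}, \code{estimate} (point-estimate curve),
#'   \code{mean}, \code{lower}, \code{upper}.
#' @export
trajectory_curve <- function(fit, age_grid, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (n_draws < 100L) warning("fewer than 100 draws: band will be noisy")
  if (any(age_grid < fit$age_range[1] - 1e-9 | age_grid > fit$age_range[2] + 1e-9))
    warning("age grid extends beyond the fitted age range (extrapolation)")
  X <- cbind(1, age_grid, if (fit$form == "quadratic") age_grid^2)
  beta <- fit$fixed$estimate
  draws <- with_seed(seed, MASS::mvrnorm(n_draws, beta, fit$vcov_fixed))
  curves <- draws %*% t(X)
  data.frame(age = age_grid,
             estimate = drop(X %*% beta),
             mean = colMeans(curves),
             lower = apply(curves, 2L, stats::quantile, 0.025),
             upper = apply(curves, 2L, stats::quantile, 0.975))
}

#' Residualize markers on a cubic spline of age
#'
#' Removes the age signal from each marker by regressing it on a cubic
#' B-spline basis of age (interior knots at age quantiles) and keeping the
#' residuals, optionally re-standardized to mean 0 / SD 1. Used to check that
#' an axis is not merely an age proxy.
#'
#' @param x numeric matrix (observations x markers) or a
#'   \code{standardized_matrix}.
#' @param ages ages aligned with the rows (default: the matrix's meta age).
#' @param n_knots interior knot count (default 5).
#' @param rescale re-standardize residuals (default TRUE).
#' @return object of the same kind as \code{x} with residualized values.
#' @export
age_adjust <- function(x, ages = NULL, n_knots = 5L, rescale = TRUE) {
  is_sm <- inherits(x, "standardized_matrix")
  M <- if (is_sm) x$values else as.matrix(x)
  if (is.null(ages) && is_sm) ages <- x$meta$age
  if (length(ages) != nrow(M)) stop("ages must align with the rows", call. = FALSE)
  if (stats::sd(ages) == 0) stop("age is constant: cannot build a spline basis", call. = FALSE)
  B <- splines::bs(ages, df = n_knots + 3L, degree = 3L)
  res <- stats::lm.fit(cbind(1, B), M)$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  colnames(res) <- colnames(M)
  if (rescale) {
    sds <- apply(res, 2L, stats::sd)
    sds[sds < 1e-12] <- 1
    res <- sweep(sweep(res, 2L, colMeans(res)), 2L, sds, "/")
  }
  if (is_sm) { x$values <- res; x } else res
}

#' Per-variable correlation with age
#'
#' Pearson r and two-sided p for each column against age. When an
#' \code{axis_model} is supplied, rows are ordered by descending |loading| on
#' its first axis (the conventional display order).
#'
#' @param values numeric matrix/data.frame of variables (or a single vector).
#' @param ages ages aligned with the rows.
#' @param model optional \code{axis_model} providing the ordering.
#' @return data.frame: \code{variable}, \code{r}, \code{p}.
#' @export
age_correlation_table <- function(values, ages, model = NULL) {
  M <- as.matrix(values)
  if (is.null(colnames(M))) colnames(M) <- paste0("v", seq_len(ncol(M)))
  if (nrow(M) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  out <- do.call(rbind, lapply(colnames(M), function(cn) {
    ok <- is.finite(M[, cn]) & is.finite(ages)
    ct <- stats::cor.test(M[ok, cn], ages[ok])
    data.frame(variable = cn, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(model)) {
    l <- abs(model$loadings[, 1L])
    ord <- order(-l[match(out$variable, names(l))], na.last = TRUE)
    out <- out[ord, ]
  }
  rownames(out) <- NULL
  out
}
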