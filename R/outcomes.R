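# Associations between axis scores and health outcomes, controlling for age.
# The mortality model is a Cox proportional-hazards fit with age as the
# timescale: every visit contributes an interval (entry age, exit age] with
# left truncation at the entry age and exit at the next visit (censored) or at
# death. Count outcomes (frailty 0-5, comorbidity 0-13) use linear or Poisson
# regression with a cubic age-spline control; binary disease flags use
# logistic regression, with ambiguous codes assigned to the positive category
# by default.

new_association <- function(outcome, family, effect, ci, p, n_obs, n_subjects,
                            n_events = NA_integer_, age_control, axis = "axis1",
                            extra = list()) {
  structure(c(list(outcome = outcome, family = family, effect = effect,
                   ci = ci, p = p, n_obs = n_obs, n_subjects = n_subjects,
                   n_events = n_events, age_control = age_control, axis = axis),
              extra),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  lab <- switch(x$family, cox = "HR", logistic = "OR", "beta")
  cat(sprintf("<association_result> %s (%s): %s = %.3f [%.3f, %.3f], p = %.3g; n = %d, events = %s\n",
              x$outcome, x$family, lab, x$effect, x$ci[1], x$ci[2], x$p,
              x$n_obs, ifelse(is.na(x$n_events), "-", x$n_events)))
  invisible(x)
}

#' Flatten an association result for CSV export
#' @param x \code{association_result}.
#' @param ... unused.
#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(outcome = x$outcome, family = x$family, axis = x$axis,
             effect = x$effect, lci = x$ci[1], uci = x$ci[2], p = x$p,
             n_obs = x$n_obs, n_subjects = x$n_subjects, n_events = x$n_events,
             age_control = x$age_control, stringsAsFactors = FALSE)
}

#' Build visit intervals for survival analysis
#'
#' One interval per visit: entry at the visit age; exit at the next visit age
#' (censored) or, for the last visit, at the death age (event) or censoring
#' age. Scores and covariates are taken at entry.
#'
#' @param panel cohort panel data.frame with columns \code{cohort},
#'   \code{subject}, \code{age}, \code{death_age} (NA when alive) and
#'   \code{censor_age}.
#' @param scores numeric vector aligned with the panel rows (entry scores).
#' @return data.frame: subject key, \code{entry}, \code{exit}, \code{event},
#'   \code{score} and the panel's remaining columns at entry.
#' @export
build_intervals <- function(panel, scores = NULL) {
  need <- c("subject", "age", "death_age", "censor_age")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  key <- if ("cohort" %in% names(panel)) paste(panel$cohort, panel$subject) else panel$subject
  ord <- order(key, panel$age)
  panel <- panel[ord, , drop = FALSE]
  key <- key[ord]
  if (!is.null(scores)) scores <- scores[ord]
  nxt <- c(panel$age[-1], NA)
  last <- key != c(key[-1], "")
  death <- panel$death_age
  if (any(!is.na(death) & !last & death < nxt - 1e-9))
    stop("death age precedes a recorded subsequent visit (data inconsistency)", call. = FALSE)
  if (any(!is.na(death) & death < panel$age - 1e-9))
    stop("death age precedes a visit age (data inconsistency)", call. = FALSE)
  exit <- ifelse(last, ifelse(is.na(death), panel$censor_age, death), nxt)
  event <- as.integer(last & !is.na(death))
  ok <- exit > panel$age + 1e-12
  out <- data.frame(subject = key, entry = panel$age, exit = exit, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(scores)) out$score <- scores
  extra <- setdiff(names(panel), c("subject", "age", "death_age", "censor_age"))
  out <- cbind(out, panel[, extra, drop = FALSE])
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cox regression of mortality on an axis score, age as timescale
#'
#' Fits \code{survival::coxph(Surv(entry, exit, event) ~ score)}: the hazard
#' is indexed by attained age with left truncation at each interval's entry
#' age, so age is controlled by construction.
#'
#' @param intervals \code{\link{build_intervals}} output with a \code{score}
#'   column.
#' @param axis label recorded on the result.
#' @return \code{association_result} with the hazard ratio per unit score,
#'   95% CI and p; \code{extra} carries \code{log_hr}, its SE, and
#'   \code{pseudo_r2} (Cox-Snell-type R-squared as reported by
#'   \code{summary.coxph}).
#' @export
cox_axis <- function(intervals, axis = "axis1") {
  if (!"score" %in% names(intervals)) stop("intervals lack a 'score' column", call. = FALSE)
  if (sum(intervals$event) == 0L) stop("no events: Cox model cannot be fit", call. = FALSE)
  fit <- survival::coxph(survival::Surv(entry, exit, event) ~ score, data = intervals)
  sm <- summary(fit)
  conv <- is.finite(sm$coefficients["score", "se(coef)"])
  new_association(
    outcome = "mortality", family = "cox",
    effect = unname(exp(stats::coef(fit)["score"])),
    ci = unname(exp(stats::confint(fit)["score", ])),
    p = sm$coefficients["score", "Pr(>|z|)"],
    n_obs = nrow(intervals), n_subjects = length(unique(intervals$subject)),
    n_events = sum(intervals$event), age_control = "age as timescale",
    axis = axis,
    extra = list(log_hr = unname(stats::coef(fit)["score"]),
                 se = sm$coefficients["score", "se(coef)"],
                 pseudo_r2 = unname(sm$rsq["rsq"]), converged = conv)
  )
}

spline_frame <- function(ages, n_knots) {
  B <- splines::bs(ages, df = n_knots + 3L, degree = 3L)
  d <- as.data.frame(unclass(B))
  names(d) <- paste0("bs", seq_len(ncol(d)))
  d
}

#' Count outcome (frailty / comorbidity) regression on an axis score
#'
#' Regresses the count on the score plus a cubic age-spline basis. When
#' subjects contribute repeated visits, a subject-level random intercept is
#' included (nlme for the linear family, lme4 for Poisson); single-visit data
#' use ordinary lm/glm.
#'
#' @param scores axis scores.
#' @param counts non-negative integer counts.
#' @param ages ages (years).
#' @param family "linear" (change in criteria per unit score) or "poisson"
#'   (log-rate per unit score).
#' @param subjects subject ids; NULL for baseline-only data.
#' @param n_knots interior spline knots for the age control (default 5).
#' @param outcome label.
#' @return \code{association_result}.
#' @export
count_association <- function(scores, counts, ages, family = c("linear", "poisson"),
                              subjects = NULL, n_knots = 5L, outcome = "frailty",
                              axis = "axis1") {
  family <- match.arg(family)
  s <- if (inherits(scores, "axis_scores")) scores$score else as.numeric(scores)
  if (any(counts < 0, na.rm = TRUE) || any(counts %% 1 != 0, na.rm = TRUE))
    stop("counts must be non-negative integers", call. = FALSE)
  d <- data.frame(count = counts, score = s)
  d <- cbind(d, spline_frame(ages, n_knots))
  bs_terms <- grep("^bs", names(d), value = TRUE)
  rhs <- paste(c("score", bs_terms), collapse = " + ")
  repeated <- !is.null(subjects) && any(duplicated(subjects))
  if (repeated) d$subject <- as.character(subjects)
  if (family == "linear") {
    if (repeated) {
      fit <- nlme::lme(stats::as.formula(paste("count ~", rhs)),
                       random = ~ 1 | subject, data = d, method = "REML")
      tt <- summary(fit)$tTable
      est <- tt["score", "Value"]; se <- tt["score", "Std.Error"]; p <- tt["score", "p-value"]
    } else {
      fit <- stats::lm(stats::as.formula(paste("count ~", rhs)), data = d)
      cf <- summary(fit)$coefficients
      est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    }
  } else {
    if (repeated) {
      fit <- lme4::glmer(stats::as.formula(paste("count ~", rhs, "+ (1 | subject)")),
                         data = d, family = stats::poisson())
      cf <- stats::coef(summary(fit))
      est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    } else {
      fit <- stats::glm(stats::as.formula(paste("count ~", rhs)), data = d,
                        family = stats::poisson())
      cf <- summary(fit)$coefficients
      est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    }
  }
  new_association(outcome = outcome, family = family, effect = unname(est),
                  ci = unname(est + c(-1, 1) * stats::qnorm(0.975) * se), p = unname(p),
                  n_obs = nrow(d),
                  n_subjects = if (is.null(subjects)) nrow(d) else length(unique(subjects)),
                  age_control = sprintf("cubic B-spline, %d interior knots", n_knots),
                  axis = axis, extra = list(se = unname(se)))
}

#' Binary disease outcome regression on an axis score
#'
#' Logistic regression of a disease flag on the score with a cubic age-spline
#' control. Ambiguous diagnoses are assigned to the positive category by
#' default; alternatives assign them negative, or score them 0.5 on a 0-0.5-1
#' scale analyzed by linear regression (sensitivity analyses).
#'
#' @param scores axis scores.
#' @param flags character/factor with levels among "positive", "negative",
#'   "ambiguous".
#' @param ages ages (years).
#' @param ambiguous "positive" (default), "negative", or "half".
#' @param n_knots interior spline knots (default 5).
#' @param outcome label.
#' @return \code{association_result}: odds ratio per unit score (logistic) or
#'   slope on the 0-0.5-1 scale (linear).
#' @export
binary_association <- function(scores, flags, ages, ambiguous = c("positive", "negative", "half"),
                               n_knots = 5L, outcome = "disease", axis = "axis1") {
  ambiguous <- match.arg(ambiguous)
  s <- if (inherits(scores, "axis_scores")) scores$score else as.numeric(scores)
  f <- as.character(flags)
  bad <- setdiff(unique(f), c("positive", "negative", "ambiguous"))
  if (length(bad)) stop("unknown flag value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  y <- switch(ambiguous,
    positive = as.numeric(f %in% c("positive", "ambiguous")),
    negative = as.numeric(f == "positive"),
    half = ifelse(f == "positive", 1, ifelse(f == "ambiguous", 0.5, 0))
  )
  if (length(unique(y)) < 2L) stop("single-class outcome: model cannot be fit", call. = FALSE)
  d <- cbind(data.frame(y = y, score = s), spline_frame(ages, n_knots))
  rhs <- paste(c("score", grep("^bs", names(d), value = TRUE)), collapse = " + ")
  if (ambiguous == "half") {
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    cf <- summary(fit)$coefficients
    est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    eff <- est; ci <- est + c(-1, 1) * stats::qnorm(0.975) * se; fam <- "linear"
  } else {
    fit <- stats::glm(stats::as.formula(paste("y ~", rhs)), data = d, family = stats::binomial())
    cf <- summary(fit)$coefficients
    est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    eff <- exp(est); ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se); fam <- "logistic"
  }
  new_association(outcome = outcome, family = fam, effect = unname(eff),
                  ci = unname(ci), p = unname(p), n_obs = nrow(d), n_subjects = nrow(d),
                  n_events = sum(y == 1),
                  age_control = sprintf("cubic B-spline, %d interior knots", n_knots),
                  axis = axis,
                  extra = list(ambiguous = ambiguous, n_positive = sum(y >= 0.5)))
}

#' Compound a per-unit hazard (or odds) ratio over a score difference
#'
#' Per-unit ratios imply exponential effects: two individuals differing by
#' \code{delta} score units differ in risk by \code{hr^delta} (e.g. a per-unit
#' hazard ratio of 1.1 over 5 units compounds to 1.1^5 = 1.61, displayed 1.6).
#'
#' @param hr per-unit ratio (> 0).
#' @param delta score-unit difference.
#' @param digits optional display rounding; NULL returns the exact value.
#' @return compounded ratio.
#' @export
compound_hazard <- function(hr, delta, digits = NULL) {
  if (!isTRUE(hr > 0)) stop("hazard ratio must be > 0", call. = FALSE)
  out <- hr^delta
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Expected false positives across a test battery
#'
#' Under independence, m tests at level alpha yield about m * alpha
#' significant results by chance.
#'
#' @param m number of tests (>= 0).
#' @param alpha significance level in (0,1).
#' @return expected count.
#' @export
expected_false_positives <- function(m, alpha = 0.05) {
  if (m < 0) stop("m must be >= 0", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  m * alpha
}
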