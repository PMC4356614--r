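# Synthetic multi-cohort generator.
#
# A linear two-factor model on the standardized scale, mapped to native units:
#   S_m = lambda_m1 * F1 + lambda_m2 * F2 + shift_m * (sex) + eps_m
# with F1 following a quadratic age trend plus a subject-level random
# intercept and visit-level noise, and F2 a flat metabolic factor. Gaussian
# markers are mean + sd * S; lognormal markers are exp(mu + sigma * S) with
# (mu, sigma) moment-matched to the native mean/SD. Mortality, frailty,
# comorbidity and a diabetes-like flag are generated from the factors so that
# downstream association models have known truth.

#' Build a synthetic-cohort generator configuration
#'
#' @param cohorts named list; each element a list with fields \code{n_subjects},
#'   \code{age_range} (length-2 years), \code{visits} (>= 1),
#'   \code{gap_years}, \code{p_female} in \[0,1\], and optionally
#'   \code{strata}, a named list of named probability vectors (e.g.
#'   \code{list(race = c(white = .7, black = .3))}).
#' @param markers data.frame like \code{\link{marker_reference}} restricted to
#'   the desired markers; must carry \code{marker}, \code{family},
#'   \code{sex_shift} and \code{mean_<cohort>}/\code{sd_<cohort>} columns for
#'   every cohort name.
#' @param loadings numeric matrix, markers x 2: column 1 the multi-system
#'   ("albunemia") factor F1, column 2 the metabolic factor F2, on the
#'   standardized scale.
#' @param factor_age list with elements \code{F1} and \code{F2}, each a list
#'   \code{beta0}, \code{beta1} (per year), \code{beta2} (per year^2),
#'   \code{intercept_sd} (between subjects), \code{noise_sd} (within subject).
#' @param residual_sd per-marker residual SD on the standardized scale;
#'   default \code{sqrt(1 - rowSums(loadings^2))} so each marker's implied
#'   standardized variance is 1.
#' @param missingness scalar, per-marker named vector, or cohort x marker
#'   matrix of completely-at-random missingness rates in \[0,1\].
#' @param mortality list \code{h0} (baseline hazard per year), \code{log_hr}
#'   (log hazard per unit F1), \code{followup_years} (administrative
#'   censoring after entry).
#' @param frailty list \code{log_rate}, \code{log_rr} (per unit F1); counts
#'   are Poisson truncated to 0-5 (phenotype criteria count).
#' @param comorbidity list \code{log_rate}, \code{log_rr} (per unit F1);
#'   Poisson truncated to 0-13.
#' @param disease list \code{intercept} (logit), \code{slope} (per unit F2),
#'   \code{ambiguous_prob} (probability a positive/negative code is recorded
#'   as "ambiguous").
#' @param seed integer seed controlling all generation.
#' @return object of class \code{generator_config}.
#' @seealso [default_generator_config()], [generate_panel()]
#' @export
generator_config <- function(cohorts, markers, loadings, factor_age,
                             residual_sd = NULL, missingness = 0,
                             mortality = list(h0 = 0.03, log_hr = 0.1, followup_years = 8),
                             frailty = list(log_rate = log(0.8), log_rr = 0.25),
                             comorbidity = list(log_rate = log(2), log_rr = 0.1),
                             disease = list(intercept = -1.5, slope = 0.4, ambiguous_prob = 0.05),
                             seed = 1L) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != 2L) stop_field("loadings", "must have exactly 2 columns (F1, F2)")
  if (nrow(loadings) != nrow(markers)) stop_field("loadings", "one row per marker required")
  if (is.null(residual_sd)) {
    rs2 <- 1 - rowSums(loadings^2)
    if (any(rs2 < 0)) stop_field("loadings", "implied standardized variance exceeds 1 for some marker")
    residual_sd <- sqrt(rs2)
  }
  cfg <- structure(list(
    cohorts = cohorts, markers = markers, loadings = loadings,
    factor_age = factor_age, residual_sd = residual_sd,
    missingness = missingness, mortality = mortality, frailty = frailty,
    comorbidity = comorbidity, disease = disease, seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!length(cfg$cohorts)) stop_field("cohorts", "at least one cohort required")
  if (is.null(names(cfg$cohorts)) || any(names(cfg$cohorts) == ""))
    stop_field("cohorts", "must be a named list")
  for (nm in names(cfg$cohorts)) {
    co <- cfg$cohorts[[nm]]
    if (!isTRUE(co$n_subjects >= 1)) stop_field(paste0("cohorts$", nm, "$n_subjects"), "must be >= 1")
    if (length(co$age_range) != 2L || diff(co$age_range) <= 0)
      stop_field(paste0("cohorts$", nm, "$age_range"), "must be increasing length-2")
    if (!isTRUE(co$visits >= 1)) stop_field(paste0("cohorts$", nm, "$visits"), "must be >= 1")
    if (co$visits > 1 && !isTRUE(co$gap_years > 0))
      stop_field(paste0("cohorts$", nm, "$gap_years"), "must be > 0 with repeated visits")
    if (!isTRUE(co$p_female >= 0 && co$p_female <= 1))
      stop_field(paste0("cohorts$", nm, "$p_female"), "must be in [0,1]")
    mcol <- paste0("mean_", nm); scol <- paste0("sd_", nm)
    if (!all(c(mcol, scol) %in% names(cfg$markers)))
      stop_field("markers", paste0("missing columns ", mcol, "/", scol))
    if (any(cfg$markers[[scol]] <= 0)) stop_field(scol, "all SDs must be > 0")
  }
  if (any(cfg$residual_sd < 0)) stop_field("residual_sd", "must be >= 0")
  miss <- missingness_matrix(cfg)
  if (any(miss < 0 | miss > 1)) stop_field("missingness", "rates must be in [0,1]")
  for (f in c("F1", "F2")) {
    fa <- cfg$factor_age[[f]]
    if (is.null(fa)) stop_field("factor_age", paste0("missing element ", f))
    if (!isTRUE(fa$intercept_sd >= 0)) stop_field(paste0("factor_age$", f, "$intercept_sd"), "must be >= 0")
    if (!isTRUE(fa$noise_sd >= 0)) stop_field(paste0("factor_age$", f, "$noise_sd"), "must be >= 0")
  }
  if (!isTRUE(cfg$mortality$h0 >= 0)) stop_field("mortality$h0", "baseline hazard must be >= 0")
  if (!isTRUE(cfg$disease$ambiguous_prob >= 0 && cfg$disease$ambiguous_prob <= 1))
    stop_field("disease$ambiguous_prob", "must be in [0,1]")
  invisible(cfg)
}

# Expand the missingness field to a cohort x marker matrix.
missingness_matrix <- function(cfg) {
  p <- nrow(cfg$markers); cn <- names(cfg$cohorts)
  m <- cfg$missingness
  if (is.matrix(m)) {
    out <- m[cn, cfg$markers$marker, drop = FALSE]
  } else if (!is.null(names(m))) {
    v <- rep(0, p); names(v) <- cfg$markers$marker
    v[intersect(names(m), names(v))] <- m[intersect(names(m), names(v))]
    out <- matrix(v, nrow = length(cn), ncol = p, byrow = TRUE,
                  dimnames = list(cn, cfg$markers$marker))
  } else {
    out <- matrix(m, nrow = length(cn), ncol = p,
                  dimnames = list(cn, cfg$markers$marker))
  }
  out
}

#' Default three-cohort configuration
#'
#' Ships the 43 markers of \code{\link{marker_reference}} with F1 loading at
#' |0.6| on a 12-marker cluster (red-cell/iron markers and IL-6 positive;
#' albumin, albumin-globulin ratio, calcium and RDW negative) and F2 on
#' lipids, glucose and CRP; residual SDs default to sqrt(1 - loading^2), i.e.
#' 0.8 for the F1 cluster. F1 follows a J-shaped quadratic age trend
#' (accelerating after midlife); F2 is age-flat.
#'
#' @param n_subjects named integer vector of subjects per cohort.
#' @param age_trend logical; FALSE zeroes the F1 age coefficients (useful for
#'   moment checks where the configured native moments should be exact).
#' @param missingness,mortality_log_hr,seed passed through to the config.
#' @return \code{generator_config}.
#' @export
default_generator_config <- function(n_subjects = c(whas = 250, inchianti = 650, blsa = 300),
                                     age_trend = TRUE, missingness = 0,
                                     mortality_log_hr = 0.1, seed = 1L) {
  ref <- marker_reference()
  p <- nrow(ref)
  lam <- matrix(0, p, 2, dimnames = list(ref$marker, c("F1", "F2")))
  f1_pos <- c("hemoglobin", "hematocrit", "rbc", "iron", "mch", "mchc", "il6", "platelets")
  f1_neg <- c("albumin", "albumin_globulin_ratio", "calcium", "rdw")
  lam[f1_pos, 1] <- 0.6
  lam[f1_neg, 1] <- -0.6
  lam[c("crp", "triglycerides", "glucose"), 2] <- 0.6
  lam["cholesterol_total", 2] <- 0.5
  lam["hdl", 2] <- -0.5
  fa <- list(
    F1 = list(beta0 = 0.22, beta1 = -0.025, beta2 = 0.00032,
              intercept_sd = 0.8, noise_sd = 0.6),
    F2 = list(beta0 = 0, beta1 = 0, beta2 = 0,
              intercept_sd = 0.8, noise_sd = 0.6)
  )
  if (!age_trend) fa$F1[c("beta0", "beta1", "beta2")] <- list(0, 0, 0)
  cohorts <- list(
    whas = list(n_subjects = unname(n_subjects[["whas"]]), age_range = c(65, 100),
                visits = 3L, gap_years = 1.5, p_female = 1,
                strata = list(race = c(white = 0.65, black = 0.35),
                              education = c(lt10 = 0.4, ge10 = 0.6))),
    inchianti = list(n_subjects = unname(n_subjects[["inchianti"]]), age_range = c(21, 95),
                     visits = 1L, gap_years = 3, p_female = 0.5,
                     strata = list(village = c(greve = 0.5, bagno = 0.5))),
    blsa = list(n_subjects = unname(n_subjects[["blsa"]]), age_range = c(21, 96),
                visits = 2L, gap_years = 2, p_female = 0.5,
                strata = list(race = c(white = 0.8, black = 0.2)))
  )
  generator_config(
    cohorts = cohorts, markers = ref, loadings = lam, factor_age = fa,
    missingness = missingness,
    mortality = list(h0 = 0.03, log_hr = mortality_log_hr, followup_years = 8),
    seed = seed
  )
}

quad_trend <- function(fa, age) fa$beta0 + fa$beta1 * age + fa$beta2 * age^2

#' Generate a synthetic multi-cohort visit panel
#'
#' Draws visit schedules, latent factors, native-unit marker values and
#' factor-linked outcomes for every cohort in the configuration. The same
#' (config, seed) always produces identical output.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{panel} (data.frame, one row per cohort/subject/visit
#'   with demographics, outcomes and marker columns; class
#'   \code{cohort_panel}) and \code{truth} (data.frame of true F1/F2, the
#'   subject random intercept and true death age per row, with the config
#'   attached as attribute \code{config}).
#' @export
generate_panel <- function(config) {
  validate_generator_config(config)
  seeds <- child_seeds(config$seed, 3L)
  pieces <- with_seed(seeds[1L], lapply(names(config$cohorts), function(nm) {
    draw_cohort(nm, config$cohorts[[nm]], config)
  }))
  panel <- rbind_fill(lapply(pieces, `[[`, "panel"))
  truth <- do.call(rbind, lapply(pieces, `[[`, "truth"))
  rownames(panel) <- rownames(truth) <- NULL

  out <- simulate_outcomes(truth, config, seed = seeds[2L])
  keep <- out$keep
  panel <- cbind(panel[keep, , drop = FALSE],
                 out[keep, c("death_age", "censor_age", "frailty", "comorbidity", "diabetes")])
  truth <- truth[keep, , drop = FALSE]
  truth$true_death_age <- out$death_age[keep]
  # marker columns last, metadata first
  mk <- config$markers$marker
  meta_cols <- setdiff(names(panel), mk)
  panel <- panel[, c(meta_cols, mk)]
  panel <- apply_missingness(panel, missingness_matrix(config), seed = seeds[3L])
  rownames(panel) <- rownames(truth) <- NULL
  class(panel) <- c("cohort_panel", "data.frame")
  attr(truth, "config") <- config
  list(panel = panel, truth = truth)
}

draw_cohort <- function(nm, co, cfg) {
  n <- co$n_subjects; v <- co$visits
  subj <- sprintf("%s_%05d", nm, seq_len(n))
  sex <- ifelse(stats::runif(n) < co$p_female, "female", "male")
  strata <- lapply(co$strata %||% list(), function(pr) {
    sample(names(pr), n, replace = TRUE, prob = pr)
  })
  lo <- co$age_range[1L]; hi <- co$age_range[2L]
  span <- if (v > 1) (v - 1L) * co$gap_years else 0
  age0 <- stats::runif(n, lo, max(lo + 1e-6, hi - span))
  ages <- rep(age0, each = v) + rep(seq_len(v) - 1L, times = n) * co$gap_years

  idx <- rep(seq_len(n), each = v)
  nrow_ <- n * v
  f1a <- cfg$factor_age$F1; f2a <- cfg$factor_age$F2
  b1 <- stats::rnorm(n, 0, f1a$intercept_sd)
  b2 <- stats::rnorm(n, 0, f2a$intercept_sd)
  F1 <- quad_trend(f1a, ages) + b1[idx] + stats::rnorm(nrow_, 0, f1a$noise_sd)
  F2 <- quad_trend(f2a, ages) + b2[idx] + stats::rnorm(nrow_, 0, f2a$noise_sd)

  mk <- cfg$markers
  p <- nrow(mk)
  lam <- cfg$loadings
  sexnum <- ifelse(sex == "female", 0.5, -0.5)[idx]
  vals <- matrix(NA_real_, nrow_, p, dimnames = list(NULL, mk$marker))
  mu <- mk[[paste0("mean_", nm)]]; sg <- mk[[paste0("sd_", nm)]]
  for (j in seq_len(p)) {
    S <- lam[j, 1L] * F1 + lam[j, 2L] * F2 + mk$sex_shift[j] * sexnum +
      stats::rnorm(nrow_, 0, cfg$residual_sd[j])
    if (mk$family[j] == "lognormal") {
      s2 <- log(1 + (sg[j] / mu[j])^2)
      vals[, j] <- exp(log(mu[j]) - s2 / 2 + sqrt(s2) * S)
    } else {
      vals[, j] <- mu[j] + sg[j] * S
    }
  }

  panel <- data.frame(cohort = nm, subject = subj[idx], visit = rep(seq_len(v), times = n),
                      age = ages, sex = sex[idx], stringsAsFactors = FALSE)
  for (sn in names(strata)) panel[[sn]] <- strata[[sn]][idx]
  panel <- cbind(panel, as.data.frame(vals))
  truth <- data.frame(cohort = nm, subject = subj[idx], visit = panel$visit,
                      age = ages, F1 = F1, F2 = F2,
                      subject_intercept = b1[idx], stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

#' Simulate factor-linked outcomes
#'
#' Death times are exponential from study entry with hazard
#' \code{h0 * exp(log_hr * F1_entry)} on the age timescale; frailty and
#' comorbidity counts are truncated Poisson with log-rate linear in per-visit
#' F1; the diabetes-like flag is Bernoulli in F2 with a configurable
#' probability of an "ambiguous" code.
#'
#' @param truth truth data.frame as produced by \code{\link{generate_panel}}
#'   (columns cohort, subject, visit, age, F1, F2).
#' @param config the generating \code{\link{generator_config}}.
#' @param seed integer seed.
#' @return data.frame aligned with \code{truth}: \code{death_age} (NA when
#'   censored), \code{censor_age}, \code{frailty} (0-5),
#'   \code{comorbidity} (0-13), \code{diabetes}
#'   ("positive"/"negative"/"ambiguous"), and \code{keep} (FALSE for visits
#'   scheduled after the simulated death).
#' @export
simulate_outcomes <- function(truth, config, seed = config$seed) {
  if (!isTRUE(config$mortality$h0 >= 0)) stop_field("mortality$h0", "baseline hazard must be >= 0")
  with_seed(seed, {
    mo <- config$mortality
    key <- paste(truth$cohort, truth$subject)
    first <- !duplicated(key)
    entry <- stats::setNames(truth$age[first], key[first])[key]
    f1_entry <- stats::setNames(truth$F1[first], key[first])[key]
    usub <- key[first]
    rate <- mo$h0 * exp(mo$log_hr * f1_entry[match(usub, key)])
    tdeath <- if (mo$h0 > 0) stats::rexp(length(usub), rate) else rep(Inf, length(usub))
    fup <- mo$followup_years %||% 8
    death_sub <- ifelse(tdeath <= fup, entry[match(usub, key)] + tdeath, NA_real_)
    names(death_sub) <- usub
    death_age <- death_sub[key]
    censor_age <- pmax(entry + fup, stats::ave(truth$age, key, FUN = max))

    fr <- pmin(stats::rpois(nrow(truth), exp(config$frailty$log_rate +
                                               config$frailty$log_rr * truth$F1)), 5L)
    cm <- pmin(stats::rpois(nrow(truth), exp(config$comorbidity$log_rate +
                                               config$comorbidity$log_rr * truth$F1)), 13L)
    pr <- stats::plogis(config$disease$intercept + config$disease$slope * truth$F2)
    dz <- ifelse(stats::runif(nrow(truth)) < pr, "positive", "negative")
    amb <- stats::runif(nrow(truth)) < config$disease$ambiguous_prob
    dz[amb] <- "ambiguous"

    keep <- is.na(death_age) | truth$age < death_age
    data.frame(death_age = unname(death_age), censor_age = unname(censor_age),
               frailty = fr, comorbidity = cm, diabetes = dz, keep = keep,
               stringsAsFactors = FALSE)
  })
}

#' Set marker cells missing completely at random
#'
#' @param panel cohort panel data.frame with a \code{cohort} column.
#' @param rates scalar rate, named per-marker vector, or cohort x marker
#'   matrix, all in \[0,1\].
#' @param seed integer seed.
#' @return the panel with the selected cells set to NA.
#' @export
apply_missingness <- function(panel, rates, seed = 1L) {
  mkcols <- if (is.matrix(rates)) colnames(rates) else if (!is.null(names(rates))) names(rates)
            else intersect(marker_reference()$marker, names(panel))
  mkcols <- intersect(mkcols, names(panel))
  rmat <- if (is.matrix(rates)) rates else {
    v <- if (!is.null(names(rates))) rates[mkcols] else rep(rates, length(mkcols))
    matrix(v, nrow = length(unique(panel$cohort)), ncol = length(mkcols), byrow = TRUE,
           dimnames = list(unique(panel$cohort), mkcols))
  }
  if (any(rmat < 0 | rmat > 1, na.rm = TRUE)) stop_field("rates", "must be in [0,1]")
  if (all(rmat == 0)) return(panel)
  with_seed(seed, {
    for (co in rownames(rmat)) {
      rows <- which(panel$cohort == co)
      for (mk in colnames(rmat)) {
        r <- rmat[co, mk]
        if (r > 0 && length(rows)) {
          hit <- stats::runif(length(rows)) < r
          panel[[mk]][rows[hit]] <- NA_real_
        }
      }
    }
    panel
  })
}

#' Validate a cohort visit panel
#'
#' Checks the structural invariants: unique (cohort, subject, visit) keys,
#' strictly increasing visit ages within subject, death age not before the
#' last visit, and frailty counts in 0-5.
#'
#' @param panel data.frame.
#' @return the panel, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel) {
  req <- c("cohort", "subject", "visit", "age")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop_field(paste(miss, collapse = ", "), "required panel column(s) absent")
  key <- paste(panel$cohort, panel$subject, panel$visit)
  if (anyDuplicated(key))
    stop("duplicate (cohort, subject, visit) keys: ", key[anyDuplicated(key)], call. = FALSE)
  ord <- order(panel$cohort, panel$subject, panel$visit)
  a <- panel$age[ord]; k <- paste(panel$cohort, panel$subject)[ord]
  same <- k[-1] == k[-length(k)]
  if (any(same & diff(a) <= 0))
    stop("visit ages not strictly increasing within subject", call. = FALSE)
  if ("death_age" %in% names(panel)) {
    last <- tapply(panel$age, paste(panel$cohort, panel$subject), max)
    d <- tapply(panel$death_age, paste(panel$cohort, panel$subject), function(x) x[1])
    bad <- !is.na(d) & d < last - 1e-9
    if (any(bad)) stop("death age precedes a recorded visit for subject(s): ",
                       paste(utils::head(names(which(bad)), 3), collapse = ", "), call. = FALSE)
  }
  if ("frailty" %in% names(panel) &&
      any(panel$frailty < 0 | panel$frailty > 5, na.rm = TRUE))
    stop_field("frailty", "counts must lie in 0-5")
  invisible(panel)
}
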