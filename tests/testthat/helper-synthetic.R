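# Shared fixtures, built in code. A compact single-cohort config factory for
# focused tests, plus one medium three-cohort panel (the package defaults)
# computed once and reused by the recovery/stability/acceptance tests.

# Single-cohort generator config with p gaussian markers; loadings on F1 only
# unless a full loadings matrix is supplied.
small_config <- function(n_subjects = 200, p = 6, lambda = 0.6,
                         f1_markers = seq_len(p), loadings = NULL,
                         residual_sd = NULL, visits = 1L, gap = 2,
                         age_range = c(60, 90), trend = c(0, 0, 0),
                         intercept_sd = sqrt(0.5), noise_sd = sqrt(0.5),
                         family = "gaussian", missingness = 0,
                         mortality = list(h0 = 0.03, log_hr = 0.1, followup_years = 8),
                         seed = 1L) {
  mk <- data.frame(
    marker = sprintf("m%02d", seq_len(p)), group = "synthetic",
    family = family, in_34 = TRUE, clinical_14 = FALSE, sex_shift = 0,
    mean_c1 = 10, sd_c1 = 2, stringsAsFactors = FALSE
  )
  if (is.null(loadings)) {
    loadings <- matrix(0, p, 2)
    loadings[f1_markers, 1] <- lambda
  }
  generator_config(
    cohorts = list(c1 = list(n_subjects = n_subjects, age_range = age_range,
                             visits = visits, gap_years = gap, p_female = 0.5)),
    markers = mk, loadings = loadings,
    factor_age = list(
      F1 = list(beta0 = trend[1], beta1 = trend[2], beta2 = trend[3],
                intercept_sd = intercept_sd, noise_sd = noise_sd),
      F2 = list(beta0 = 0, beta1 = 0, beta2 = 0,
                intercept_sd = sqrt(0.5), noise_sd = sqrt(0.5))
    ),
    residual_sd = residual_sd, missingness = missingness,
    mortality = mortality, seed = seed
  )
}

# Wrap a plain numeric matrix as a standardized_matrix (ages optional).
as_sm <- function(X, ages = NULL, subjects = NULL, cohort = "c1") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("m%02d", seq_len(ncol(X)))
  meta <- data.frame(cohort = cohort,
                     subject = subjects %||% sprintf("s%05d", seq_len(nrow(X))),
                     visit = 1L,
                     age = ages %||% rep(NA_real_, nrow(X)))
  structure(list(values = X, meta = meta, markers = colnames(X),
                 spec = list(version = "test")),
            class = "standardized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Medium default-config fixture shared across tests (computed once per run).
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gp <- generate_panel(default_generator_config(seed = 1))
      spec <- fit_transform_spec(gp$panel)
      sm <- standardize(gp$panel, spec)
      cc <- complete_cases(sm)
      pa <- principal_axis(cc$matrix, source = "shared")
      cache <<- list(panel = gp$panel, truth = gp$truth, spec = spec,
                     sm = sm, cc = cc, model = pa$model, scores = pa$scores)
    }
    cache
  }
})
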