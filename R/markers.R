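#' Reference table of the 43 clinical biomarkers
#'
#' Per-cohort native-unit means and standard deviations for the 43 routine
#' clinical biomarkers used throughout the package, organized by functional
#' group. The three built-in cohort profiles ("whas", "inchianti", "blsa")
#' emulate an elderly all-female US cohort, an all-age Italian cohort, and an
#' all-age US cohort. Units are conventional clinical units and deliberately
#' differ across cohorts for albumin (g/dL in whas/blsa, percent of total
#' protein in inchianti), which forces per-cohort standardization downstream.
#'
#' @return data.frame with one row per marker: \code{marker}, \code{group},
#'   distribution \code{family} ("gaussian"/"lognormal"), \code{in_34}
#'   (available longitudinally), \code{clinical_14} (member of the reduced
#'   clinical set), \code{sex_shift} (additive sex offset on the standardized
#'   scale, female minus male), and \code{mean_}/\code{sd_} columns per cohort.
#' @export
marker_reference <- function() {
  # marker, group, family, in_34, clin14, sex_shift, mW, sW, mI, sI, mB, sB
  rows <- list(
    list("hemoglobin",            "blood",      "gaussian",  TRUE,  TRUE,  0,   13.0, 1.2,  13.8, 1.5,  13.6, 1.4),
    list("hematocrit",            "blood",      "gaussian",  TRUE,  TRUE,  0,   39,   4,    41,   4,    41,   4),
    list("iron",                  "blood",      "gaussian",  TRUE,  TRUE,  0,   80,   27,   85,   29,   89,   32),
    list("rdw",                   "blood",      "gaussian",  TRUE,  TRUE,  0,   14.1, 1.4,  13.8, 1.2,  13.5, 1.5),
    list("mch",                   "blood",      "gaussian",  TRUE,  TRUE,  0,   30.5, 2.1,  30.5, 2.1,  30.4, 2.1),
    list("mchc",                  "blood",      "gaussian",  TRUE,  TRUE,  0,   33.1, 1.2,  33.7, 1.0,  33.5, 1.2),
    list("platelets",             "blood",      "gaussian",  TRUE,  TRUE,  0,   242,  68,   236,  64,   231,  74),
    list("ferritin",              "blood",      "lognormal", TRUE,  FALSE, 0,   112,  124,  123,  127,  107,  99),
    list("rbc",                   "blood",      "gaussian",  TRUE,  TRUE,  0,   4.26, 0.43, 4.53, 0.47, 4.50, 0.48),
    list("glucose",               "blood",      "lognormal", TRUE,  FALSE, 0,   114,  57,   94,   26,   93,   18),
    list("wbc",                   "immune",     "gaussian",  TRUE,  FALSE, 0,   6.3,  2.4,  6.3,  1.7,  6.0,  3.5),
    list("neutrophils_pct",       "immune",     "gaussian",  TRUE,  FALSE, 0,   60,   10,   59,   9,    55,   10),
    list("monocytes",             "immune",     "gaussian",  TRUE,  FALSE, 0,   6.9,  2.4,  6.6,  2.2,  9.2,  4.3),
    list("lymphocytes",           "immune",     "gaussian",  TRUE,  FALSE, 0,   29,   9,    31,   8,    32,   10),
    list("eosinophils",           "immune",     "gaussian",  TRUE,  FALSE, 0,   3.0,  2.2,  3.2,  2.1,  3.5,  2.3),
    list("basophils",             "immune",     "gaussian",  TRUE,  FALSE, 0,   0.74, 0.53, 0.52, 0.35, 0.55, 0.32),
    list("il6",                   "immune",     "lognormal", FALSE, FALSE, 0,   4.3,  9.7,  3.4,  2.4,  2.9,  2.3),
    list("crp",                   "immune",     "lognormal", FALSE, TRUE,  0,   6.3,  8.5,  4.5,  9.0,  3.0,  5.9),
    list("calcium",               "electrolyte","gaussian",  TRUE,  TRUE,  0,   9.5,  0.5,  9.4,  0.5,  9.3,  0.4),
    list("chloride",              "electrolyte","gaussian",  TRUE,  FALSE, 0,   103,  4,    106,  4,    104,  3),
    list("magnesium",             "electrolyte","gaussian",  TRUE,  FALSE, 0,   1.99, 0.20, 2.08, 0.36, 2.05, 0.20),
    list("sodium",                "electrolyte","gaussian",  TRUE,  FALSE, 0,   140.0,2.9,  141.2,2.9,  141.7,2.8),
    list("potassium",             "electrolyte","gaussian",  TRUE,  FALSE, 0,   4.2,  0.43, 4.19, 0.40, 4.20, 0.34),
    list("vitamin_b12",           "vitamin",    "lognormal", FALSE, FALSE, 0,   494,  307,  471,  334,  640,  366),
    list("folate",                "vitamin",    "lognormal", FALSE, FALSE, 0,   12.4, 10.4, 10.1, 6.9,  24.6, 14.2),
    list("igf1",                  "hormone",    "gaussian",  FALSE, FALSE, 0,   119,  54,   129,  65,   125,  47),
    list("estradiol",             "hormone",    "lognormal", FALSE, FALSE, 1.2, 16.2, 17.8, 10.1, 14.8, 19.6, 30.7),
    list("dheas",                 "hormone",    "lognormal", FALSE, FALSE, 0,   43,   37,   104,  87,   64,   60),
    list("tsh",                   "hormone",    "lognormal", FALSE, FALSE, 0,   2.3,  2.9,  1.9,  4.7,  2.6,  2.1),
    list("cholesterol_total",     "lipid",      "gaussian",  TRUE,  FALSE, 0,   224,  41,   212,  42,   191,  37),
    list("triglycerides",         "lipid",      "lognormal", TRUE,  FALSE, 0,   160,  98,   127,  77,   103,  58),
    list("hdl",                   "lipid",      "gaussian",  TRUE,  FALSE, 0,   55,   16,   57,   15,   59,   17),
    list("albumin",               "protein",    "gaussian",  TRUE,  TRUE,  0,   4.1,  0.3,  58.9, 4.2,  4.1,  0.3),
    list("albumin_globulin_ratio","protein",    "gaussian",  TRUE,  TRUE,  0,   1.46, 0.26, 1.46, 0.25, 1.36, 0.22),
    list("alkaline_phosphatase",  "protein",    "lognormal", TRUE,  TRUE,  0,   87,   35,   165,  110,  78,   23),
    list("bun_creatinine_ratio",  "protein",    "gaussian",  FALSE, FALSE, 0,   19.1, 5.9,  37.8, 10.4, 16.9, 4.8),
    list("total_proteins",        "protein",    "gaussian",  TRUE,  FALSE, 0,   7.0,  0.5,  7.3,  0.5,  7.1,  0.5),
    list("ggt",                   "protein",    "lognormal", TRUE,  FALSE, 0,   31,   36,   27,   32,   30,   24),
    list("ldh",                   "protein",    "gaussian",  TRUE,  FALSE, 0,   177,  35,   344,  75,   430,  163),
    list("creatinine",            "protein",    "gaussian",  TRUE,  FALSE, 0,   1.01, 0.36, 0.92, 0.27, 1.02, 0.29),
    list("uric_acid",             "protein",    "gaussian",  TRUE,  FALSE, 0,   5.6,  1.7,  5.2,  1.4,  5.3,  1.4),
    list("alt",                   "protein",    "gaussian",  TRUE,  TRUE,  0,   19.6, 10.9, 20.8, 10.5, 32.0, 12.4),
    list("ast",                   "protein",    "gaussian",  TRUE,  FALSE, 0,   16.2, 12.1, 19.4, 15.2, 28.1, 10.6)
  )
  out <- data.frame(
    marker = vapply(rows, `[[`, "", 1L),
    group = vapply(rows, `[[`, "", 2L),
    family = vapply(rows, `[[`, "", 3L),
    in_34 = vapply(rows, `[[`, TRUE, 4L),
    clinical_14 = vapply(rows, `[[`, TRUE, 5L),
    sex_shift = vapply(rows, function(r) as.numeric(r[[6L]]), 0),
    mean_whas = vapply(rows, function(r) as.numeric(r[[7L]]), 0),
    sd_whas = vapply(rows, function(r) as.numeric(r[[8L]]), 0),
    mean_inchianti = vapply(rows, function(r) as.numeric(r[[9L]]), 0),
    sd_inchianti = vapply(rows, function(r) as.numeric(r[[10L]]), 0),
    mean_blsa = vapply(rows, function(r) as.numeric(r[[11L]]), 0),
    sd_blsa = vapply(rows, function(r) as.numeric(r[[12L]]), 0),
    stringsAsFactors = FALSE
  )
  out
}

#' Named biomarker sets
#'
#' The three panel presets used throughout: the full cross-sectional set of 43
#' markers, the 34-marker subset available longitudinally, and the reduced
#' 14-marker clinical set (cheap markers from a standard blood panel:
#' hemoglobin, hematocrit, MCH, MCHC, RDW, RBC, platelets, albumin,
#' albumin-globulin ratio, calcium, CRP, ALT, iron, alkaline phosphatase).
#'
#' @param name one of "full-43", "longitudinal-34", "clinical-14".
#' @return character vector of marker names.
#' @export
marker_set <- function(name = c("full-43", "longitudinal-34", "clinical-14")) {
  name <- match.arg(name)
  ref <- marker_reference()
  switch(name,
    "full-43" = ref$marker,
    "longitudinal-34" = ref$marker[ref$in_34],
    "clinical-14" = ref$marker[ref$clinical_14]
  )
}

#' Anemia-related marker names
#'
#' The red-cell/iron cluster summarized by its own first principal axis in
#' \code{\link{anemia_subaxis}}.
#'
#' @return character vector.
#' @export
anemia_markers <- function() {
  c("hemoglobin", "hematocrit", "rbc", "mch", "mchc", "rdw", "iron", "ferritin")
}
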