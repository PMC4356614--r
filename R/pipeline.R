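# End-to-end pipeline: generate or read a panel, select visits, fit the
# transformation spec (refit per analysis input), extract axes, run stability,
# trajectory and outcome stages, and bundle results with a manifest. All
# randomness flows from the config seed.

#' Pipeline configuration
#'
#' @param input path to a panel CSV/TSV, or NULL to generate.
#' @param generator \code{generator_config} used when \code{input} is NULL.
#' @param marker_set "full-43", "longitudinal-34", "clinical-14", or "custom".
#' @param custom_markers marker names when \code{marker_set = "custom"}.
#' @param visit_rule "first" (first visit per subject), "all", or "random"
#'   (one random visit per subject) for the cross-sectional stages.
#' @param stages character subset of c("axes", "stability", "trajectories",
#'   "outcomes", "score").
#' @param n_axes axes to summarize (importance profiles etc.).
#' @param stability_k,stability_reps random-exclusive-subset null parameters.
#' @param seed master seed.
#' @param outdir output directory (NULL: nothing written).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            marker_set = c("full-43", "longitudinal-34", "clinical-14", "custom"),
                            custom_markers = NULL,
                            visit_rule = c("first", "all", "random"),
                            stages = c("axes", "stability", "trajectories", "outcomes", "score"),
                            n_axes = 3L, stability_k = 10L, stability_reps = 20L,
                            seed = 1L, outdir = NULL) {
  marker_set <- match.arg(marker_set)
  visit_rule <- match.arg(visit_rule)
  if (is.null(input) && is.null(generator)) stop("exactly one input source required", call. = FALSE)
  if (!is.null(input) && !is.null(generator)) stop("exactly one input source required", call. = FALSE)
  if (marker_set == "custom" && is.null(custom_markers))
    stop_field("custom_markers", "required when marker_set = 'custom'")
  structure(list(input = input, generator = generator, marker_set = marker_set,
                 custom_markers = custom_markers, visit_rule = visit_rule,
                 stages = stages, n_axes = n_axes, stability_k = stability_k,
                 stability_reps = stability_reps, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

resolve_markers <- function(config, panel) {
  mk <- if (config$marker_set == "custom") config$custom_markers else marker_set(config$marker_set)
  absent <- setdiff(mk, names(panel))
  if (length(absent))
    stop("marker set not resolvable against the panel; missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  mk
}

select_visits <- function(panel, rule, seed) {
  key <- paste(panel$cohort, panel$subject)
  switch(rule,
    all = panel,
    first = {
      ord <- order(key, panel$age)
      p <- panel[ord, , drop = FALSE]
      p[!duplicated(key[ord]), , drop = FALSE]
    },
    random = with_seed(seed, {
      idx <- unlist(lapply(split(seq_len(nrow(panel)), key), function(i)
        if (length(i) == 1L) i else sample(i, 1L)), use.names = FALSE)
      panel[sort(idx), , drop = FALSE]
    })
  )
}

#' Run the full analysis pipeline
#'
#' Stage order: input -> transform/standardize -> axes -> stability ->
#' trajectories -> outcomes -> clinical score. A stage failure marks the
#' bundle partial and skips dependent stages with a recorded reason.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return object of class \code{report_bundle}: named stage results plus a
#'   \code{manifest} (config echo, seed, package version, timestamp) and
#'   \code{skipped} reasons. Written to \code{config$outdir} when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- child_seeds(config$seed, 4L)
  bundle <- list(); skipped <- list()

  panel <- if (!is.null(config$input)) read_panel(config$input)
           else generate_panel(config$generator)$panel
  markers <- resolve_markers(config, panel)
  bundle$counts_all_visits <- table(panel$cohort)

  cross <- select_visits(panel, config$visit_rule, seeds[1L])
  spec <- fit_transform_spec(cross, markers = markers)
  sm <- standardize(cross, spec)
  cc <- complete_cases(sm, markers)
  bundle$complete_case_counts <- cc$counts
  bundle$spec <- spec

  ax <- NULL
  if ("axes" %in% config$stages) {
    ax <- principal_axis(cc$matrix, source = paste0("pipeline-", config$marker_set))
    bundle$axis_model <- ax$model
    bundle$importance <- lapply(seq_len(min(config$n_axes, length(markers))),
                                function(k) importance(ax$model, k))
    bundle$scores <- ax$scores
  } else skipped$axes <- "disabled"

  if ("stability" %in% config$stages) {
    if (is.null(ax)) skipped$stability <- "axes stage disabled"
    else bundle$stability <- tryCatch(
      null_distribution(cc$matrix, k = config$stability_k,
                        reps = config$stability_reps, seed = seeds[2L]),
      error = function(e) { skipped$stability <<- conditionMessage(e); NULL })
  } else skipped$stability <- "disabled"

  if ("trajectories" %in% config$stages) {
    if (is.null(ax)) skipped$trajectories <- "axes stage disabled"
    else {
      # longitudinal stage: project the cross-sectional axis on all visits
      sm_all <- standardize(panel, spec)
      cc_all <- complete_cases(sm_all, markers)
      sc_all <- project(ax$model, cc_all$matrix, 1L)
      bundle$trajectories <- lapply(split(seq_along(sc_all$score), cc_all$matrix$meta$cohort),
        function(i) {
          m <- cc_all$matrix$meta[i, ]
          tryCatch(fit_trajectory(sc_all$score[i], m$age, m$subject),
                   error = function(e) conditionMessage(e))
        })
      bundle$scores_all_visits <- sc_all
    }
  } else skipped$trajectories <- "disabled"

  if ("outcomes" %in% config$stages) {
    if (is.null(ax)) skipped$outcomes <- "axes stage disabled"
    else if (!all(c("death_age", "censor_age") %in% names(panel)))
      skipped$outcomes <- "panel lacks follow-up columns"
    else {
      sm_all <- standardize(panel, spec)
      cc_all <- complete_cases(sm_all, markers)
      sc_all <- project(ax$model, cc_all$matrix, 1L)
      pan_cc <- panel[stats::complete.cases(sm_all$values[, markers, drop = FALSE]), , drop = FALSE]
      res <- list()
      iv <- build_intervals(pan_cc, sc_all$score)
      res$mortality <- tryCatch(cox_axis(iv), error = function(e) conditionMessage(e))
      if ("frailty" %in% names(pan_cc))
        res$frailty <- tryCatch(
          count_association(sc_all$score, pan_cc$frailty, pan_cc$age, "linear",
                            subjects = paste(pan_cc$cohort, pan_cc$subject),
                            outcome = "frailty"),
          error = function(e) conditionMessage(e))
      if ("comorbidity" %in% names(pan_cc))
        res$comorbidity <- tryCatch(
          count_association(sc_all$score, pan_cc$comorbidity, pan_cc$age, "linear",
                            subjects = paste(pan_cc$cohort, pan_cc$subject),
                            outcome = "comorbidity"),
          error = function(e) conditionMessage(e))
      if ("diabetes" %in% names(pan_cc)) {
        sc2 <- project(ax$model, cc_all$matrix, 2L)
        res$diabetes <- tryCatch(
          binary_association(sc2$score, pan_cc$diabetes, pan_cc$age,
                             outcome = "diabetes", axis = "axis2"),
          error = function(e) conditionMessage(e))
      }
      bundle$associations <- res
    }
  } else skipped$outcomes <- "disabled"

  if ("score" %in% config$stages) {
    bundle$clinical <- tryCatch({
      ref <- clinical_reference(panel)
      red <- if (!is.null(ax) && length(setdiff(marker_set("clinical-14"), markers)) == 0)
        reduce_axis(ax$model, cc$matrix, required = marker_set("clinical-14"),
                    target_size = 14L)$r else NA_real_
      list(reference = ref, r_with_full_axis = red)
    }, error = function(e) { skipped$score <<- conditionMessage(e); NULL })
  } else skipped$score <- "disabled"

  bundle$manifest <- list(
    package = "albunemia", version = as.character(utils::packageVersion("albunemia")),
    seed = config$seed,
    config = config[setdiff(names(config), "generator")],
    generated = !is.null(config$generator),
    timestamp = format(Sys.time(), tz = "UTC"))
  bundle$skipped <- skipped
  bundle$partial <- any(vapply(skipped, function(r) !identical(r, "disabled"), TRUE))
  class(bundle) <- "report_bundle"
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir, panel)
  bundle
}

write_bundle <- function(bundle, outdir, panel = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(panel)) write_panel(panel, file.path(outdir, "panel.csv"))
  if (!is.null(bundle$axis_model)) {
    write_axis_model(bundle$axis_model, file.path(outdir, "axis_model.json"))
    for (k in seq_along(bundle$importance))
      write_importance(bundle$importance[[k]],
                       file.path(outdir, sprintf("importance_axis%d.csv", k)))
  }
  if (!is.null(bundle$spec)) write_transform_spec(bundle$spec, file.path(outdir, "transform_spec.json"))
  if (!is.null(bundle$stability)) {
    s <- bundle$stability
    jsonlite::write_json(list(replicates = s$replicates, k = s$k, seed = s$seed,
                              mean_of_means = s$mean_of_means,
                              mean_of_minima = s$mean_of_minima,
                              mean_iqr = s$mean_iqr),
                         file.path(outdir, "stability_null.json"),
                         digits = NA, auto_unbox = TRUE)
    utils::write.csv(s$per_replicate, file.path(outdir, "stability_replicates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$trajectories)) {
    tt <- do.call(rbind, lapply(names(bundle$trajectories), function(nm) {
      f <- bundle$trajectories[[nm]]
      if (inherits(f, "trajectory_fit")) cbind(cohort = nm, as.data.frame(f)) else NULL
    }))
    if (!is.null(tt)) utils::write.csv(tt, file.path(outdir, "trajectories.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$associations)) {
    at <- do.call(rbind, lapply(bundle$associations, function(a)
      if (inherits(a, "association_result")) as.data.frame(a) else NULL))
    if (!is.null(at)) utils::write.csv(at, file.path(outdir, "associations.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$clinical) && !is.null(bundle$clinical$reference))
    write_clinical_reference(bundle$clinical$reference,
                             file.path(outdir, "clinical_reference.json"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

#' Batch clinical scoring from a measurements file
#'
#' Scores each row of a measurements CSV against a stored clinical reference.
#' Rows with missing reference markers are reported, not scored.
#'
#' @param measurements data.frame or path to a CSV with one column per
#'   reference marker.
#' @param reference \code{clinical_reference} or path to its JSON file.
#' @return list with \code{scores} (data.frame row, score) and
#'   \code{rejected} (data.frame row, missing markers); errors when no row is
#'   scorable.
#' @export
score_batch <- function(measurements, reference) {
  if (is.character(measurements)) measurements <- utils::read.csv(measurements)
  if (is.character(reference)) reference <- read_clinical_reference(reference)
  mk <- reference$markers
  absent <- setdiff(mk, names(measurements))
  ok_row <- if (length(absent)) rep(FALSE, nrow(measurements))
            else stats::complete.cases(measurements[, mk, drop = FALSE])
  rejected <- data.frame(row = which(!ok_row), missing = vapply(which(!ok_row), function(i) {
    if (length(absent)) paste(absent, collapse = ";")
    else paste(mk[is.na(unlist(measurements[i, mk]))], collapse = ";")
  }, ""), stringsAsFactors = FALSE)
  if (!any(ok_row)) stop("no scorable rows: every row lacks reference markers", call. = FALSE)
  sc <- clinical_score(measurements[ok_row, mk, drop = FALSE], reference)
  list(scores = data.frame(row = which(ok_row), score = sc),
       rejected = rejected)
}
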