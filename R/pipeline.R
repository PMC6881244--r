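#' End-to-end pipeline configuration
#'
#' @param cohort an `hr_cohort_spec` (to simulate) or a manifest path/object
#'   (to reuse existing data).
#' @param sides hippocampi to model: "left", "right", or both.
#' @param selection an `hr_selection_config`.
#' @param n_repetitions evaluation repetitions (default 10).
#' @param catalog a feature catalog.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory for artifacts.
#' @return List of class `hr_run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), sides = c("left", "right"),
                       selection = selection_config(), n_repetitions = 10L,
                       catalog = feature_catalog(), seed = 1L,
                       out_dir = tempfile("hipporad_run_")) {
  sides <- match.arg(sides, c("left", "right"), several.ok = TRUE)
  structure(list(cohort = cohort, sides = sides, selection = selection,
                 n_repetitions = as.integer(n_repetitions), catalog = catalog,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "hr_run_config")
}

# stage-specific seeds derived from the master seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, extract = 23L, select_left = 37L,
            select_right = 41L, model_left = 53L, model_right = 59L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the full radiomics pipeline
#'
#' Orchestrates simulate (or load) -> extract -> select -> train -> report
#' for each requested side, each side an independent model. Writes the
#' feature table, per-side selection results and model reports (JSON/CSV)
#' to the output directory and returns them.
#'
#' @param config an `hr_run_config`.
#' @param verbose print stage progress.
#' @return List of class `hr_run_result`: `manifest`, `features` (table),
#'   and per side `selection` and `report`; element `counts` gives the
#'   feature-cascade checkpoints per side.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "hr_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  if (inherits(config$cohort, "hr_cohort_spec")) {
    say("simulating cohort ...")
    spec <- config$cohort
    spec$seed <- .stage_seed(config$seed, "simulate")
    manifest <- generate_cohort(spec, file.path(config$out_dir, "cohort"))
  } else if (is.character(config$cohort)) {
    manifest <- read_manifest(config$cohort)
  } else {
    manifest <- config$cohort
  }

  say("extracting features (", nrow(manifest), " subjects x ",
      length(config$sides), " sides) ...")
  features <- extract_cohort(manifest, config$catalog, config$sides,
                             verbose = verbose)
  write_feature_table(features, file.path(config$out_dir, "features.csv"))

  out <- list(manifest = manifest, features = features, sides = list())
  counts <- list()
  for (side in config$sides) {
    say("selecting + modeling side: ", side)
    tab <- features[features$side == side, , drop = FALSE]
    sel <- run_selection(tab, config$selection,
                         seed = .stage_seed(config$seed, paste0("select_", side)))
    report <- if (!sel$empty)
      run_repetitions(tab, sel$selected, config$n_repetitions,
                      seed = .stage_seed(config$seed, paste0("model_", side)),
                      train_fraction = config$selection$train_fraction)
    else NULL
    counts[[side]] <- sel$stages
    out$sides[[side]] <- list(selection = sel, report = report)
    jsonlite::write_json(
      list(side = side, stages = as.list(sel$stages),
           selected = sel$selected,
           metrics_mean = if (!is.null(report)) as.list(report$mean) else NULL,
           metrics_sd = if (!is.null(report)) as.list(report$sd) else NULL),
      file.path(config$out_dir, paste0("report_", side, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$counts <- counts
  class(out) <- "hr_run_result"
  out
}
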