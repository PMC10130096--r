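# End-to-end orchestration: simulate (or read) the linked tables, ascertain
# comorbidities, build outcomes, split, fit the index, validate it, and
# produce the prognosis tables, with a content-hash manifest for
# reproducibility.

#' Pipeline configuration
#'
#' Either `scenario` (a [scenario_config()]; the simulate stage generates
#' the linked tables) or `input_dir` (a directory with
#' `registry.csv`/`claims.csv`/`deaths.csv`/`enrollment.csv`) must be given.
#'
#' @param out_dir output directory.
#' @param scenario optional [scenario_config()].
#' @param input_dir optional directory of existing input tables.
#' @param seed integer seed recorded in the manifest and used for the fold
#'   assignment (and the scenario, if one is generated here from a config
#'   file).
#' @param window_months ascertainment window (30/54/78).
#' @param code_map condition code map (list or YAML path).
#' @param cause_map optional `cause_map` (defaults to the registry's sites).
#' @param death_horizon,enrollment_horizon follow-up horizons.
#' @param stages which stages to run, in pipeline order.
#' @param horizons_years prognosis/validation horizons.
#' @param strata prognosis stratifiers.
#' @param boot_B bootstrap replicates for validation AUC standard errors.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scenario = NULL, input_dir = NULL,
                            seed = 1, window_months = 30,
                            code_map = default_code_map(),
                            cause_map = NULL,
                            death_horizon = "2016-12-31",
                            enrollment_horizon = "2015-12-31",
                            stages = c("simulate", "ascertain", "endpoints",
                                       "split", "index", "validate",
                                       "prognosis"),
                            horizons_years = c(1, 2, 5),
                            strata = c("site", "sex", "age_band", "stage",
                                       "level"),
                            boot_B = 0) {
  if (is.null(scenario) && is.null(input_dir)) {
    stop("either scenario or input_dir is required")
  }
  if (is.character(code_map)) code_map <- read_code_map(code_map)
  structure(list(out_dir = out_dir, scenario = scenario,
                 input_dir = input_dir, seed = as.integer(seed),
                 window_months = window_months, code_map = code_map,
                 cause_map = cause_map, death_horizon = death_horizon,
                 enrollment_horizon = enrollment_horizon, stages = stages,
                 horizons_years = horizons_years, strata = strata,
                 boot_B = boot_B),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; a `scenario`
#' mapping is passed to [scenario_config()].
#'
#' @param path YAML file.
#' @param out_dir,seed overrides (e.g. from a command line).
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    for (nm in intersect(names(sc),
                         c("site_mix", "sex_mix", "age_distribution",
                           "stage_mix", "comorbidity_prevalence",
                           "true_weights", "cancer_hazard",
                           "histology_mix"))) {
      sc[[nm]] <- unlist(sc[[nm]])
    }
    if (!is.null(seed)) sc$seed <- seed
    y$scenario <- do.call(scenario_config, sc)
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

run_stage <- function(stage, enabled, fun) {
  if (!stage %in% enabled) return(NULL)
  stage_log(stage, "start")
  out <- tryCatch(fun(), error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  stage_log(stage, "done")
  out
}

#' Run the full pipeline
#'
#' Executes, in order and as enabled: simulate -> ascertain -> endpoints ->
#' split -> index -> validate -> prognosis. Every output file is listed in
#' `manifest.csv` with its MD5 content hash and the seed; re-running with
#' the same configuration and seed reproduces the hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest data.frame, invisibly; all outputs are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  enabled <- config$stages
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  catalog <- condition_catalog(code_map = config$code_map)

  ds <- run_stage("simulate", enabled, function() {
    if (is.null(config$scenario)) {
      read_linked_dataset(config$input_dir)
    } else {
      d <- generate_cohort(config$scenario)
      write_linked_dataset(d, file.path(config$out_dir, "data"))
      outputs <<- c(outputs, list.files(file.path(config$out_dir, "data"),
                                        full.names = TRUE))
      d
    }
  })
  if (is.null(ds)) ds <- read_linked_dataset(config$input_dir)

  policy <- ascertainment_policy(window_months = config$window_months)
  profiles <- run_stage("ascertain", enabled, function() {
    p <- build_profiles(ds, policy, catalog)
    emit("profiles.csv", function(f) utils::write.csv(p, f, row.names = FALSE))
    emit("prevalence.csv", function(f)
      utils::write.csv(prevalence_table(p, ds$registry$site), f,
                       row.names = FALSE))
    p
  })

  outcomes <- run_stage("endpoints", enabled, function() {
    o <- build_outcomes(ds, config$cause_map,
                        death_horizon = config$death_horizon,
                        enrollment_horizon = config$enrollment_horizon)
    emit("outcomes.csv", function(f) write_outcomes(o, f))
    o
  })

  split <- run_stage("split", enabled, function() {
    s <- nested_split(ds$registry$patient_id, config$seed)
    emit("split.csv", function(f) utils::write.csv(s, f, row.names = FALSE))
    s
  })

  model <- run_stage("index", enabled, function() {
    top <- select_top11(profiles)
    spec <- model_spec(top, catalog = catalog)
    train_ids <- split$patient_id[split$fold == "train"]
    reg_train <- ds$registry[ds$registry$patient_id %in% train_ids, ,
                             drop = FALSE]
    m <- negative_deletion_fit(reg_train, profiles, outcomes, spec)
    emit("index_model.tsv", function(f) write_index_model(m, f))
    m
  })

  run_stage("validate", enabled, function() {
    train_ids <- split$patient_id[split$fold == "train"]
    auc <- validate_index(model, ds, profiles, outcomes, split,
                          fold = "validation", train_ids = train_ids,
                          horizons_years = config$horizons_years,
                          boot_B = config$boot_B)
    emit("validation_auc.csv", function(f)
      utils::write.csv(auc, f, row.names = FALSE))
    auc
  })

  run_stage("prognosis", enabled, function() {
    sc <- tcci_score(profiles, model)
    lv <- data.frame(patient_id = profiles$patient_id, tcci = sc,
                     level = assign_level(profiles, sc, catalog$severe),
                     stringsAsFactors = FALSE)
    emit("levels.csv", function(f) utils::write.csv(lv, f, row.names = FALSE))
    emit("prognosis.csv", function(f)
      utils::write.csv(prognosis_grid(outcomes, lv, ds$registry,
                                      horizons_years = config$horizons_years,
                                      strata = config$strata), f,
                       row.names = FALSE))
    emit("stage_age_level.csv", function(f)
      utils::write.csv(stage_age_level_table(ds$registry, lv), f,
                       row.names = FALSE))
    lv
  })

  manifest <- data.frame(
    file = basename(outputs),
    path = outputs,
    md5 = unname(tools::md5sum(outputs)),
    seed = config$seed, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
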