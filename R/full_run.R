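#' Run configuration for an end-to-end harmonization study
#'
#' Bundles every stage's settings: cohort simulation, autoencoder
#' training, the harmonization modalities to compare, and the three
#' evaluation experiments. One global seed fans out to per-stage seeds
#' by fixed offsets, so a single integer reproduces the whole run.
#'
#' @param seed global seed
#' @param simulation named list of [sim_config()] arguments
#' @param adae named list of [adae_config()] arguments (seed is derived)
#' @param modalities harmonization modalities to evaluate; any of
#'   `"raw"`, `"dual_adae"`, `"combat_center_scanner"`,
#'   `"combat_scanner_center"`, `"recombat_center_scanner"`,
#'   `"recombat_scanner_center"`, `"opnested"`
#' @param experiment1 list: `n_trials` bootstrap trials
#' @param drift list: `n_iter`, `noise_variance`, `subset_fraction`
#' @param experiment3 list: `n_splits`, `split_fraction`
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1,
                       simulation = list(),
                       adae = list(),
                       modalities = c("raw", "dual_adae",
                                      "combat_center_scanner",
                                      "combat_scanner_center"),
                       experiment1 = list(n_trials = 100),
                       drift = list(n_iter = 100, noise_variance = 3,
                                    subset_fraction = 0.5),
                       experiment3 = list(n_splits = 20, split_fraction = 0.7)) {
  known <- c("raw", "dual_adae", "combat_center_scanner", "combat_scanner_center",
             "recombat_center_scanner", "recombat_scanner_center", "opnested")
  bad <- setdiff(modalities, known)
  if (length(bad) > 0) {
    stopf("run_config validation error: unknown modality '%s' (known: %s)",
          bad[1], paste(known, collapse = ", "))
  }
  if (!"raw" %in% modalities) modalities <- c("raw", modalities)
  structure(list(seed = as.integer(seed), simulation = simulation, adae = adae,
                 modalities = modalities, experiment1 = experiment1,
                 drift = drift, experiment3 = experiment3),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# compute the lesion-level feature matrix of one modality on the
# standardized confounded table
modality_features <- function(name, std_table, adae_model) {
  switch(name,
    raw = feature_matrix(std_table),
    dual_adae = adae_encode(adae_model, std_table),
    combat_center_scanner =
      feature_matrix(sequential_harmonize(std_table, c("center", "scanner"))$table),
    combat_scanner_center =
      feature_matrix(sequential_harmonize(std_table, c("scanner", "center"))$table),
    recombat_center_scanner =
      feature_matrix(sequential_harmonize(std_table, c("center", "scanner"),
                                          method = "recombat")$table),
    recombat_scanner_center =
      feature_matrix(sequential_harmonize(std_table, c("scanner", "center"),
                                          method = "recombat")$table),
    opnested = feature_matrix(opnested_select_order(std_table)$table),
    stopf("unknown modality '%s'", name))
}

#' Harmonize a lesion table with one modality
#'
#' Thin dispatcher behind the CLI `harmonize` subcommand: standardizes
#' the table, applies the requested modality, and returns the
#' transformed feature matrix (plus the trained model where relevant).
#'
#' @param table a `lesion_table`
#' @param method modality name (see [run_config()])
#' @param adae_args [adae_config()] overrides for the `dual_adae` method
#' @param seed RNG seed
#' @return list with `features` (matrix, lesion ids as rownames),
#'   `model` (for `dual_adae`), and `std_params`
#' @export
harmonize <- function(table, method = "dual_adae", adae_args = list(), seed = 1) {
  std <- standardize(table)
  model <- NULL
  if (method == "dual_adae") {
    cfg <- do.call(adae_config, utils::modifyList(list(seed = derive_seed(seed, 2L)),
                                                  adae_args))
    spec <- adae_spec(input_dim = n_features(table),
                      n_center = length(unique(table$center)),
                      n_scanner = length(unique(table$scanner)))
    model <- train_adae(init_adae(spec, seed = derive_seed(seed, 1L)), std$table, cfg)
  }
  list(features = modality_features(method, std$table, model),
       model = model, std_params = std$params)
}

#' Execute a full simulation-to-report study
#'
#' Pipeline: simulate the cohort; standardize the confounded table;
#' harmonize with every configured modality; Experiment 1 deconfusion
#' table; Experiment 2 drift report for the dual AD-AE modality (when
#' configured); Experiment 3 prognostic table. All stage seeds derive
#' from the global seed, and every output file is written
#' deterministically, so two runs with one config are byte-identical.
#'
#' @param config a `run_config`
#' @param out_dir report directory (created; `run_config.json`, the
#'   report tables, the drift report and a log end up here)
#' @return (invisibly) list with all in-memory results
#' @export
full_run <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "log.txt"))
      stopf("full_run aborted at stage '%s': %s (partial outputs in %s)",
            name, conditionMessage(e), out_dir)
    })
  }

  jsonlite::write_json(unclass(config), file.path(out_dir, "run_config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")

  say("stage simulate: seed %d", config$seed)
  cohort <- stage("simulate", {
    sim <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                 config$simulation))
    generate_cohort(sim)
  })
  say("  %d lesions, %d patients", nrow(cohort$confounded),
      length(unique(cohort$confounded$patient_id)))

  std <- stage("standardize", standardize(cohort$confounded))

  adae_model <- NULL
  if ("dual_adae" %in% config$modalities) {
    say("stage train dual_adae")
    adae_model <- stage("dual_adae", {
      cfg <- do.call(adae_config,
                     utils::modifyList(list(seed = derive_seed(config$seed, 2L)),
                                       config$adae))
      spec <- adae_spec(input_dim = n_features(cohort$confounded),
                        n_center = length(unique(cohort$confounded$center)),
                        n_scanner = length(unique(cohort$confounded$scanner)))
      train_adae(init_adae(spec, seed = derive_seed(config$seed, 1L)), std$table, cfg)
    })
    say("  trained %d epochs (best %d)", nrow(adae_model$history),
        attr(adae_model$history, "best_epoch"))
  }

  say("stage harmonize: %s", paste(config$modalities, collapse = ", "))
  feats <- stage("harmonize", {
    lapply(stats::setNames(config$modalities, config$modalities),
           modality_features, std_table = std$table, adae_model = adae_model)
  })

  say("stage experiment1: %d bootstrap trials", config$experiment1$n_trials)
  exp1 <- stage("experiment1", deconfusion_report(
    feats, labels = list(center = std$table$center, scanner = std$table$scanner),
    n_trials = config$experiment1$n_trials,
    seed = derive_seed(config$seed, 3L), baseline = "raw"))

  exp2 <- NULL
  if ("dual_adae" %in% config$modalities) {
    say("stage experiment2: drift test, %d null draws", config$drift$n_iter)
    exp2 <- stage("experiment2", {
      orig <- clouds_from_table(std$table)
      transf <- clouds_from_table(feats$dual_adae,
                                  patient_ids = std$table$patient_id)
      drift_test(orig, transf[names(orig)],
                 n_iter = config$drift$n_iter,
                 noise_variance = config$drift$noise_variance,
                 subset_fraction = config$drift$subset_fraction,
                 seed = derive_seed(config$seed, 4L))
    })
    say("  mean PCSD %.4f, empirical p %.2f", exp2$observed_mean, exp2$p_value)
    write_drift_report(exp2, file.path(out_dir, "drift_report.json"))
  }

  exp3 <- NULL
  if (!is.null(cohort$survival)) {
    say("stage experiment3: %d splits", config$experiment3$n_splits)
    exp3 <- stage("experiment3", prognostic_report(
      feats, patient_ids = std$table$patient_id, survival = cohort$survival,
      reference = if ("dual_adae" %in% config$modalities) "dual_adae" else "raw",
      reduce = setdiff(names(feats), "dual_adae"),
      n_splits = config$experiment3$n_splits,
      split_fraction = config$experiment3$split_fraction,
      seed = derive_seed(config$seed, 5L)))
  }

  write_report_tables(list(table1 = exp1$table,
                           table2 = if (is.null(exp3)) NULL else exp3$table),
                      out_dir)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  say("done: %s", out_dir)
  invisible(list(cohort = cohort, std = std, adae_model = adae_model,
                 features = feats, experiment1 = exp1, experiment2 = exp2,
                 experiment3 = exp3, out_dir = out_dir))
}
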