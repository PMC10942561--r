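#' Default run configuration
#'
#' Bundles the per-stage configurations for the end-to-end pipeline:
#' cohort simulation, signal preparation, onset and movement-unit settings,
#' the statistics options and the classifier configuration.
#'
#' @param seed global seed; each stochastic stage derives its own seed from it
#'   by a fixed offset so stages are independently reproducible.
#' @return A named list of stage configurations (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_adult = 10L, n_td = 15L, n_asd = 26L, effect_scale = 1,
                  trials_per_subject = 6L, blocks_per_trial = 4L),
    signal_prep = list(lowpass_cutoff = 10, filter_order = 4),
    onset = list(threshold_frac = 0.2),
    movement_units = list(hysteresis_frac = 0.05, rms_divisor = "mean"),
    stats = list(alpha = 0.05, q = 0.05, aggregate = "trial"),
    classifier = list(epochs = 200L, batch_size = 16L, n_folds = 10L,
                      normalization_scope = "whole_dataset", repeats = 10L)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror [default_run_config()]; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  for (section in intersect(names(user), names(cfg))) {
    if (section == "seed") next
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop(sprintf("unknown config key %s.%s", section, key), call. = FALSE)
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

stage_cfgs <- function(config) {
  list(prep = signal_prep_config(config$signal_prep$lowpass_cutoff,
                                 config$signal_prep$filter_order),
       onset = onset_config(config$onset$threshold_frac),
       mu = movement_unit_config(config$movement_units$hysteresis_frac,
                                 config$movement_units$rms_divisor))
}

classifier_from_config <- function(config, seed) {
  classifier_config(epochs = config$classifier$epochs,
                    batch_size = config$classifier$batch_size,
                    n_folds = config$classifier$n_folds,
                    normalization_scope = config$classifier$normalization_scope,
                    repeats = config$classifier$repeats, seed = seed)
}

# Binary classification + importance for two groups of a feature table.
classify_groups <- function(features, positive, negative, ccfg) {
  sub <- features[features$group %in% c(positive, negative), , drop = FALSE]
  y <- as.integer(sub$group == positive)
  cv <- cross_validate(sub, y, ccfg)
  # importance on a stratified holdout: train on ~9/10, evaluate the held-out
  set.seed(ccfg$seed + 999L)
  fold <- make_folds(y, ccfg$n_folds)
  tr <- fold != 1L
  Xn <- minmax_normalize(as_feature_matrix(sub, ccfg$feature_set))$x
  fit <- train_mlp(Xn[tr, , drop = FALSE], y[tr], ccfg,
                   Xn[!tr, , drop = FALSE], y[!tr])
  imp <- permutation_importance(fit, Xn[!tr, , drop = FALSE], y[!tr],
                                repeats = ccfg$repeats, seed = ccfg$seed)
  list(cv = cv, importance = imp,
       class_balance = c(positive = sum(y == 1L), negative = sum(y == 0L)))
}

#' Run the end-to-end pipeline
#'
#' Simulates a three-group cohort, writes it to disk, extracts the kinematic
#' feature table, runs the statistical battery, trains and cross-validates
#' the MLP for the TD-vs-ASD and adult-vs-TD contrasts, computes permutation
#' feature importance, and writes a JSON run manifest recording the seed and
#' a hash of the configuration.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, a list with the feature table, battery results, both
#'   classification results and the manifest path.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cc <- config$cohort
  spec <- three_group_cohort_spec(n_adult = cc$n_adult, n_td = cc$n_td,
                                  n_asd = cc$n_asd,
                                  effect_scale = cc$effect_scale,
                                  seed = seed + 101L,
                                  trials_per_subject = cc$trials_per_subject,
                                  blocks_per_trial = cc$blocks_per_trial)
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  cfgs <- stage_cfgs(config)
  features <- extract_cohort_features(cohort$trials, cohort$manifest,
                                      prep_cfg = cfgs$prep,
                                      onset_cfg = cfgs$onset,
                                      mu_cfg = cfgs$mu)
  write_feature_table(features, file.path(out_dir, "features.csv"))
  battery <- run_battery(features, alpha = config$stats$alpha,
                         q = config$stats$q,
                         aggregate = config$stats$aggregate)
  write_csv_num(battery$anova, file.path(out_dir, "anova.csv"))
  write_csv_num(battery$posthoc, file.path(out_dir, "posthoc.csv"))
  write_csv_num(battery$correlations, file.path(out_dir, "correlations.csv"))
  res <- list()
  for (contrast in list(c("ASD", "TD", "td_asd"), c("TD", "ADULT", "adult_td"))) {
    ccfg <- classifier_from_config(config, seed + 202L)
    r <- classify_groups(features, contrast[1L], contrast[2L], ccfg)
    write_csv_num(data.frame(fold = seq_along(r$cv$fold_accuracy),
                             accuracy = r$cv$fold_accuracy,
                             best_val_loss = r$cv$fold_best_val_loss),
                  file.path(out_dir, sprintf("cv_results_%s.csv", contrast[3L])))
    write_csv_num(r$importance,
                  file.path(out_dir, sprintf("importance_%s.csv", contrast[3L])))
    res[[contrast[3L]]] <- r
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(seed = seed,
                   config = unclass(config),
                   config_hash = unname(tools::md5sum(tmp)),
                   class_balance = lapply(res, `[[`, "class_balance"),
                   mean_cv_accuracy = lapply(res, function(r) r$cv$mean_accuracy),
                   outputs = sort(list.files(out_dir, recursive = TRUE)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(list(features = features, battery = battery,
                 classification = res,
                 manifest_path = file.path(out_dir, "run_manifest.json")))
}

cli_usage <- function() {
  paste(
    "usage: reachkin <subcommand> [options]",
    "subcommands:",
    "  simulate   --out DIR [--config FILE] [--seed N]     write a synthetic cohort",
    "  extract    --manifest FILE --out FILE [--config FILE]  feature table from trials",
    "  stats      --features FILE --out DIR [--config FILE]   ANOVA/post-hoc/correlations",
    "  train      --features FILE --out DIR [--config FILE] [--seed N]  TD-vs-ASD CV",
    "  importance --features FILE --out DIR [--config FILE] [--seed N]  permutation importance",
    "  pipeline   --out DIR [--config FILE] [--seed N]      full pipeline",
    sep = "\n")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args))
      stop("malformed arguments near: ", key, call. = FALSE)
    out[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions; see
#' `inst/cli/reachkin` for the Rscript wrapper. Diagnostics go to stderr.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return Integer exit code: 0 on success, 1 on error.
#' @export
reach_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  res <- tryCatch({
    if (length(argv) == 0L) stop(cli_usage(), call. = FALSE)
    sub <- argv[1L]
    opts <- parse_cli_args(argv[-1L])
    config <- if (!is.null(opts$config)) read_run_config(opts$config) else
      default_run_config()
    seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else config$seed
    cfgs <- stage_cfgs(config)
    switch(sub,
      simulate = {
        if (is.null(opts$out)) stop("simulate requires --out", call. = FALSE)
        cc <- config$cohort
        spec <- three_group_cohort_spec(cc$n_adult, cc$n_td, cc$n_asd,
                                        cc$effect_scale, seed = seed + 101L,
                                        trials_per_subject = cc$trials_per_subject,
                                        blocks_per_trial = cc$blocks_per_trial)
        path <- write_cohort(simulate_cohort(spec), opts$out)
        message("wrote ", path)
      },
      extract = {
        if (is.null(opts$manifest) || is.null(opts$out))
          stop("extract requires --manifest and --out", call. = FALSE)
        co <- read_trials(opts$manifest)
        ft <- extract_cohort_features(co$trials, co$manifest,
                                      prep_cfg = cfgs$prep,
                                      onset_cfg = cfgs$onset, mu_cfg = cfgs$mu)
        write_feature_table(ft, opts$out)
        message("wrote ", opts$out)
      },
      stats = {
        if (is.null(opts$features) || is.null(opts$out))
          stop("stats requires --features and --out", call. = FALSE)
        ft <- read_feature_table(opts$features)
        battery <- run_battery(ft, alpha = config$stats$alpha,
                               q = config$stats$q,
                               aggregate = config$stats$aggregate)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        write_csv_num(battery$anova, file.path(opts$out, "anova.csv"))
        write_csv_num(battery$posthoc, file.path(opts$out, "posthoc.csv"))
        write_csv_num(battery$correlations,
                      file.path(opts$out, "correlations.csv"))
        message("wrote ", opts$out)
      },
      train = ,
      importance = {
        if (is.null(opts$features) || is.null(opts$out))
          stop(sub, " requires --features and --out", call. = FALSE)
        ft <- read_feature_table(opts$features)
        r <- classify_groups(ft, "ASD", "TD",
                             classifier_from_config(config, seed + 202L))
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        if (sub == "train") {
          write_csv_num(data.frame(fold = seq_along(r$cv$fold_accuracy),
                                   accuracy = r$cv$fold_accuracy,
                                   best_val_loss = r$cv$fold_best_val_loss),
                        file.path(opts$out, "cv_results.csv"))
        } else {
          write_csv_num(r$importance, file.path(opts$out, "importance.csv"))
        }
        message("wrote ", opts$out)
      },
      pipeline = {
        if (is.null(opts$out)) stop("pipeline requires --out", call. = FALSE)
        run_pipeline(config, opts$out, seed = seed)
        message("wrote ", opts$out)
      },
      stop("unknown subcommand: ", sub, "\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}
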