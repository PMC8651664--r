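# Run configuration (YAML) and the end-to-end pipeline:
# simulate-cohort -> augment -> fit-arte -> train ensemble -> recommend ->
# evaluate, with every stage resumable from its files on disk and every
# JSON artifact stamped with the configuration hash and seed.

#' Default run configuration
#'
#' Nested configuration covering every pipeline stage. Any field can be
#' overridden from a YAML file via [read_run_config()]; unknown keys are
#' rejected.
#'
#' @param seed Global seed; stage seeds derive from it.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_patients = 200L),
    arte = list(
      alpha_beta_tumor = 10, alpha_beta_lung = 4,
      a_tumor = -10, a_lung = 1,
      kappa_tumor = 10, kappa_lung = 3,
      protocol_dose = 2.0, max_steps = 10L
    ),
    qdecision = list(
      n_qubits = 5L, d_min = 1.0, d_max = 4.1,
      backend = "controller-sim", shots = 256L
    ),
    agent = list(
      gamma = 0.99, episodes = 300L, batch = 64L, lr = 1e-3,
      eps_decay_steps = 1000L, target_sync = 100L,
      hidden = c(64, 64, 64), ensemble_size = 5L
    ),
    augmentation = list(
      enabled = TRUE, n_generate = 4000L, epochs = 400L,
      use_for_training = TRUE
    ),
    evaluation = list()
  ), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop_config("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Values not present fall back to [default_run_config()]; keys absent from
#' the default schema raise a configuration error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  cfg
}

write_stamped_json <- function(x, path, hash, seed) {
  jsonlite::write_json(c(list(config_hash = hash, seed = seed), x), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes, in order: synthetic cohort simulation, WGAN-GP augmentation,
#' environment fitting, ensemble training, recommendation, and evaluation.
#' Each stage writes its artifacts under `out_dir` and, with
#' `resume = TRUE`, is skipped when its outputs already exist. A
#' `manifest.json` records the configuration hash, seed and file list;
#' every JSON artifact embeds the same hash, so identical (config, seed)
#' runs under the noiseless backend are byte-identical.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param resume Skip stages whose outputs exist.
#' @return The [evaluate_cohort()] report, invisibly, with the artifact
#'   paths in attribute `files`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, resume = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  pth <- function(f) file.path(out_dir, f)
  files <- c(cohort = pth("cohort.csv"),
             augmented = pth("cohort_augmented.csv"),
             traces = pth("episode_traces.jsonl"),
             recommendations = pth("recommendations.csv"),
             report = pth("evaluation.json"),
             manifest = pth("manifest.json"))

  # stage: simulate-cohort
  if (!(resume && file.exists(files["cohort"]))) {
    ccfg <- do.call(cohort_config,
                    c(config$cohort, list(seed = seed,
                                          kappa_tumor = config$arte$kappa_tumor,
                                          kappa_lung = config$arte$kappa_lung)))
    write_cohort(generate_cohort(ccfg), files["cohort"])
  }
  cohort <- read_cohort(files["cohort"])

  # stage: augment
  if (isTRUE(config$augmentation$enabled)) {
    if (!(resume && file.exists(files["augmented"]))) {
      gcfg <- gan_config(n_generate = config$augmentation$n_generate,
                         epochs = config$augmentation$epochs,
                         seed = seed + 1L)
      write_cohort(augment_cohort(cohort, gcfg), files["augmented"])
    }
    augmented <- read_cohort(files["augmented"])
  } else {
    augmented <- NULL
  }

  # stage: fit-arte
  grid <- build_dose_grid(config$qdecision$n_qubits,
                          config$qdecision$d_min, config$qdecision$d_max)
  params <- radiobio_params(
    alpha_beta_tumor = config$arte$alpha_beta_tumor,
    alpha_beta_lung = config$arte$alpha_beta_lung,
    a_tumor = config$arte$a_tumor, a_lung = config$arte$a_lung,
    kappa_tumor = config$arte$kappa_tumor, kappa_lung = config$arte$kappa_lung)
  fit <- fit_arte(cohort, grid, params,
                  protocol_dose = config$arte$protocol_dose,
                  max_steps = config$arte$max_steps, seed = seed + 2L)

  # stage: train ensemble
  train_pool <- if (isTRUE(config$augmentation$use_for_training) &&
                    !is.null(augmented)) {
    rbind(cohort[, cohort_columns], augmented[, cohort_columns])
  } else {
    cohort
  }
  tcfg <- train_config(
    gamma = config$agent$gamma, episodes = config$agent$episodes,
    batch = config$agent$batch, lr = config$agent$lr,
    eps_decay_steps = config$agent$eps_decay_steps,
    target_sync = config$agent$target_sync,
    hidden = config$agent$hidden,
    max_steps = config$arte$max_steps,
    ensemble_size = config$agent$ensemble_size,
    backend = config$qdecision$backend, shots = config$qdecision$shots,
    seed = seed + 3L)
  ckpt_paths <- pth(sprintf("agent_%d.rds", seq_len(tcfg$ensemble_size)))
  if (resume && all(file.exists(ckpt_paths))) {
    ensemble <- structure(lapply(ckpt_paths, load_agent), class = "qdrl_ensemble")
  } else {
    ensemble <- train_ensemble(cohort_states(train_pool), fit$env, grid, tcfg)
    for (k in seq_along(ensemble)) save_agent(ensemble[[k]], ckpt_paths[k], hash)
  }
  write_episode_log(lapply(ensemble, function(a) a$traces), files["traces"])

  # stage: recommend (for the real cohort)
  rec <- recommend_dose(ensemble, cohort_states(cohort))
  rec$patient_id <- cohort$patient_id
  utils::write.csv(rec[, c("patient_id", "dose_mean", "dose_sem", "q_mean")],
                   files["recommendations"], row.names = FALSE, quote = FALSE)

  # stage: evaluate
  report <- evaluate_cohort(cohort, rec)
  write_eval_report(report, files["report"],
                    meta = list(config_hash = hash, seed = seed))
  write_stamped_json(list(files = as.list(files)), files["manifest"], hash, seed)

  attr(report, "files") <- files
  invisible(report)
}
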