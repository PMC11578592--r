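## End-to-end pipeline: simulate -> kinematics -> ERP extraction ->
## single-trial models -> mediation (cluster tests are run separately,
## at whatever grid size the analysis calls for).

#' Default run configuration
#'
#' @param seed integer master seed.
#' @param out_dir optional output directory; NULL keeps results in
#'   memory only.
#' @param generator a [generator_config()]; built from `seed` when NULL.
#' @param stages stages to run, in order.
#' @param mediation_n_perm permutations for the mediation stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL, generator = NULL,
                       stages = c("simulate", "kinematics", "erp", "fit",
                                  "mediate"),
                       mediation_n_perm = 2500) {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(list(seed = seed, out_dir = out_dir, generator = generator,
                 stages = stages, mediation_n_perm = mediation_n_perm),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys `seed`, `out_dir`, `stages`, `mediation_n_perm`, and a
#' `generator` block whose entries override [generator_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (is.null(gen_args$seed)) gen_args$seed <- y$seed %||% 1
  gen <- do.call(generator_config, gen_args)
  run_config(seed = y$seed %||% 1, out_dir = y$out_dir,
             generator = gen,
             stages = y$stages %||% c("simulate", "kinematics", "erp",
                                      "fit", "mediate"),
             mediation_n_perm = y$mediation_n_perm %||% 2500)
}

## ERP window means for a (possibly large) trial table, generated and
## extracted one participant at a time to bound memory
extract_erp_measures <- function(trials, config) {
  parts <- unique(trials$participant)
  res <- vector("list", length(parts))
  rej <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    sub <- trials[trials$participant == parts[i], , drop = FALSE]
    prep <- generate_eeg_epochs(sub, config, "preparation")
    inc <- generate_eeg_epochs(sub, config, "incentive")
    flags <- data.frame(trial_id = sub$trial_id,
                        ocular = sub$eeg_artifact_type %in% "ocular")
    prep <- epoch_and_baseline(prep, c(prep$times[1], 1500))
    inc <- epoch_and_baseline(inc, c(inc$times[1], 1100))
    kept <- reject_artifacts(prep, flags)
    rej[[i]] <- kept$rejections
    keep_ids <- kept$epochs$trial_ids
    inc_keep <- subset_epochs(inc, keep_ids)
    res[[i]] <- erp_measures(kept$epochs, inc_keep, baselined = TRUE)
  }
  list(measures = do.call(rbind, res), rejections = do.call(rbind, rej))
}

#' Run the full pipeline on synthetic data
#'
#' Executes the requested stages: `simulate` (trial table), `kinematics`
#' (residual velocity, log RT, inclusion flags), `erp` (epoch
#' generation, artifact rejection, window means merged into the table),
#' `fit` (the factorial single-trial models for the three behavioural
#' and three ERP outcomes plus the ERP ~ behaviour matrix), and
#' `mediate` (mediation of the incentive effect on RT and velocity by
#' the CNV, plus the drug mediated moderation for RT). When `out_dir`
#' is set, every table is written as CSV/JSON stamped with the config
#' hash and seed.
#'
#' @param config a [run_config()].
#' @return list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  res <- list(seed = config$seed, config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  trials <- stage("simulate", generate_trial_table(gen))
  message(sprintf("simulate: %d trials (%d participants x %d sessions)",
                  nrow(trials), gen$n_participants, 2L))

  if ("kinematics" %in% config$stages) {
    trials <- stage("kinematics", {
      tr <- residual_velocity(trials)
      tr$log_rt <- ifelse(is.finite(tr$rt_ms) & tr$rt_ms > 0,
                          log(tr$rt_ms), NA_real_)
      tr$included <- !tr$missed & is.finite(tr$rt_ms) &
        tr$rt_ms >= 100 & tr$rt_ms <= 900 &
        is.finite(tr$peak_velocity) &
        tr$peak_velocity >= 50 & tr$peak_velocity <= 1600
      tr$exclusion_reason <- ifelse(tr$included, NA_character_,
                                    ifelse(tr$missed, "no_primary_saccade",
                                           "bounds"))
      tr
    })
    message(sprintf("kinematics: %d/%d trials included",
                    sum(trials$included), nrow(trials)))
  }

  if ("erp" %in% config$stages) {
    erp <- stage("erp", extract_erp_measures(trials, gen))
    keep <- c("trial_id", setdiff(names(erp$measures), "trial_id"))
    m <- match(trials$trial_id, erp$measures$trial_id)
    trials$p3a <- erp$measures$p3a[m]
    trials$cnv <- erp$measures$cnv[m]
    trials$pre_preparation <- erp$measures$pre_preparation[m]
    res$rejections <- erp$rejections
    retained <- sum(!erp$rejections$rejected)
    message(sprintf("erp: %d/%d trials retained (%.1f/%d per condition)",
                    retained, nrow(trials),
                    retained / (gen$n_participants * 2 * 4),
                    gen$n_blocks * gen$trials_per_condition_per_block))
  }
  res$trials <- trials

  if ("fit" %in% config$stages) {
    res$fits <- stage("fit", {
      beh <- trials[trials$included %in% TRUE, ]
      fits <- list(
        residual_velocity = fit_single_trial_model(beh, "residual_velocity"),
        log_rt = fit_single_trial_model(beh, "rt_ms", transform = "log"),
        pull_deg = fit_single_trial_model(beh, "pull_deg"))
      erp_ok <- trials[!is.na(trials$cnv), ]
      fits$cnv <- fit_single_trial_model(erp_ok, "cnv")
      fits$p3a <- fit_single_trial_model(erp_ok, "p3a")
      fits$pre_preparation <- fit_single_trial_model(
        erp_ok[!is.na(erp_ok$pre_preparation), ], "pre_preparation")
      both <- trials[trials$included %in% TRUE & !is.na(trials$cnv), ]
      both$log_rt <- log(both$rt_ms)
      fits$erp_behaviour <- fit_erp_behaviour_models(both)
      fits
    })
  }

  if ("mediate" %in% config$stages) {
    res$mediation <- stage("mediate", {
      med <- trials[trials$included %in% TRUE & !is.na(trials$cnv), ]
      med$log_rt <- log(med$rt_ms)
      list(
        rt = mediation_test(med, outcome = "log_rt",
                            n_perm = config$mediation_n_perm,
                            seed = config$seed + 101),
        velocity = mediation_test(med, outcome = "residual_velocity",
                                  n_perm = config$mediation_n_perm,
                                  seed = config$seed + 102),
        rt_moderation = mediated_moderation_test(
          med, outcome = "log_rt", n_perm = config$mediation_n_perm,
          seed = config$seed + 103))
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(config$out_dir, "run_config.yaml")
    yaml::write_yaml(list(seed = config$seed,
                          generator = gen[setdiff(names(gen), "layout")],
                          stages = config$stages), cfg_path)
    stamp <- list(seed = config$seed,
                  config_md5 = unname(tools::md5sum(cfg_path)),
                  package_version = as.character(
                    utils::packageVersion("vigoureeg")))
    jsonlite::write_json(stamp, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
    write_trial_table(res$trials, file.path(config$out_dir, "trials.csv"))
    if (!is.null(res$fits)) {
      for (nm in setdiff(names(res$fits), "erp_behaviour")) {
        utils::write.csv(as.data.frame(res$fits[[nm]]),
                         file.path(config$out_dir,
                                   sprintf("fit_%s.csv", nm)),
                         row.names = FALSE)
      }
      utils::write.csv(as.data.frame(res$fits$erp_behaviour),
                       file.path(config$out_dir, "fit_erp_behaviour.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$mediation)) {
      to_json <- lapply(res$mediation, function(m) {
        m$null <- NULL
        unclass(m)
      })
      jsonlite::write_json(to_json,
                           file.path(config$out_dir, "mediation.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  class(res) <- "pipeline_result"
  res
}
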