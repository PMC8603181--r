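# End-to-end orchestration: simulate -> extract -> analyze (plus the
# optional consensus sub-pipeline), with a manifest that makes a run
# reproducible from a single master seed.

# documented stage-seed derivation: one master seed fans out deterministically
derive_seed <- function(master_seed, stage) {
  offsets <- c(simulate = 101L, consensus = 211L)
  as.integer((as.numeric(master_seed) * 7919 + offsets[[stage]]) %%
               (.Machine$integer.max - 1))
}

#' Pipeline run configuration
#'
#' @param master_seed Single integer reproducing the whole run; stage seeds
#'   are derived from it deterministically.
#' @param n_healthy,n_mci Cohort sizes (study design: 23 and 23).
#' @param game_seeds Deal seeds played in order by every participant.
#' @param profiles Named list of group [cognitive_profile()]s; defaults to
#'   [healthy_profile()] / [mci_profile()].
#' @param alpha Significance level for the results filter, in (0, 1].
#' @param include_neutral Count aborted drags in the board-move denominator.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(master_seed = 1L, n_healthy = 23L, n_mci = 23L,
                       game_seeds = default_game_seeds(),
                       profiles = NULL, alpha = 0.05,
                       include_neutral = FALSE, out_dir = tempfile("sbm_run_")) {
  stopifnot(alpha > 0, alpha <= 1, n_healthy >= 1, n_mci >= 1,
            length(game_seeds) >= 1)
  structure(list(schema = "sbm-run/1", master_seed = as.integer(master_seed),
                 n_healthy = as.integer(n_healthy), n_mci = as.integer(n_mci),
                 game_seeds = as.integer(game_seeds), profiles = profiles,
                 alpha = alpha, include_neutral = include_neutral,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates the cohort, writes one JSONL log per participant-game plus the
#' participants CSV, extracts the biomarker analysis table, fits the
#' per-biomarker mixed models with the likelihood-ratio test and R-squared,
#' applies the significance filter, optionally runs the expert-rating
#' consensus analysis, and writes a JSON manifest (config, derived seeds,
#' package version, row counts, per-stage status). If a stage fails, the
#' manifest records the stage and error before the error is re-signalled.
#'
#' @param config A [run_config()] (or a path to a YAML file with its
#'   fields).
#' @param ratings Optional long ratings tibble for the consensus
#'   sub-pipeline.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, ratings = NULL) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- run_config(master_seed = cfg$master_seed %||% 1L,
                         n_healthy = cfg$n_healthy %||% 23L,
                         n_mci = cfg$n_mci %||% 23L,
                         game_seeds = cfg$game_seeds %||% default_game_seeds(),
                         alpha = cfg$alpha %||% 0.05,
                         include_neutral = isTRUE(cfg$include_neutral),
                         out_dir = cfg$out_dir %||% tempfile("sbm_run_"))
  }
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "logs"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema = config$schema,
                   package_version = as.character(utils::packageVersion("solitairebm")),
                   master_seed = config$master_seed,
                   stage_seeds = list(simulate = derive_seed(config$master_seed,
                                                             "simulate")),
                   config = config[c("n_healthy", "n_mci", "game_seeds",
                                     "alpha", "include_neutral")],
                   stages = list())
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       error = conditionMessage(res))
      finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  cohort <- stage("simulate", {
    profs <- config$profiles %||% list(healthy = healthy_profile(),
                                       mci = mci_profile())
    generate_cohort(config$n_healthy, config$n_mci, profiles = profs,
                    game_seeds = config$game_seeds,
                    rng_seed = derive_seed(config$master_seed, "simulate"))
  })
  manifest$stages$simulate$n_participants <- nrow(cohort$participants)
  manifest$stages$simulate$n_logs <- length(cohort$logs)

  stage("write_logs", {
    utils::write.csv(cohort$participants, file.path(out, "participants.csv"),
                     row.names = FALSE)
    for (log in cohort$logs) {
      write_event_log(log, file.path(out, "logs",
                                     sprintf("%s_game%d.jsonl",
                                             log$participant_id,
                                             log$game_index)))
    }
  })

  tab <- stage("extract", {
    tab <- cohort_table(cohort$logs, cohort$participants,
                        include_neutral = config$include_neutral)
    utils::write.csv(tab, file.path(out, "analysis_table.csv"),
                     row.names = FALSE)
    tab
  })
  manifest$stages$extract$n_rows <- nrow(tab)

  res <- stage("analyze", {
    if (config$n_healthy < 2 || config$n_mci < 2) {
      stop("mixed-model analysis needs at least 2 participants per group",
           call. = FALSE)
    }
    res <- results_table(tab)
    utils::write.csv(res, file.path(out, "results.csv"), row.names = FALSE)
    res
  })
  manifest$stages$analyze$n_rows <- nrow(res)
  manifest$stages$analyze$n_significant <-
    significance_filter(res, config$alpha)$n_retained

  if (!is.null(ratings)) {
    stage("consensus", {
      utils::write.csv(ratings_summary(ratings),
                       file.path(out, "consensus_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(icc_by(ratings, "player_action"),
                       file.path(out, "consensus_icc.csv"), row.names = FALSE)
    })
  }

  finish()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
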