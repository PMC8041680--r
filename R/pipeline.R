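#' Default end-to-end run configuration
#'
#' A fully serialisable list describing one reproducible run: task layout,
#' simulation scenario, detector settings, segmentation rules, metric
#' options, RQA/MultiMatch options and the statistics plan.  Every field
#' can be overridden; [run_study()] consumes it.
#'
#' @param seed Run seed.
#' @param n_per_group Participants per group, in the order of `profiles`.
#' @param render_samples If `TRUE`, raw samples are rendered and fixations
#'   re-detected with the I-DT detector; otherwise ground-truth fixations
#'   feed segmentation directly (fast; identical in expectation).
#' @return A nested `vs_config` list.
#' @export
default_config <- function(seed = 1, n_per_group = c(29, 23, 15, 18),
                           render_samples = FALSE) {
  structure(list(
    seed = seed,
    simulate = list(n_per_group = n_per_group,
                    render_samples = render_samples,
                    sampling_rate = 120, jitter_deg = 0.12),
    detector = list(min_duration_ms = 60, max_dispersion_deg = 2,
                    dispersion_metric = "sum", gap_bridge_ms = 75),
    segmentation = list(window_ms = c(1700, 3300),
                        max_prescan_fixations = 1,
                        max_prescan_duration_ms = 300),
    metrics = list(min_trials = 10),
    rqa = list(min_line_length = 2),
    multimatch = list(amp_threshold = 0.1, dir_threshold_deg = 45,
                      dur_threshold_ms = 300, aggregate = "median"),
    stats = list(
      variables = c("mean_entry_to_cue", "mean_cue_fix_duration",
                    "mean_cue_fix_count", "mean_entry_to_grid",
                    "mean_search_fix_duration", "mean_search_fix_count",
                    "sd_entry_to_cue", "sd_cue_fix_duration",
                    "sd_cue_fix_count", "sd_entry_to_grid",
                    "sd_search_fix_duration", "sd_search_fix_count",
                    "rt_mean", "rtsd"),
      outlier_rule = character(0), k_sd = 3)),
    class = c("vs_config", "list"))
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file.
#' @return A `vs_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  class(cfg) <- c("vs_config", "list")
  cfg
}

#' Run the full pipeline: simulate, detect, segment, summarise, compare
#'
#' Executes simulate -> (optionally render + I-DT detect) -> AOI labelling
#' -> segmentation -> per-trial metrics -> participant summaries -> RQA
#' (per trial + subtracted ISV) -> MultiMatch ISV -> group statistics, and
#' writes every stage's table as TSV plus a JSON run manifest (config,
#' config hash, package and R versions, seed).  Outputs are pure functions
#' of (config, seed): re-running with the same configuration reproduces
#' all tables bit-identically.
#'
#' @param config A `vs_config` list ([default_config()] / [read_config()]).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the tables.
#' @param profiles,layout Optional overrides of the simulation scenario.
#' @return Invisibly, a named list with all stage outputs: `participants`,
#'   `validity`, `trial_features`, `participant_summary`, `rqa_trials`,
#'   `rqa_isv`, `multimatch_isv`, `group_stats` (+ `posthoc`), `manifest`.
#' @export
run_study <- function(config = default_config(), out_dir = NULL,
                      profiles = default_profiles(),
                      layout = task_layout()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }
  scr <- layout$screen

  study <- stage("simulate", simulate_group_study(
    profiles = profiles, n_per_group = config$simulate$n_per_group,
    layout = layout, seed = config$seed,
    render_samples = isTRUE(config$simulate$render_samples),
    sampling_rate = config$simulate$sampling_rate,
    jitter_deg = config$simulate$jitter_deg))

  fixations <- stage("detect", {
    if (isTRUE(config$simulate$render_samples)) {
      det <- imap(study$samples, function(s, id) {
        fx <- detect_fixations(
          s, screen = scr,
          min_duration = config$detector$min_duration_ms,
          max_dispersion = config$detector$max_dispersion_deg,
          dispersion_metric = config$detector$dispersion_metric,
          gap_bridge = config$detector$gap_bridge_ms,
          sampling_rate = config$simulate$sampling_rate)
        mutate(fx, participant_id = id, .before = 1)
      })
      list_rbind(det)
    } else {
      study$fixations[, c("participant_id", "start", "end", "x", "y",
                          "duration")]
    }
  })

  segments <- stage("segment", {
    meta <- score_responses(study$meta, study$responses)
    fx <- assign_trials(fixations, study$meta, layout$trial_span) |>
      label_fixations(layout)
    seg <- segment_trials(
      fx, meta,
      window = config$segmentation$window_ms,
      max_prescan_fixations = config$segmentation$max_prescan_fixations,
      max_prescan_duration = config$segmentation$max_prescan_duration_ms)
    list(fixations = fx, segments = seg)
  })
  fx_labeled <- segments$fixations
  seg <- segments$segments
  validity <- tabulate_validity(seg)

  feats <- stage("metrics", {
    trial_features(fx_labeled, seg,
                   cross_duration = layout$cross_duration) |>
      left_join(study$participants[, c("participant_id", "group")],
                by = "participant_id")
  })
  summaries <- stage("metrics", summarize_participants(
    feats, min_trials = config$metrics$min_trials))

  rqa_tr <- stage("rqa", rqa_trials(fx_labeled, seg,
                                    min_line = config$rqa$min_line_length))
  rqa_sub <- stage("rqa", rqa_isv(rqa_tr))

  mm <- stage("multimatch", multimatch_isv(
    fx_labeled, seg, screen = scr,
    amp_threshold = config$multimatch$amp_threshold,
    dir_threshold = config$multimatch$dir_threshold_deg,
    dur_threshold = config$multimatch$dur_threshold_ms,
    aggregate = config$multimatch$aggregate))

  gs <- stage("stats", group_stats(
    summaries, variables = config$stats$variables,
    outlier_rule = config$stats$outlier_rule, k_sd = config$stats$k_sd))

  manifest <- list(
    package = "visearch",
    version = as.character(utils::packageVersion("visearch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config))

  out <- list(participants = study$participants, validity = validity,
              trial_features = feats, participant_summary = summaries,
              rqa_trials = rqa_tr, rqa_isv = rqa_sub, multimatch_isv = mm,
              group_stats = gs$comparisons, posthoc = gs$posthoc,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("participants", "validity", "trial_features",
                "participant_summary", "rqa_trials", "rqa_isv",
                "multimatch_isv", "group_stats", "posthoc")
    for (tb in tables) {
      write_table(out[[tb]], file.path(out_dir, paste0(tb, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    n_rej <- sum(seg$status == "rejected")
    inform(paste0("run complete: ", nrow(study$participants),
                  " participants, ", nrow(seg), " trials (",
                  sum(seg$status == "valid"), " valid, ", n_rej,
                  " rejected); tables in ", out_dir))
  }
  invisible(out)
}
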