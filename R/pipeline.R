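# End-to-end driver binding the synthetic generators to the analysis
# stages. A pipeline run is fully determined by (config, seed): rerunning
# with the same config reproduces every output byte for byte.

default_config <- function() {
  list(seed = 1,
       out_dir = "dendromito-run",
       stages = c("proteome", "stack", "photoactivation", "profile",
                  "spine", "calcium"),
       stack = list(overlap_fraction = 0.5, snr = 10),
       photoactivation = list(compartment_length = 10, loss_rate = 0.005,
                              snr = 20),
       spine = list(base_sigma = 0.25,
                    growth_profile = c(0, 0.35, 0.38, 0.4, 0.4, 0.4, 0.4, 0.4),
                    snr = 10),
       profile = list(length = 500, rho = 0.8, n_shuffles = 1000),
       calcium = list(n_peaks = 3, peak_sign = 1, snr = 5),
       proteome = list(n_true = 129))
}

#' Load a pipeline configuration
#'
#' @param config a named list, or a path to a YAML file with the same
#'   structure. Unknown keys are rejected. Omitted keys take defaults.
#' @return validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  bad_stage <- setdiff(cfg$stages, names(def)[-(1:3)])
  if (length(bad_stage))
    stop("unknown stage(s) in config$stages: ",
         paste(bad_stage, collapse = ", "))
  assert_scalar_finite(cfg$seed, "seed")
  cfg
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full quantification pipeline on synthetic data
#'
#' Executes the requested stages: each stage generates its synthetic
#' input from the config seed, runs the corresponding quantification, and
#' writes CSV/JSON outputs plus a consolidated `report.json` under
#' `out_dir`. Every stochastic step derives its seed from `config$seed`,
#' so a rerun with the same config is byte-identical.
#'
#' @param config a config list or YAML path (see [load_config()]).
#' @return the run report (named list, one entry per executed stage),
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list())
  seed_for <- function(stage)
    cfg$seed + match(stage, c("proteome", "stack", "photoactivation",
                              "profile", "spine", "calcium")) * 1000L

  for (stage in cfg$stages) {
    sd <- seed_for(stage)
    res <- switch(stage,
      proteome = stage_proteome(cfg$proteome, sd, cfg$out_dir),
      stack = stage_stack(cfg$stack, sd, cfg$out_dir),
      photoactivation = stage_photoactivation(cfg$photoactivation, sd, cfg$out_dir),
      profile = stage_profile(cfg$profile, sd, cfg$out_dir),
      spine = stage_spine(cfg$spine, sd, cfg$out_dir),
      calcium = stage_calcium(cfg$calcium, sd, cfg$out_dir))
    res$seed <- sd
    report$stages[[stage]] <- res
  }
  write_json_out(report, file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

stage_proteome <- function(p, seed, out_dir) {
  g <- do.call(gen_proteomics_tables, c(p, list(seed = seed)))
  rep_ <- run_filter_cascade(g$experiments, g$controls, g$db)
  write.csv(data.frame(protein_id = rep_$consensus_set,
                       go_mito = rep_$consensus_set %in% rep_$mito_annotated,
                       go_er = rep_$consensus_set %in% rep_$er_annotated,
                       interactor_class = unname(rep_$classification)),
            file.path(out_dir, "proteome_consensus.csv"), row.names = FALSE)
  cnt <- attr(rep_$classification, "counts")
  list(outputs = "proteome_consensus.csv",
       consensus_n = length(rep_$consensus_set),
       mito_annotated_n = length(rep_$mito_annotated),
       actin_only = unname(cnt[["actin_only"]]),
       tubulin_only = unname(cnt[["tubulin_only"]]),
       both = unname(cnt[["both"]]),
       soluble_top_pct = if (length(rep_$overlap_counts))
         unname(rep_$overlap_counts$top[["percentage"]]) else NA)
}

stage_stack <- function(p, seed, out_dir) {
  g <- do.call(gen_two_channel_stack, c(p, list(seed = seed)))
  mito <- segment_channel(g$stack, "mito", "otsu")
  actin <- segment_channel(g$stack, "actin", "otsu")
  pct <- interaction_percentage(mito, actin)
  write.csv(data.frame(region = "dendrite",
                       mito_volume_um3 = volume_um3(mito),
                       coloc_volume_um3 = volume_um3(mito) * pct / 100,
                       interaction_pct = pct,
                       planted_pct = g$truth$params$overlap_pct),
            file.path(out_dir, "interaction.csv"), row.names = FALSE)
  list(outputs = "interaction.csv", interaction_pct = pct,
       planted_pct = g$truth$params$overlap_pct)
}

stage_photoactivation <- function(p, seed, out_dir) {
  g <- do.call(gen_photoactivation_series, c(p, list(seed = seed)))
  act <- g$truth$params$activation_frame
  fr <- get_frame(g$stack, act)
  thr <- otsu_threshold(fr)
  lens <- compartment_length_series(g$stack, thr, act)
  trace <- roi_fluorescence_series(g$stack, thr, act)
  write.csv(data.frame(frame = seq_along(lens),
                       time_min = trace$times,
                       length_um = lens,
                       F = trace$roi_fluorescence),
            file.path(out_dir, "photoactivation.csv"), row.names = FALSE)
  list(outputs = "photoactivation.csv",
       stability_index = stability_index(trace),
       length_5min_um = lens[frame_at_minutes_post(act, 5, g$stack$frame_interval)],
       planted_length_um = g$truth$params$length_um,
       planted_stability = g$truth$params$stability_55min)
}

stage_profile <- function(p, seed, out_dir) {
  g <- gen_line_profile_pair(length = p$length, rho = p$rho, seed = seed)
  nul <- shuffled_null(g$a, g$b, n_shuffles = p$n_shuffles, seed = seed + 1)
  out <- list(observed_r = nul$observed_r,
              null_mean_r = mean(nul$null_rs),
              empirical_p = nul$empirical_p,
              planted_rho = p$rho)
  write_json_out(out, file.path(out_dir, "profile_correlation.json"))
  c(list(outputs = "profile_correlation.json"), out)
}

stage_spine <- function(p, seed, out_dir) {
  g <- do.call(gen_spine_timelapse, c(p, list(seed = seed)))
  tr <- g$truth$params
  nt <- length(tr$timepoints_min)
  widths <- vapply(seq_len(nt), function(i) {
    img <- preprocess_timepoint(array(g$stack$data[, , , i],
                                      dim(g$stack$data)[1:3]))
    fit <- spine_head_width(img, center = tr$head_center_px,
                            direction = c(1, 0), length_um = 3,
                            pixel_size_um = g$stack$voxel_size[1] / 1000)
    fit$fwhm_um
  }, 0)
  rec <- spine_record("synthetic", "induced", 0, widths,
                      timepoints = tr$timepoints_min)
  tc <- plasticity_time_course(list(rec))
  tc$planted_fwhm_um <- tr$fwhm_um
  write.csv(tc, file.path(out_dir, "spine_plasticity.csv"), row.names = FALSE)
  list(outputs = "spine_plasticity.csv",
       final_width_ratio = unname(widths[nt] / widths[1]),
       planted_ratio = unname(tr$sigma_um[nt] / tr$sigma_um[1]))
}

stage_calcium <- function(p, seed, out_dir) {
  g <- do.call(gen_calcium_trace, c(p, list(seed = seed)))
  ct <- delta_f_over_f(g$raw, g$baseline_window, g$times_s)
  dirn <- if (g$truth$params$peak_sign > 0) "positive" else "negative"
  pk <- detect_peaks(ct, direction = dirn)
  write.csv(data.frame(time_s = ct$times, raw = ct$raw, dff = ct$dff),
            file.path(out_dir, "calcium_trace.csv"), row.names = FALSE)
  out <- list(peak_times_s = pk$peak_times,
              peak_values = pk$peak_values,
              mean_peak_value = pk$mean_peak_value,
              planted_times_s = g$truth$params$peak_times_s)
  write_json_out(out, file.path(out_dir, "calcium_peaks.json"))
  list(outputs = c("calcium_trace.csv", "calcium_peaks.json"),
       n_detected = length(pk$peak_frames),
       n_planted = length(g$truth$params$peak_frames),
       mean_peak_value = pk$mean_peak_value)
}
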