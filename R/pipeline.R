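# Orchestration: declarative config with materialised defaults, stage
# runners with a reproducibility manifest, and the study-shaped hierarchical
# averaging (images -> slices -> animals).

#' Default study configuration
#'
#' Every tunable of every stage with its default value. [resolve_config()]
#' merges a user config over these defaults so the resolved config is fully
#' explicit (no hidden defaults at run time). `puncta$pixel_size_um` defaults
#' to 0.1 um/px but must be set deliberately for real data (the 63x pixel
#' size is acquisition-dependent).
#'
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    hierarchy = list(images_per_slice = 3L, slices_per_animal = 5L),
    calcium = list(smoothing_frames = 100L, threshold_multiplier = 2.25,
                   baseline_eligibility_dff = 0.1, min_area_dff_s = 0.15,
                   n_baseline_points = 100L, sd_on = "raw_dff",
                   lesion_frame = NA, pre_window_s = 20),
    puncta = list(pixel_size_um = 0.1,
                  pre_threshold = c(15, 255), post_threshold = c(30, 255),
                  rolling_ball_radius_px = 10, connectivity = 8L),
    phago = list(min_beads = 1L),
    spatial = list(metric = "euclidean", sd_type = "population"),
    ephys = list(threshold_pA = 15, min_interval_ms = 5,
                 filter_cutoff_hz = 2000, baseline_window_s = 180,
                 post_delay_s = 100, post_window_s = 180,
                 segment_s = 20, temp_C = 33,
                 ttx_onset_s = NA, agonist_onset_s = NA,
                 polarity = "inward"),
    simulate = list(trace = list(n_traces = 10L),
                    puncta = list(), scene = list(n_fovs = 1L),
                    pattern = list(), current = list())
  )
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Resolve a user configuration against the defaults
#'
#' @param config a nested list, a path to a JSON config file, or `NULL` for
#'   pure defaults.
#' @return the fully materialised config.
#' @export
resolve_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_config(default_config(), config)
}

require_field <- function(config, stage, field) {
  v <- config[[stage]][[field]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) {
    stop(sprintf("config error: `%s.%s` is required but not set",
                 stage, field), call. = FALSE)
  }
  v
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

update_manifest <- function(out_dir, stage, config, inputs, outputs, seed) {
  p <- manifest_path(out_dir)
  man <- if (file.exists(p)) {
    jsonlite::read_json(p, simplifyVector = TRUE)
  } else {
    list(stages = list())
  }
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  man$stages[[stage]] <- list(config = config, input_md5 = checksums,
                              outputs = outputs, seed = seed)
  jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Run one pipeline stage
#'
#' Verbs: `simulate` (generate synthetic inputs under `out_dir/sim`),
#' `calcium`, `puncta`, `phago`, `spatial`, `ephys` (each reads the inputs
#' named in `config$<stage>$input` or the simulate outputs), and `aggregate`.
#' Outputs are CSV files under `out_dir`; every run updates
#' `out_dir/manifest.json` with the resolved config block, input checksums,
#' the seed, and output row counts. Deterministic stages re-run from an
#' identical manifest byte-identically.
#'
#' @param name stage verb.
#' @param config resolved or user config (see [resolve_config()]).
#' @param out_dir output directory.
#' @param seed integer seed recorded and used for stochastic stages.
#' @return invisibly, a list of output file paths.
#' @export
run_stage <- function(name, config = NULL, out_dir = ".", seed = NULL) {
  config <- resolve_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(
    name,
    simulate = stage_simulate(config, out_dir),
    calcium = stage_calcium(config, out_dir),
    puncta = stage_puncta(config, out_dir),
    phago = stage_phago(config, out_dir),
    spatial = stage_spatial(config, out_dir),
    ephys = stage_ephys(config, out_dir),
    aggregate = stage_aggregate(config, out_dir),
    all = {
      paths <- run_stage("simulate", config, out_dir)
      for (s in c("calcium", "puncta", "phago", "spatial", "ephys")) {
        paths <- c(paths, run_stage(s, config, out_dir))
      }
      invisible(paths)
    },
    stop(sprintf("unknown stage `%s`", name))
  )
}

sim_dir <- function(out_dir) file.path(out_dir, "sim")

stage_simulate <- function(config, out_dir) {
  sd0 <- config$seed
  dir.create(sim_dir(out_dir), showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  # traces
  nt <- config$simulate$trace$n_traces
  spec_args <- config$simulate$trace
  spec_args$n_traces <- NULL
  traces <- list()
  for (k in seq_len(nt)) {
    sp <- do.call(trace_gen_spec, c(spec_args, list(seed = sd0 + k)))
    traces[[sprintf("roi%02d", k)]] <- simulate_trace(sp)$trace
  }
  p <- file.path(sim_dir(out_dir), "traces.csv")
  write_traces_csv(traces, p); paths <- c(paths, p)
  # puncta field
  psp <- do.call(puncta_gen_spec,
                 c(config$simulate$puncta, list(seed = sd0 + 1000L)))
  field <- simulate_puncta_field(psp)
  p1 <- file.path(sim_dir(out_dir), "puncta_pre.csv")
  p2 <- file.path(sim_dir(out_dir), "puncta_post.csv")
  write_image_csv(field$pre, p1); write_image_csv(field$post, p2)
  paths <- c(paths, p1, p2)
  # bead scenes
  nf <- config$simulate$scene$n_fovs
  sargs <- config$simulate$scene; sargs$n_fovs <- NULL
  for (k in seq_len(nf)) {
    ssp <- do.call(scene_gen_spec, c(sargs, list(seed = sd0 + 2000L + k)))
    write_scene(simulate_bead_scene(ssp),
                file.path(sim_dir(out_dir), sprintf("scene%02d", k)))
  }
  # point pattern
  gsp <- do.call(pattern_gen_spec,
                 c(config$simulate$pattern, list(seed = sd0 + 3000L)))
  p <- file.path(sim_dir(out_dir), "pattern.csv")
  write_pattern_csv(simulate_point_pattern(gsp), p); paths <- c(paths, p)
  # current trace
  esp <- do.call(ephys_gen_spec,
                 c(config$simulate$current, list(seed = sd0 + 4000L)))
  p <- file.path(sim_dir(out_dir), "current.csv")
  write_current_csv(simulate_current_trace(esp)$trace, p)
  paths <- c(paths, p)
  update_manifest(out_dir, "simulate", config["simulate"], character(0),
                  list(files = length(paths)), sd0)
  invisible(paths)
}

stage_calcium <- function(config, out_dir) {
  input <- config$calcium$input
  if (is.null(input)) input <- file.path(sim_dir(out_dir), "traces.csv")
  traces <- read_traces_csv(input, is_dff = TRUE)
  params <- detection_params(
    config$calcium$smoothing_frames, config$calcium$threshold_multiplier,
    config$calcium$baseline_eligibility_dff, config$calcium$min_area_dff_s,
    config$calcium$n_baseline_points, config$calcium$sd_on)
  events <- list(); summary <- list()
  for (nm in names(traces)) {
    det <- detect_transients(traces[[nm]], params = params)
    if (nrow(det$events)) {
      events[[nm]] <- cbind(roi = nm, det$events)
    }
    summary[[nm]] <- data.frame(roi = nm, n_events = nrow(det$events),
                                rate_per_300s = det$rate_per_300s,
                                rate_per_min = det$rate_per_min,
                                threshold = det$threshold)
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(roi = character(0))
  }
  sm <- do.call(rbind, summary)
  rownames(ev) <- rownames(sm) <- NULL
  p1 <- file.path(out_dir, "calcium_events.csv")
  p2 <- file.path(out_dir, "calcium_summary.csv")
  utils::write.csv(ev, p1, row.names = FALSE)
  utils::write.csv(sm, p2, row.names = FALSE)
  update_manifest(out_dir, "calcium", config["calcium"], input,
                  list(calcium_events = nrow(ev), calcium_summary = nrow(sm)),
                  config$seed)
  invisible(c(p1, p2))
}

stage_puncta <- function(config, out_dir) {
  px <- require_field(config, "puncta", "pixel_size_um")
  pre_in <- config$puncta$input_pre
  post_in <- config$puncta$input_post
  if (is.null(pre_in)) pre_in <- file.path(sim_dir(out_dir), "puncta_pre.csv")
  if (is.null(post_in)) {
    post_in <- file.path(sim_dir(out_dir), "puncta_post.csv")
  }
  pre_img <- read_image_csv(pre_in, px, "pre")
  post_img <- read_image_csv(post_in, px, "post")
  res <- puncta_pipeline(
    pre_img, post_img,
    threshold_spec(config$puncta$pre_threshold[1],
                   config$puncta$pre_threshold[2]),
    threshold_spec(config$puncta$post_threshold[1],
                   config$puncta$post_threshold[2]),
    config$puncta$rolling_ball_radius_px,
    as.integer(config$puncta$connectivity))
  tab <- rbind(cbind(channel = "pre", res$pre$table,
                     colocalized = res$pre$table$id %in%
                       res$report$synapse_pre_ids),
               cbind(channel = "post", res$post$table, colocalized = NA))
  rep <- res$report
  report_df <- data.frame(
    n_pre = rep$n_pre, n_post = rep$n_post, n_synapses = rep$n_synapses,
    pre_per_100um2 = rep$density_pre[["per_100um2"]],
    post_per_100um2 = rep$density_post[["per_100um2"]],
    synapses_per_100um2 = rep$density_synapses[["per_100um2"]],
    pre_per_mm2 = rep$density_pre[["per_mm2"]],
    post_per_mm2 = rep$density_post[["per_mm2"]],
    synapses_per_mm2 = rep$density_synapses[["per_mm2"]],
    area_fraction_pre = rep$area_fraction_pre,
    area_fraction_post = rep$area_fraction_post,
    area_fraction_coloc = rep$area_fraction_coloc,
    area_fraction_coloc_union = rep$area_fraction_coloc_union)
  p1 <- file.path(out_dir, "puncta_table.csv")
  p2 <- file.path(out_dir, "puncta_report.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  utils::write.csv(report_df, p2, row.names = FALSE)
  update_manifest(out_dir, "puncta", config["puncta"], c(pre_in, post_in),
                  list(puncta_table = nrow(tab), puncta_report = 1L),
                  config$seed)
  invisible(c(p1, p2))
}

stage_phago <- function(config, out_dir) {
  dirs <- config$phago$input_dirs
  if (is.null(dirs)) {
    dirs <- list.dirs(sim_dir(out_dir), recursive = FALSE)
    dirs <- dirs[grepl("scene", basename(dirs))]
  }
  if (!length(dirs)) stop("config error: `phago.input_dirs` is required")
  reports <- lapply(dirs, function(d) {
    scene <- read_scene(d)
    phagocytic_index(assign_beads(scene)$counts, config$phago$min_beads)
  })
  df <- do.call(rbind, lapply(seq_along(reports), function(k) {
    r <- reports[[k]]
    data.frame(fov = basename(dirs[k]), n_cells = r$n_cells,
               n_phagocytic = r$n_phagocytic,
               phagocytic_pct = r$phagocytic_pct,
               fov_has_phagocytic = r$fov_has_phagocytic)
  }))
  p1 <- file.path(out_dir, "phago_per_fov.csv")
  utils::write.csv(df, p1, row.names = FALSE)
  p2 <- file.path(out_dir, "phago_summary.csv")
  utils::write.csv(data.frame(n_fov = nrow(df),
                              fov_occurrence_pct = fov_occurrence(reports),
                              mean_phagocytic_pct = mean(df$phagocytic_pct)),
                   p2, row.names = FALSE)
  update_manifest(out_dir, "phago", config["phago"],
                  file.path(dirs, "beads.csv"),
                  list(phago_per_fov = nrow(df)), config$seed)
  invisible(c(p1, p2))
}

stage_spatial <- function(config, out_dir) {
  input <- config$spatial$input
  if (is.null(input)) input <- file.path(sim_dir(out_dir), "pattern.csv")
  pat <- read_pattern_csv(input)
  rep <- spatial_report(pat, config$spatial$metric, config$spatial$sd_type)
  p <- file.path(out_dir, "spatial_report.csv")
  utils::write.csv(rep, p, row.names = FALSE)
  update_manifest(out_dir, "spatial", config["spatial"], input,
                  list(spatial_report = nrow(rep)), config$seed)
  invisible(p)
}

stage_ephys <- function(config, out_dir) {
  input <- config$ephys$input
  if (is.null(input)) input <- file.path(sim_dir(out_dir), "current.csv")
  cf <- config$ephys
  trace <- read_current_csv(input, ttx_onset_s = cf$ttx_onset_s,
                            agonist_onset_s = cf$agonist_onset_s,
                            polarity = cf$polarity)
  ev <- detect_events(trace, cf$threshold_pA, cf$min_interval_ms,
                      cf$filter_cutoff_hz)
  p1 <- file.path(out_dir, "ephys_events.csv")
  utils::write.csv(as.data.frame(ev), p1, row.names = FALSE)
  paths <- p1
  if (!is.na(cf$ttx_onset_s)) {
    cmp <- ttx_comparison(ev, cf$ttx_onset_s,
                          duration_s = attr(ev, "duration_s"),
                          baseline_window_s = cf$baseline_window_s,
                          post_delay_s = cf$post_delay_s,
                          post_window_s = cf$post_window_s)
    p2 <- file.path(out_dir, "ephys_ttx.csv")
    utils::write.csv(data.frame(
      baseline_freq_hz = cmp$baseline_freq_hz,
      post_freq_hz = cmp$post_freq_hz,
      baseline_mean_amplitude_pA = cmp$baseline_mean_amplitude_pA,
      post_mean_amplitude_pA = cmp$post_mean_amplitude_pA), p2,
      row.names = FALSE)
    paths <- c(paths, p2)
  }
  if (!is.na(cf$agonist_onset_s)) {
    ag <- agonist_current(trace, cf$agonist_onset_s, cf$segment_s)
    p3 <- file.path(out_dir, "ephys_agonist.csv")
    utils::write.csv(data.frame(shift_pA = ag$shift_pA,
                                control_pA = ag$control_pA,
                                response_pA = ag$response_pA), p3,
                     row.names = FALSE)
    paths <- c(paths, p3)
  }
  # reversal-potential report from the built-in recipes
  p4 <- file.path(out_dir, "ephys_reversal.csv")
  utils::write.csv(data.frame(
    solution = c("excitatory internal", "inhibitory internal"),
    e_cl_mV = c(e_rev_cl(recipe_internal_excitatory(), temp_C = cf$temp_C),
                e_rev_cl(recipe_internal_inhibitory(), temp_C = cf$temp_C)),
    temp_C = cf$temp_C), p4, row.names = FALSE)
  update_manifest(out_dir, "ephys", config["ephys"], input,
                  list(ephys_events = nrow(ev)), config$seed)
  invisible(c(paths, p4))
}

stage_aggregate <- function(config, out_dir) {
  input <- config$aggregate$input
  if (is.null(input)) stop("config error: `aggregate.input` is required")
  rows <- utils::read.csv(input)
  agg <- aggregate_hierarchy(rows)
  p1 <- file.path(out_dir, "per_slice.csv")
  p2 <- file.path(out_dir, "per_animal.csv")
  utils::write.csv(agg$slice, p1, row.names = FALSE)
  utils::write.csv(agg$animal, p2, row.names = FALSE)
  update_manifest(out_dir, "aggregate", config["aggregate"], input,
                  list(per_slice = nrow(agg$slice),
                       per_animal = nrow(agg$animal)), config$seed)
  invisible(c(p1, p2))
}

#' Hierarchical averaging: images -> slices -> animals
#'
#' Unweighted means at each level; the animal is the terminal statistical
#' unit. Idempotent on already-aggregated data (one row per group) and
#' invariant to row order.
#'
#' @param rows data frame with `animal` and `slice` label columns plus
#'   numeric value columns; every row must be labelled.
#' @return list with `slice` (per-slice means) and `animal` (means of the
#'   slice means).
#' @export
aggregate_hierarchy <- function(rows) {
  need <- c("animal", "slice")
  if (!all(need %in% names(rows))) {
    stop("rows must carry `animal` and `slice` labels")
  }
  if (any(is.na(rows$animal)) || any(is.na(rows$slice))) {
    stop("unlabeled rows: `animal`/`slice` must be non-missing")
  }
  vals <- names(rows)[vapply(rows, is.numeric, logical(1))]
  vals <- setdiff(vals, need)
  if (!length(vals)) stop("no numeric value columns to aggregate")
  slice <- aggregate(rows[vals],
                     by = list(animal = rows$animal, slice = rows$slice),
                     FUN = mean)
  slice <- slice[order(slice$animal, slice$slice), , drop = FALSE]
  animal <- aggregate(slice[vals], by = list(animal = slice$animal),
                      FUN = mean)
  animal <- animal[order(animal$animal), , drop = FALSE]
  rownames(slice) <- rownames(animal) <- NULL
  list(slice = slice, animal = animal)
}
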