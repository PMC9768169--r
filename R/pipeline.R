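#' Validate a pipeline configuration
#'
#' Checks a staged-pipeline configuration (an R list, or a path to a YAML /
#' JSON file) against the schema before any stage runs.  Required fields:
#' `assay` (one of `"clusters"`, `"frap"`, `"xcorr"`, `"msd"`), `seed`
#' (integer; every stochastic stage derives its seed from it) and the
#' per-assay parameter block.  Violations raise an error naming the field.
#'
#' @param config list or file path.
#' @return The normalized configuration (invisibly classed
#'   `pipeline_config`).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_txspot("config must be a list or a file path")
  bad <- function(field, why) stop_txspot("config field '%s': %s", field, why)

  assays <- c("clusters", "frap", "xcorr", "msd")
  if (is.null(config$assay) || !config$assay %in% assays)
    bad("assay", sprintf("must be one of %s", paste(assays, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      config$seed != round(config$seed))
    bad("seed", "an integer seed is required")

  chk_pos <- function(block, field, allow_zero = FALSE) {
    v <- config[[block]][[field]]
    full <- paste(block, field, sep = ".")
    if (is.null(v) || !is.numeric(v)) bad(full, "required numeric value")
    if (allow_zero && v < 0) bad(full, "must be >= 0")
    if (!allow_zero && v <= 0) bad(full, "must be > 0")
  }
  switch(config$assay,
    clusters = {
      chk_pos("clusters", "n_scenes", allow_zero = TRUE)
      chk_pos("clusters", "distance_median_nm")
      chk_pos("clusters", "n_clusters")
      chk_pos("clusters", "psf_sigma_px")
    },
    frap = {
      chk_pos("frap", "n_curves", allow_zero = TRUE)
      chk_pos("frap", "baseline", allow_zero = TRUE)
      chk_pos("frap", "f_mobile", allow_zero = TRUE)
      chk_pos("frap", "tau")
    },
    xcorr = {
      chk_pos("xcorr", "n_cells", allow_zero = TRUE)
      chk_pos("xcorr", "separation_kb")
      chk_pos("xcorr", "elongation_rate_kb_per_min")
      chk_pos("xcorr", "duration_min")
    },
    msd = {
      chk_pos("msd", "n_tracks", allow_zero = TRUE)
      chk_pos("msd", "D_alpha", allow_zero = TRUE)
      chk_pos("msd", "alpha")
      chk_pos("msd", "dt_s")
      chk_pos("msd", "n_frames")
    })
  invisible(structure(config, class = c("pipeline_config", "list")))
}

# deterministic per-stage seed expansion from the root seed
stage_seed <- function(root_seed, stage_index) {
  (as.integer(root_seed) + 7919L * as.integer(stage_index)) %% 2147483647L
}

# small FNV-1a style fingerprint of the serialized config
config_fingerprint <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a CSV table with a provenance header
#'
#' Prepends `#`-prefixed provenance lines (package version, config
#' fingerprint, seed) so each stage output records how it was produced;
#' [read_stage_table()] skips them.
#'
#' @param df data frame.
#' @param path output path.
#' @param fingerprint config fingerprint string.
#' @param seed integer seed used by the stage.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(df, path, fingerprint = "none", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# txspot %s", as.character(packageVersion("txspot"))),
               sprintf("# config %s", fingerprint),
               sprintf("# seed %s", seed)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_table
#' @param path input path.
#' @export
read_stage_table <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Run a staged analysis pipeline
#'
#' Executes the configured assay end to end on synthetic inputs, writing
#' each stage's table under `out_dir` with a provenance header.  All
#' randomness is derived from the root `seed` via a fixed per-stage
#' expansion, so the same configuration always produces byte-identical
#' outputs.  Assays:
#'
#' * `clusters` — simulate anchor/cluster scenes, detect spots in both
#'   channels, record nearest-cluster distances (`truth.csv`,
#'   `distances.csv`).
#' * `frap` — simulate recovery curves and fit each (`frap_fits.csv`).
#' * `xcorr` — simulate telegraph-driven reporter pairs, average their
#'   cross-correlation, estimate delay and elongation rate
#'   (`ccf.csv`, `delay.csv`).
#' * `msd` — simulate locus tracks and fit the anomalous-diffusion model
#'   (`msd.csv`, `msd_fit.csv`).
#'
#' @param config a validated (or validatable) pipeline configuration.
#' @param out_dir output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(unclass(config))
  root <- config$seed
  paths <- list()
  emit <- function(df, name, seed) {
    p <- file.path(out_dir, name)
    write_stage_table(df, p, fingerprint = fp, seed = seed)
    paths[[name]] <<- p
  }

  if (config$assay == "clusters") {
    cl <- config$clusters
    s1 <- stage_seed(root, 1L)
    truth <- data.frame(); dist <- data.frame()
    if (cl$n_scenes > 0) {
      res <- lapply(seq_len(cl$n_scenes), function(i) {
        analyze_cluster_scene_once(
          state = cl$state %||% "ON",
          distance_median_nm = cl$distance_median_nm,
          n_clusters = cl$n_clusters, psf_sigma_px = cl$psf_sigma_px,
          dispersion = cl$dispersion %||% 0.5,
          seed = stage_seed(s1, i))
      })
      truth <- do.call(rbind, lapply(res, `[[`, "truth"))
      dist <- do.call(rbind, lapply(res, `[[`, "record"))
    } else {
      truth <- data.frame(scene = integer(), true_nm = numeric())
      dist <- data.frame(scene = integer(), distance_nm = numeric())
    }
    if (cl$n_scenes > 0) { truth$scene <- seq_len(nrow(truth))
                           dist$scene <- seq_len(nrow(dist)) }
    emit(truth, "truth.csv", s1)
    emit(dist, "distances.csv", s1)
  } else if (config$assay == "frap") {
    fr <- config$frap
    s1 <- stage_seed(root, 1L)
    rows <- lapply(seq_len(fr$n_curves %||% 0), function(i) {
      cv <- simulate_frap_curve(frap_sim_params(
        fr$baseline, fr$f_mobile, fr$tau, dt_s = fr$dt_s %||% 4,
        n_points = fr$n_points %||% 25,
        noise_sigma = fr$noise_sigma %||% 0.05,
        seed = stage_seed(s1, i)))
      ft <- fit_frap(cv, baseline = fr$fit_baseline %||% "free")
      data.frame(curve = i, baseline = ft$baseline, f_mobile = ft$f_mobile,
                 tau = ft$tau, S = ft$S, converged = ft$converged)
    })
    fits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(curve = integer(), baseline = numeric(),
                 f_mobile = numeric(), tau = numeric(), S = numeric(),
                 converged = logical())
    emit(fits, "frap_fits.csv", s1)
  } else if (config$assay == "xcorr") {
    xc <- config$xcorr
    s1 <- stage_seed(root, 1L)
    n_cells <- xc$n_cells %||% 0
    pairs <- lapply(seq_len(n_cells), function(i) {
      simulate_reporter_cell(xc, seed = stage_seed(s1, i))
    })
    if (n_cells > 0) {
      cc <- ccf_average(pairs, max_lag = xc$max_lag %||% 20L)
      dr <- delay_and_rate(cc, xc$separation_kb)
      emit(cc$table, "ccf.csv", s1)
      emit(data.frame(delay_min = dr$delay_min,
                      rate_kb_per_min = dr$rate_kb_per_min,
                      n_cells = cc$n_cells), "delay.csv", s1)
    } else {
      emit(data.frame(lag_min = numeric(), mean_r = numeric(),
                      ci_lo = numeric(), ci_hi = numeric()), "ccf.csv", s1)
      emit(data.frame(delay_min = numeric(), rate_kb_per_min = numeric(),
                      n_cells = integer()), "delay.csv", s1)
    }
  } else if (config$assay == "msd") {
    ms <- config$msd
    s1 <- stage_seed(root, 1L)
    n_tracks <- ms$n_tracks %||% 0
    if (n_tracks > 0) {
      trk <- simulate_locus_track(ms$D_alpha, ms$alpha, ms$n_frames,
                                  ms$dt_s,
                                  localization_sigma_nm = ms$localization_sigma_nm %||% 0,
                                  n_tracks = n_tracks, seed = s1)
      ft <- msd_fit(trk, max_lag_steps = ms$max_lag_steps %||% 66L)
      emit(ft$msd, "msd.csv", s1)
      emit(data.frame(D_alpha = ft$D_alpha, alpha = ft$alpha,
                      residual = ft$residual, n_tracks = n_tracks),
           "msd_fit.csv", s1)
    } else {
      emit(data.frame(lag_s = numeric(), msd_um2 = numeric(),
                      n_tracks = integer()), "msd.csv", s1)
      emit(data.frame(D_alpha = numeric(), alpha = numeric(),
                      residual = numeric(), n_tracks = integer()),
           "msd_fit.csv", s1)
    }
  }
  invisible(paths)
}

#' Run one anchor/cluster scene through the detection pipeline
#'
#' Simulates a two-channel scene with [simulate_cluster_scene()], renders
#' both channels, detects the anchor and the clusters with
#' [detect_and_refine()], and records the nearest-cluster distance —
#' the single-scene unit of the cluster-distance analysis.
#'
#' @param state `"ON"` or `"OFF"` (label carried into the records).
#' @param distance_median_nm ground-truth nearest-distance median, nm.
#' @param n_clusters clusters in the factor channel.
#' @param psf_sigma_px PSF sigma of rendered spots, px.
#' @param dispersion log-scale SD of the nearest-distance law.
#' @param seed integer seed for the scene and its rendering.
#' @return List with `truth` (one-row data frame: `true_nm`, `state`) and
#'   `record` (a [nearest_distance()] row).
#' @export
analyze_cluster_scene_once <- function(state, distance_median_nm,
                                       n_clusters, psf_sigma_px,
                                       dispersion, seed) {
  sc <- simulate_cluster_scene(state = state,
                               distance_median_nm = distance_median_nm,
                               n_clusters = n_clusters,
                               dispersion = dispersion,
                               psf_sigma_px = psf_sigma_px, seed = seed)
  ch1 <- render_scene(sc$scene, channel = 1L)
  ch2 <- render_scene(sc$scene, channel = 2L)
  anchor_tab <- detect_and_refine(ch1, max_candidates = 1L)
  thr <- median(ch2$pixels) + 3 * mad(ch2$pixels)
  cl_tab <- detect_and_refine(ch2, max_candidates = n_clusters,
                              threshold = thr)
  rec <- if (nrow(anchor_tab) == 0)
    data.frame(distance_nm = NA_real_, nearest_y_px = NA_real_,
               nearest_x_px = NA_real_, nearest_intensity = NA_real_,
               state = state, reason = "anchor not detected")
  else nearest_distance(anchor_tab[1L, ], cl_tab,
                        pixel_size_nm = sc$scene$pixel_size_nm,
                        state = state)
  list(truth = data.frame(true_nm = sc$truth$nearest_distance_nm,
                          state = state),
       record = rec)
}

#' Simulate one cell's dual-reporter trace from telegraph bursting
#'
#' Draws a telegraph promoter trajectory and converts its initiation
#' events into a paired TSS-proximal/3'UTR reporter trace.
#'
#' @param xc list of parameters: `separation_kb`,
#'   `elongation_rate_kb_per_min`, `duration_min`, and optionally `k_on`,
#'   `k_off`, `k_init` (per min; defaults 0.1, 0.5, 2), `dwell_min`
#'   (default 3) and `dt_min` (default 1).
#' @param seed integer seed.
#' @return A `reporter_pair` object (see [simulate_reporter_pair()]).
#' @export
simulate_reporter_cell <- function(xc, seed) {
  tp <- telegraph_params(k_on = xc$k_on %||% 0.1,
                         k_off = xc$k_off %||% 0.5,
                         k_init = xc$k_init %||% 2,
                         duration = xc$duration_min,
                         dt = xc$dt_min %||% 1, seed = seed)
  tr <- simulate_telegraph(tp)
  simulate_reporter_pair(tr$events, xc$separation_kb,
                         xc$elongation_rate_kb_per_min,
                         dwell_min = xc$dwell_min %||% 3,
                         dt = xc$dt_min %||% 1,
                         duration = xc$duration_min,
                         seed = stage_seed(seed, 2L))
}
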