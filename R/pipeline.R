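# End-to-end orchestration: a single reproducible entry point that runs the
# synthetic pipeline, compares every recovered quantity with its ground
# truth, and writes a deterministic JSON report.

#' Pipeline run configuration
#'
#' All ledgered defaults live here so any of them can be overridden without
#' code changes. Stage blocks are passed to the corresponding generators and
#' analysis settings.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param stages stages to run, a subset of
#'   `c("motion", "fluor", "classify", "ishreg", "quantfluor", "reflex")`.
#' @param movie named list of [synth_movie_spec()] overrides.
#' @param ish named list of [generate_ish_pair()] overrides.
#' @param emg named list of [generate_emg()] overrides.
#' @param jaw named list of [generate_jaw_track()] overrides.
#' @param immune named list of [generate_immune_image()] overrides.
#' @param write_artifacts write TIFF/CSV intermediates (default TRUE).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("motion", "fluor", "classify",
                                       "ishreg", "quantfluor", "reflex"),
                            movie = list(), ish = list(), emg = list(),
                            jaw = list(), immune = list(),
                            write_artifacts = TRUE) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("pipeline_config: `out_dir` is required")
  known <- c("motion", "fluor", "classify", "ishreg", "quantfluor", "reflex")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (blk in list(movie, ish, emg, jaw, immune))
    if (!is.list(blk)) stop("stage config blocks must be named lists")
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 movie = movie, ish = ish, emg = emg, jaw = jaw,
                 immune = immune, write_artifacts = isTRUE(write_artifacts)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the configured stages in dependency order (movie generation ->
#' motion correction -> trace extraction -> classification; ISH, immune and
#' reflex branches are independent), writes intermediates and a JSON report
#' with per-stage recovered-vs-true metrics. Identical config and seed give
#' identical numeric report fields. A stage failure halts its dependents and
#' is recorded in the report; independent branches still run.
#'
#' @param cfg a [pipeline_config()].
#' @return the report (list), invisibly; also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "dentsense",
                 version = as.character(utils::packageVersion("dentsense")),
                 seed = cfg$seed, stages = list(), warnings = character(0))
  failed <- character(0)
  run_stage <- function(name, deps, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    if (any(deps %in% failed)) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("dependency failed:",
                                                    paste(intersect(deps, failed),
                                                          collapse = ",")))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        report$warnings <<- c(report$warnings,
                              sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  spec <- do.call(synth_movie_spec,
                  modifyList(list(motion_model = "translation",
                                  seed = derive_seed(cfg$seed, 1L)),
                             cfg$movie))
  shared <- new.env(parent = emptyenv())

  run_stage("motion", character(0), function() {
    stim <- fit_electrical_train(spec$n_frames / spec$frame_rate_hz)
    gen <- generate_movie(spec, stim)
    reg <- register_stack(gen$movie)
    shared$gen <- gen
    shared$reg <- reg
    true_shift <- t(vapply(gen$truth$motion, function(m) m$offset, numeric(2)))
    est_shift <- -t(vapply(reg$transforms, function(m) m$offset, numeric(2)))
    # compare up to the global reference offset, which registration to an
    # internal reference cannot determine
    resid <- sweep(true_shift - est_shift, 2L,
                   colMeans(true_shift - est_shift))
    err <- sqrt(mean(rowSums(resid^2)))
    if (cfg$write_artifacts) {
      write_tiff(reg$movie$frames, file.path(cfg$out_dir, "registered.tif"))
      write_transforms_json(reg$transforms,
                            file.path(cfg$out_dir, "transforms.json"))
    }
    list(frames = n_frames(gen$movie), shift_rms_error_px = err,
         mean_ms_pre = mean(reg$metrics$pre),
         mean_ms_post = mean(reg$metrics$post))
  })

  run_stage("fluor", "motion", function() {
    gen <- shared$gen
    # place the scene-coordinate ground-truth ROIs on the registered grid:
    # registration to an internal reference leaves one global offset, known
    # here from truth (in real use ROIs are drawn on the registered movie)
    tf <- shared$reg$transforms
    g <- rowMeans(vapply(seq_along(tf), function(t)
      tf[[t]]$offset + gen$truth$motion[[t]]$offset, numeric(2)))
    rois <- gen$truth$rois
    if (any(abs(g) >= 0.5)) {
      sh <- round(g)
      rois$rois <- lapply(rois$rois, function(r) {
        m <- matrix(FALSE, nrow(r$mask), ncol(r$mask))
        h <- nrow(m); w <- ncol(m)
        src_r <- (1 + max(0, sh[1])):(h + min(0, sh[1]))
        src_c <- (1 + max(0, sh[2])):(w + min(0, sh[2]))
        m[src_r - sh[1], src_c - sh[2]] <- r$mask[src_r, src_c]
        if (any(m)) r$mask <- m # keep original if shifted off-grid
        r
      })
    }
    # cells whose ROI can touch the registered stack's out-of-view band are
    # excluded from recovery metrics, as an analyst would exclude border
    # ROIs on real data
    est <- vapply(tf, function(t) t$offset, numeric(2))
    d <- dim(shared$reg$movie$frames)
    lo <- pmax(0, -apply(est, 1L, min)) + 2
    hi <- c(d[1L], d[2L]) - 1 - (pmax(0, apply(est, 1L, max)) + 2)
    interior <- vapply(rois$rois, function(r) {
      px <- which(r$mask, arr.ind = TRUE) - 1L
      all(px[, 1L] >= lo[1L] & px[, 1L] <= hi[1L] &
            px[, 2L] >= lo[2L] & px[, 2L] <= hi[2L])
    }, logical(1))
    shared$rois_reg <- rois
    shared$interior <- interior
    traces <- extract_traces(shared$reg$movie, rois)
    shared$traces <- traces
    fr <- gen$movie$frame_rate_hz
    stim_f <- round(range(gen$truth$stim$pulse_onsets_s) * fr)
    resp <- intersect(gen$truth$responders, which(interior))
    rec <- vapply(resp, function(i) {
      tr <- traces[i, ]
      base <- mean(tr[1:stim_f[1L]])
      max(tr[(stim_f[1L] + 1L):min(length(tr), stim_f[2L] + 10L)]) - base
    }, numeric(1))
    frac_ok <- mean(abs(rec - gen$truth$transient_amplitudes[resp]) /
                      gen$truth$transient_amplitudes[resp] <= 0.1)
    aucs <- apply(traces, 1L, compute_auc,
                  cfg = auc_config(normalization = "none",
                                   end_frame = min(120L, ncol(traces) - 1L)))
    if (cfg$write_artifacts)
      write_traces_csv(traces, file.path(cfg$out_dir, "traces.csv"))
    list(n_cells = nrow(traces),
         n_border_excluded = sum(!interior),
         amplitude_within_10pct = frac_ok,
         mean_auc_responders = mean(aucs[resp]),
         mean_auc_nonresponders = if (length(aucs) > length(resp))
           mean(aucs[setdiff(seq_along(aucs), resp)]) else NA_real_)
  })

  run_stage("classify", c("motion", "fluor"), function() {
    gen <- shared$gen
    traces <- shared$traces
    fr <- gen$movie$frame_rate_hz
    rounds <- sort(unique(gen$truth$stim$round_id))
    rr <- sapply(rounds, function(r)
      apply(traces, 1L, detect_round_response,
            stim = stim_round(gen$truth$stim, r), frame_rate_hz = fr))
    tab <- responder_table(attr(traces, "cell_ids"), rr)
    truth_lab <- seq_len(nrow(traces)) %in% gen$truth$responders
    keep <- shared$interior
    sens <- if (any(truth_lab & keep))
      mean(tab$is_intradental[truth_lab & keep]) else NA_real_
    spec <- if (any(!truth_lab & keep))
      mean(!tab$is_intradental[!truth_lab & keep]) else NA_real_
    if (cfg$write_artifacts)
      write.csv(tab, file.path(cfg$out_dir, "responders.csv"),
                row.names = FALSE)
    list(n_intradental = sum(tab$is_intradental), sensitivity = sens,
         specificity = spec)
  })

  run_stage("ishreg", character(0), function() {
    pair <- do.call(generate_ish_pair,
                    modifyList(list(seed = derive_seed(cfg$seed, 2L)),
                               cfg$ish))
    pts <- control_points(pair$truth$guidepost_fixed,
                          pair$truth$guidepost_moving)
    poly <- fit_polynomial_warp(pts)
    model <- demons_refine(pair$fixed, pair$moving[, , 1L], poly)
    probes <- pair$truth$cell_centers
    est <- warp_points(model, probes)
    tru <- warp_points(pair$truth$warp, probes)
    landmark_rms <- sqrt(mean(rowSums((est - tru)^2)))
    aligned <- apply_warp_stack(pair$moving, model)
    calls <- score_expression(aligned, pair$truth$rois)
    agree <- mean(calls == pair$truth$positive)
    if (cfg$write_artifacts) {
      write_tiff(aligned, file.path(cfg$out_dir, "ish_aligned.tif"))
      write_tiff(list(model$displacement[, , 1L], model$displacement[, , 2L]),
                 file.path(cfg$out_dir, "warp_displacement.tif"),
                 format = "float32")
    }
    m <- attr(model, "metrics")
    list(poly_rms_residual_px = poly$rms_residual_px,
         landmark_rms_px = landmark_rms,
         positivity_agreement = agree,
         metric_by_level = m$mean_squares)
  })

  run_stage("quantfluor", character(0), function() {
    img <- do.call(generate_immune_image,
                   modifyList(list(seed = derive_seed(cfg$seed, 3L)),
                              cfg$immune))
    q <- quantify_immune(img$nuclear, img$signal)
    if (cfg$write_artifacts)
      write_tiff(list(img$nuclear, img$signal),
                 file.path(cfg$out_dir, "immune.tif"))
    list(roi_area_px = q$roi_area_px, mean_brightness = q$mean_brightness,
         mask_iou = sum(q$mask & img$truth$mask) /
           sum(q$mask | img$truth$mask))
  })

  run_stage("reflex", character(0), function() {
    emg <- do.call(generate_emg,
                   modifyList(list(seed = derive_seed(cfg$seed, 4L)),
                              cfg$emg))
    met <- reflex_metrics(emg$trace, baseline_window_s = c(0, 0.4))
    jaw <- do.call(generate_jaw_track,
                   modifyList(list(seed = derive_seed(cfg$seed, 5L)),
                              cfg$jaw))
    defl <- jaw_deflection(jaw$track)
    if (cfg$write_artifacts) {
      write.csv(data.frame(time_s = (seq_along(emg$trace$samples) - 1L) /
                             emg$trace$sample_rate_hz,
                           mv = emg$trace$samples),
                file.path(cfg$out_dir, "emg.csv"), row.names = FALSE)
      write.csv(defl$per_pulse, file.path(cfg$out_dir, "jaw_deflection.csv"),
                row.names = FALSE)
    }
    list(latency_s = met$latency_s[1L],
         latency_error_samples =
           abs(met$latency_s[1L] - emg$truth$latency_s) *
           emg$trace$sample_rate_hz,
         peak_to_peak_mv = met$peak_to_peak_mv[1L],
         mean_deflection_um = mean(defl$per_pulse$deflection_um, na.rm = TRUE),
         true_deflection_um = jaw$truth$deflection_um)
  })

  report$failed_stages <- failed
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write the demo fixture set
#'
#' Emits one synthetic instance of every input the pipeline consumes (movie,
#' ISH pair, EMG trace, jaw track, immune image) with ground-truth JSONs and
#' a checksum manifest. Used by the test suite and the CLI demo.
#'
#' @param out_dir destination directory.
#' @param seed master seed; same seed gives identical checksums.
#' @param movie_dim movie (H, W, T) (default `c(256, 256, 300)`).
#' @return the manifest (data.frame `file`, `md5`), invisibly; also written
#'   to `<out_dir>/manifest.json`.
#' @export
make_demo_fixtures <- function(out_dir, seed = 1L,
                               movie_dim = c(256L, 256L, 300L)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  stim <- fit_electrical_train(movie_dim[3L] / 5)
  # cell count scaled with field area (capped at the 12-22 per-trial range)
  n_cells <- max(4L, min(18L, round(18 * prod(movie_dim[1:2]) / 128^2)))
  spec <- synth_movie_spec(height_px = movie_dim[1L], width_px = movie_dim[2L],
                           n_frames = movie_dim[3L], n_cells = n_cells,
                           motion_model = "translation",
                           seed = derive_seed(seed, 1L))
  gen <- generate_movie(spec, stim)
  add(write_tiff(gen$movie$frames, file.path(out_dir, "movie.tif")))
  add(write_roi_json(gen$truth$rois, file.path(out_dir, "rois.json")))
  jsonlite::write_json(
    list(modality = stim$modality, pulse_onsets_s = stim$pulse_onsets_s,
         pulse_duration_s = stim$pulse_duration_s, round_id = stim$round_id),
    file.path(out_dir, "stim.json"), auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "stim.json"))
  jsonlite::write_json(
    list(cell_centers = gen$truth$cell_centers,
         responders = gen$truth$responders,
         transient_amplitudes = gen$truth$transient_amplitudes,
         diameters_um = gen$truth$diameters_um),
    file.path(out_dir, "movie_truth.json"), digits = NA)
  add(file.path(out_dir, "movie_truth.json"))

  pair <- generate_ish_pair(seed = derive_seed(seed, 2L))
  add(write_tiff(pair$fixed, file.path(out_dir, "ish_fixed.tif")))
  add(write_tiff(pair$moving, file.path(out_dir, "ish_moving.tif")))
  jsonlite::write_json(
    list(guidepost_fixed = pair$truth$guidepost_fixed,
         guidepost_moving = pair$truth$guidepost_moving,
         positive = pair$truth$positive),
    file.path(out_dir, "ish_truth.json"), digits = NA)
  add(file.path(out_dir, "ish_truth.json"))

  emg <- generate_emg(stim_onsets_s = c(0.5, 1.5, 2.5),
                      seed = derive_seed(seed, 3L))
  write.csv(data.frame(time_s = (seq_along(emg$trace$samples) - 1L) /
                         emg$trace$sample_rate_hz,
                       mv = emg$trace$samples),
            file.path(out_dir, "emg.csv"), row.names = FALSE)
  add(file.path(out_dir, "emg.csv"))
  jsonlite::write_json(emg$truth, file.path(out_dir, "emg_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "emg_truth.json"))

  jaw <- generate_jaw_track(seed = derive_seed(seed, 4L))
  write.csv(jaw$track$frames, file.path(out_dir, "jaw_track.csv"),
            row.names = FALSE)
  add(file.path(out_dir, "jaw_track.csv"))
  jsonlite::write_json(c(jaw$truth,
                         list(pulse_onsets_s = jaw$track$pulse_onsets_s,
                              trigger_rate_hz = jaw$track$trigger_rate_hz)),
                       file.path(out_dir, "jaw_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "jaw_truth.json"))

  immune <- generate_immune_image(seed = derive_seed(seed, 5L))
  add(write_tiff(list(immune$nuclear, immune$signal),
                 file.path(out_dir, "immune.tif")))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
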