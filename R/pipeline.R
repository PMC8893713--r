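#' Pipeline configuration
#'
#' Collects every analysis parameter with its study default so a whole run is
#' reproducible from one object. All stochastic steps derive their streams
#' from `seed`.
#'
#' @param n_bins Spatial bins for maps (80 bins of 2.25 cm on a 180-cm track).
#' @param kernel_sigma_bins Map smoothing kernel SD (bins).
#' @param n_s Stimulus bins for mutual information.
#' @param n_r_astro,n_r_neuron Response bins per ROI kind.
#' @param speed_threshold,merge_gap_s Running-trial segmentation parameters.
#' @param mi_n_perm Permutations for MI significance.
#' @param decode_granularities Decoding granularities G.
#' @param decode_n_chance,decode_n_shuffle Null repetition counts (full-study
#'   defaults; scale down for desk-scale runs).
#' @param corridor_length_cm,frame_rate_hz Session geometry/sampling.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_bins = 80, kernel_sigma_bins = 3, n_s = 12,
                            n_r_astro = 4, n_r_neuron = 2,
                            speed_threshold = 1, merge_gap_s = 1,
                            mi_n_perm = 1e4,
                            decode_granularities = c(4, 8, 12, 16, 20, 24),
                            decode_n_chance = 1e3, decode_n_shuffle = 500,
                            corridor_length_cm = 180, frame_rate_hz = 3,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

fmt17 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else x
}

write_table17 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write a session container
#'
#' Serializes a session (traces, trajectory, trial table, ground truth,
#' metadata) as a directory of plain CSV tables plus a YAML metadata file.
#' Numeric values are written with 17 significant digits so a write/read
#' round trip is exact.
#'
#' @param session A `synth_session`, or a list with elements `dff` (frames x
#'   ROI matrix), `trajectory`, optionally `raw` and `tuning`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(container_version = 1L,
               package = "astroplace",
               frame_rate_hz = session$trajectory$frame_rate_hz,
               n_frames = nrow(session$trajectory$frames),
               n_rois = if (!is.null(session$dff)) ncol(session$dff) else 0L)
  if (!is.null(session$config))
    meta$config <- unclass(session$config)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  write_table17(session$trajectory$frames, file.path(path, "trajectory.csv"))
  write_table17(session$trajectory$trials, file.path(path, "trials.csv"))
  if (!is.null(session$dff))
    write_table17(as.data.frame(session$dff), file.path(path, "dff.csv"))
  if (!is.null(session$raw))
    write_table17(as.data.frame(session$raw), file.path(path, "raw.csv"))
  if (!is.null(session$tuning))
    write_table17(session$tuning, file.path(path, "ground_truth.csv"))
  invisible(path)
}

#' Read a session container
#'
#' Inverse of [write_session()]. Unknown extra files are ignored with a
#' warning; a missing required table raises a schema error naming it.
#'
#' @param path Container directory.
#' @return A list with `trajectory`, `dff`, `raw`, `tuning`, `meta`.
#' @export
read_session <- function(path) {
  need <- c("meta.yaml", "trajectory.csv", "trials.csv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("container schema error: missing ", f, call. = FALSE)
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  if (!identical(as.integer(meta$container_version), 1L))
    warning("container version ", meta$container_version,
            " differs from supported version 1")
  known <- c(need, "dff.csv", "raw.csv", "ground_truth.csv")
  extra <- setdiff(list.files(path), known)
  if (length(extra))
    warning("ignoring unknown container entries: ",
            paste(extra, collapse = ", "))
  frames <- utils::read.csv(file.path(path, "trajectory.csv"))
  if (nrow(frames)) frames$in_trial <- as.logical(frames$in_trial)
  trajectory <- structure(list(
    frames = frames,
    trials = utils::read.csv(file.path(path, "trials.csv")),
    frame_rate_hz = meta$frame_rate_hz), class = "trajectory")
  read_mat <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.csv(p, check.names = FALSE))
  }
  tuning <- if (file.exists(file.path(path, "ground_truth.csv")))
    utils::read.csv(file.path(path, "ground_truth.csv")) else NULL
  list(trajectory = trajectory, dff = read_mat("dff.csv"),
       raw = read_mat("raw.csv"), tuning = tuning, meta = meta)
}

#' Run the full analysis pipeline on a session
#'
#' Executes event detection, running-trial segmentation, response-field
#' fitting with reliability/stability annotation, single-ROI mutual
#' information with permutation significance, and (optionally) population
#' decoding, on dF/F0 traces. Stage outputs are returned as tables; a failed
#' fit for one ROI is recorded in its row and does not abort the stage.
#'
#' @param session A list with `dff` (frames x ROI dF/F0 matrix), `trajectory`
#'   and optionally `tuning` (for ROI kinds), as produced by
#'   [simulate_session()] or [read_session()].
#' @param config A [pipeline_config()].
#' @param decode If `TRUE`, run SVM decoding at `config$decode_granularities`
#'   (null distributions are not run here; call [chance_null()] /
#'   [trial_shuffle_null()] explicitly).
#' @param ... Passed to [decode_cv()].
#' @return List of class `pipeline_result`: `trials`, `events` (table),
#'   `fields` (per-ROI data.frame), `info` (per-ROI data.frame), `decoding`
#'   (per-G list or `NULL`), `config`.
#' @export
run_pipeline <- function(session, config = pipeline_config(), decode = FALSE,
                         ...) {
  if (is.null(session$dff)) stop("session lacks dff traces", call. = FALSE)
  if (is.null(session$trajectory))
    stop("container schema error: missing trajectory", call. = FALSE)
  dff <- as.matrix(session$dff)
  traj <- session$trajectory
  kinds <- if (!is.null(session$tuning)) session$tuning$kind
           else rep("astro", ncol(dff))
  roi_ids <- colnames(dff) %||% paste0("roi", sprintf("%03d",
                                                      seq_len(ncol(dff))))

  trials <- find_running_trials(traj, config$speed_threshold,
                                config$merge_gap_s)
  if (!nrow(trials)) stop("no running trials in session", call. = FALSE)

  evs <- lapply(seq_len(ncol(dff)), function(j)
    detect_transients(dff[, j], kinds[j], config$frame_rate_hz))
  names(evs) <- roi_ids
  ev_mat <- vapply(evs, `[[`, numeric(nrow(dff)), "values")

  odd <- trials[seq(1, nrow(trials), by = 2), , drop = FALSE]
  even <- if (nrow(trials) > 1)
    trials[seq(2, nrow(trials), by = 2), , drop = FALSE] else NULL
  h1 <- trials[seq_len(floor(nrow(trials) / 2)), , drop = FALSE]
  h2 <- trials[(floor(nrow(trials) / 2) + 1):nrow(trials), , drop = FALSE]

  fit_on <- function(values, tr) {
    if (is.null(tr) || !nrow(tr)) return(NULL)
    maps <- compute_maps(values, traj, tr, config$n_bins,
                         config$corridor_length_cm, config$kernel_sigma_bins)
    fit_response_field(response_profile(maps))
  }
  idx_run <- trial_frames(trials)
  pos_run <- traj$frames$position[idx_run]
  disc <- discretize_session(pos_run, ev_mat[idx_run, , drop = FALSE], kinds,
                             config$n_s, config$n_r_astro, config$n_r_neuron)

  fields <- list()
  info <- list()
  for (j in seq_len(ncol(dff))) {
    f_all <- tryCatch(fit_on(ev_mat[, j], trials), error = function(e) NULL)
    f_odd <- tryCatch(fit_on(ev_mat[, j], odd), error = function(e) NULL)
    f_even <- tryCatch(fit_on(ev_mat[, j], even), error = function(e) NULL)
    f_h1 <- tryCatch(fit_on(ev_mat[, j], h1), error = function(e) NULL)
    f_h2 <- tryCatch(fit_on(ev_mat[, j], h2), error = function(e) NULL)
    rel <- tryCatch(compute_reliability(f_odd, f_even),
                    error = function(e) NA_real_)
    stab <- if (!is.null(f_h1) && !is.null(f_h2))
      classify_stability(f_h1, f_h2) else NA
    sp <- tryCatch(as.numeric(spatial_precision(ev_mat[, j], traj, trials,
                                                corridor_length_cm =
                                                  config$corridor_length_cm)),
                   error = function(e) NA_real_)
    sig <- permutation_significance(disc$s, disc$r[, j],
                                    n_perm = config$mi_n_perm,
                                    seed = derive_seed(config$seed, j))
    mi_c <- bias_corrected_mi(disc$s, disc$r[, j], method = "bootstrap",
                              n_perm = min(config$mi_n_perm, 1000),
                              seed = derive_seed(config$seed, j))
    ok <- !is.null(f_all) && f_all$status == "ok"
    fields[[j]] <- data.frame(
      roi_id = roi_ids[j], kind = kinds[j],
      center = if (ok) f_all$center else NA_real_,
      sigma = if (ok) f_all$sigma else NA_real_,
      width = if (ok) f_all$width else NA_real_,
      amplitude = if (ok) f_all$amplitude else NA_real_,
      reliability = rel, stable = stab, spatial_precision = sp,
      n_events = evs[[j]]$n_pos)
    info[[j]] <- data.frame(
      roi_id = roi_ids[j], n_s = config$n_s,
      n_r = if (grepl("^neuron", kinds[j])) config$n_r_neuron
            else config$n_r_astro,
      mi_plugin = sig$mi, mi_corrected = mi_c$mi_corrected,
      method = "bootstrap", p_value = sig$p_value,
      significant = sig$significant,
      reliable_spatial = isTRUE(rel > 0) && sig$significant)
  }
  fields <- do.call(rbind, fields)
  info <- do.call(rbind, info)

  decoding <- NULL
  if (decode) {
    decoding <- lapply(config$decode_granularities, function(G) {
      ds <- tryCatch(build_population_dataset(ev_mat, traj, trials, G,
                                              kinds = kinds,
                                              corridor_length_cm =
                                                config$corridor_length_cm),
                     error = function(e) NULL)
      if (is.null(ds)) return(NULL)
      decode_cv(ds, seed = derive_seed(config$seed, 600L + G), ...)
    })
    names(decoding) <- paste0("G", config$decode_granularities)
  }

  structure(list(trials = trials, events = event_table(evs),
                 event_traces = ev_mat, fields = fields, info = info,
                 decoding = decoding, config = config),
            class = "pipeline_result")
}
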