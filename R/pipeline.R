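#' Configuration for the end-to-end demonstration pipeline
#'
#' Bundles every stage's options for [run_pipeline()]: a reduced study
#' (participants, scans, both modalities) simulated voxel-by-voxel and
#' analysed back to agreement statistics.
#'
#' @param n_participants Number of simulated participants.  Default 2.
#' @param seed Master seed; every random stage derives from it.
#' @param pet_noise_scale,asl_noise_sd Imaging noise levels (0 = noise
#'   free).
#' @param psf_fwhm PET point-spread FWHM, mm.
#' @param use_idif Extract the PET input function from the image by
#'   clustering (`TRUE`, default) or use the phantom's known arterial
#'   curve.
#' @param truth_sds SDs (mL/min/100 mL) of the participant, kidney, day
#'   and scan components of the simulated true perfusion.
#' @param grand_mean True grand-mean perfusion, mL/min/100 mL.
#' @param asl Quantification constants, an [asl_params()].
#' @param fit A [fit_config()].
#' @param n_pairs ASL control/label repetitions.
#' @param out_dir Optional output directory; when given, all artifacts and
#'   a provenance record are written there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 2, seed = 1,
                            pet_noise_scale = 0, asl_noise_sd = 0,
                            psf_fwhm = 0, use_idif = TRUE,
                            truth_sds = c(participant = 40, kidney = 25,
                                          day = 8, scan = 15),
                            grand_mean = 290,
                            asl = asl_params(), fit = fit_config(),
                            n_pairs = 20, out_dir = NULL) {
  structure(list(n_participants = n_participants, seed = seed,
                 pet_noise_scale = pet_noise_scale,
                 asl_noise_sd = asl_noise_sd, psf_fwhm = psf_fwhm,
                 use_idif = use_idif, truth_sds = truth_sds,
                 grand_mean = grand_mean, asl = asl, fit = fit,
                 n_pairs = n_pairs, out_dir = out_dir),
            class = "pipeline_config")
}

# True single-kidney perfusion values for every (participant, kidney, scan).
.pipeline_truths <- function(config) {
  set.seed(config$seed)
  s <- config$truth_sds
  grid <- expand.grid(participant = seq_len(config$n_participants),
                      kidney = c("left", "right"), scan = 1:3,
                      stringsAsFactors = FALSE)
  grid$day <- ifelse(grid$scan == 3, 2L, 1L)
  p_eff <- stats::rnorm(config$n_participants, 0, s["participant"])
  k_key <- unique(grid[c("participant", "kidney")])
  k_eff <- stats::setNames(stats::rnorm(nrow(k_key), 0, s["kidney"]),
                           paste(k_key$participant, k_key$kidney))
  d_key <- unique(grid[c("participant", "kidney", "day")])
  d_eff <- stats::setNames(stats::rnorm(nrow(d_key), 0, s["day"]),
                           paste(d_key$participant, d_key$kidney, d_key$day))
  grid$truth <- config$grand_mean + p_eff[grid$participant] +
    k_eff[paste(grid$participant, grid$kidney)] +
    d_eff[paste(grid$participant, grid$kidney, grid$day)] +
    stats::rnorm(nrow(grid), 0, s["scan"])
  grid$truth <- pmax(grid$truth, 50)
  grid
}

# Small ASL geometry: two elliptical kidney masks on a thin slab.
.asl_geometry <- function(shape = c(24, 24, 3)) {
  mk <- function(center) {
    i <- slice.index(array(0, shape), 1L)
    j <- slice.index(array(0, shape), 2L)
    ((i - center[1]) / 5)^2 + ((j - center[2]) / 7)^2 <= 1
  }
  list(shape = shape, left = mk(c(7, 12)), right = mk(c(18, 12)))
}

#' Run the full simulate-measure-analyse pipeline
#'
#' For every participant and scan, a dynamic PET phantom and an ASL
#' control/label series are generated from a shared true perfusion value
#' per kidney; perfusion is then measured back through the package's own
#' analysis chain (clustered input function, 1TCM ROI fit; pair averaging,
#' FAIR quantification, thresholded ROI mean), the measurements are
#' assembled into a long-format agreement table, and regression,
#' Bland-Altman and the REML variance-components statistics are computed.
#' Reruns with the same configuration and seed are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return List: `table` (measured agreement table with truth column),
#'   `truths`, `mixed_fit` (a `vc_fit`, or `NULL` when fewer than 2
#'   participants), `comparisons` (derived agreement statistics),
#'   `regression`, `bland_altman`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truths <- .pipeline_truths(config)
  input <- make_aif(peak_time = 30, peak_amplitude = 40, alpha = 3,
                    arrival_time = 10, recirc_fraction = 0.1)
  schedule <- default_frame_schedule()
  geom <- .asl_geometry()
  p <- config$fit$partition_coefficient

  rows <- list()
  for (pid in seq_len(config$n_participants)) {
    for (sc in 1:3) {
      tl <- truths$truth[truths$participant == pid & truths$scan == sc &
                           truths$kidney == "left"]
      tr <- truths$truth[truths$participant == pid & truths$scan == sc &
                           truths$kidney == "right"]
      scan_seed <- config$seed * 1000L + pid * 10L + sc

      # --- PET arm: phantom, input function, per-kidney 1TCM fit
      spec <- default_phantom_spec(
        cortex_left = kinetic_params(tl / 100, tl / (100 * p), 0.15, 4),
        cortex_right = kinetic_params(tr / 100, tr / (100 * p), 0.15, 4))
      ph <- build_pet_phantom(spec, schedule, input,
                              psf_fwhm = config$psf_fwhm,
                              noise_scale = config$pet_noise_scale,
                              seed = scan_seed)
      pet_input <- if (config$use_idif) {
        box <- array(FALSE, spec$shape)
        box[20:28, 20:28, 3:22] <- TRUE
        extract_idif(ph$dynamic, box, schedule, n_clusters = 3,
                     seed = scan_seed)$input
      } else input
      for (kd in c("left", "right")) {
        lab <- if (kd == "left") 2L else 3L
        ktac <- extract_tac(ph$dynamic, ph$labels == lab, schedule)
        fit <- fit_1tcm(ktac, pet_input, config$fit)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, kidney = kd, day = ifelse(sc == 3, 2L, 1L),
          scan = sc, modality = "PET",
          perfusion_ml_min_100ml = fit$perfusion,
          truth = if (kd == "left") tl else tr)
      }

      # --- ASL arm: forward series, quantification, thresholded ROI mean
      fmap <- array(0, geom$shape)
      fmap[geom$left] <- tl
      fmap[geom$right] <- tr
      m0 <- array(1000, geom$shape)
      series <- build_asl_series(fmap, m0, config$asl,
                                 n_pairs = config$n_pairs,
                                 noise_sd = config$asl_noise_sd,
                                 seed = scan_seed)
      avg <- average_pairs(series)
      pmap <- quantify_perfusion(avg$delta_m, avg$m0, config$asl)
      for (kd in c("left", "right")) {
        roi <- roi_perfusion(pmap, geom[[kd]], config$asl)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, kidney = kd, day = ifelse(sc == 3, 2L, 1L),
          scan = sc, modality = "ASL",
          perfusion_ml_min_100ml = roi$mean,
          truth = if (kd == "left") tl else tr)
      }
    }
  }
  table <- do.call(rbind, rows)
  table <- table[order(table$participant, table$kidney, table$scan,
                       table$modality), , drop = FALSE]
  rownames(table) <- NULL

  wide <- merge(table[table$modality == "ASL",
                      c("participant", "kidney", "scan", "perfusion_ml_min_100ml")],
                table[table$modality == "PET",
                      c("participant", "kidney", "scan", "perfusion_ml_min_100ml")],
                by = c("participant", "kidney", "scan"),
                suffixes = c("_asl", "_pet"))
  regression <- if (nrow(wide) >= 3 &&
                    stats::var(wide$perfusion_ml_min_100ml_asl) > 1e-12)
    linear_fit(wide$perfusion_ml_min_100ml_asl,
               wide$perfusion_ml_min_100ml_pet) else NULL
  ba <- bland_altman(wide$perfusion_ml_min_100ml_asl,
                     wide$perfusion_ml_min_100ml_pet)

  mixed_fit <- NULL
  comparisons <- list()
  if (config$n_participants >= 2) {
    mixed_fit <- fit_mixed_model(table)
    comps <- list(comparison_repeatability("ASL"),
                  comparison_repeatability("PET"),
                  comparison_reproducibility("ASL"),
                  comparison_reproducibility("PET"),
                  comparison_cross_modality())
    comparisons <- lapply(comps, function(cc) derive_agreement(mixed_fit, cc))
    names(comparisons) <- vapply(comparisons, `[[`, character(1), "name")
  }

  provenance <- list(package = "renalperf",
                     version = as.character(utils::packageVersion("renalperf")),
                     seed = config$seed,
                     n_participants = config$n_participants,
                     pet_noise_scale = config$pet_noise_scale,
                     asl_noise_sd = config$asl_noise_sd,
                     psf_fwhm = config$psf_fwhm,
                     use_idif = config$use_idif)
  out <- list(table = table, truths = truths, mixed_fit = mixed_fit,
              comparisons = comparisons, regression = regression,
              bland_altman = ba, provenance = provenance)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_agreement_table(table, file.path(config$out_dir, "agreement_table.csv"))
    res <- list(provenance = provenance,
                fixed_effects = if (!is.null(mixed_fit)) as.list(mixed_fit$fixed),
                sds = if (!is.null(mixed_fit)) as.list(mixed_fit$sds),
                comparisons = lapply(comparisons, function(x)
                  x[c("name", "bias", "loa", "cov_percent")]),
                bland_altman = ba, regression = regression)
    jsonlite::write_json(res, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
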