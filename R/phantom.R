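#' Simulate a framed time-activity curve
#'
#' Frame values are the exact time-averages of the forward 1TCM prediction
#' over each frame interval.  Optional zero-mean Gaussian noise with
#' per-frame SD proportional to `sqrt(value / duration)` emulates the
#' count-statistics behaviour of reconstructed PET frames (short, hot
#' frames are noisier per unit activity than long ones).
#'
#' @param params A [kinetic_params()].
#' @param input An [aif()]; must span the schedule.
#' @param schedule A [frame_schedule()].
#' @param noise_scale Non-negative noise multiplier; 0 gives the noise-free
#'   curve.
#' @param seed Integer seed used when `noise_scale > 0`.
#' @return A [tac()].
#' @export
simulate_tac <- function(params, input, schedule, noise_scale = 0, seed = 1) {
  stopifnot(inherits(params, "kinetic_params"), inherits(input, "aif"),
            inherits(schedule, "frame_schedule"))
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  if (schedule_span(schedule) > input$time[length(input$time)] + 1e-9)
    stop("schedule exceeds the input function's span")
  v <- .predict_frames(params, input, schedule)
  if (noise_scale > 0) {
    sd <- noise_scale * sqrt(pmax(v, 0) / schedule$frame_durations)
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, sd)
  }
  tac(v, schedule)
}

#' Phantom geometry and kinetics specification
#'
#' Describes a digital phantom: image shape, voxel size, and a list of
#' non-overlapping regions.  Each region is a list with elements `name`,
#' `label` (unique positive integer), `shape` (`"ellipsoid"` or `"box"`),
#' `center` and `semi_axes` (voxel-index units, 1-based), and either
#' `params` (a [kinetic_params()]) or `is_blood = TRUE` for regions that
#' carry the arterial curve directly (the aorta).
#'
#' @param shape Integer vector of 3 image dimensions (voxels).
#' @param voxel_size_mm Isotropic voxel edge length, mm.  Default 3.
#' @param regions List of region descriptions (see above).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size_mm = 3, regions) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  labels <- vapply(regions, `[[`, numeric(1), "label")
  if (anyDuplicated(labels) || any(labels <= 0))
    stop("region labels must be unique positive integers")
  for (r in regions) {
    if (!r$shape %in% c("ellipsoid", "box")) stop("unknown region shape: ", r$shape)
    if (any(r$center - r$semi_axes < 0.5) || any(r$center + r$semi_axes > shape + 0.5))
      stop("region '", r$name, "' extends beyond the image bounds")
    if (is.null(r$params) && !isTRUE(r$is_blood))
      stop("region '", r$name, "' needs kinetic params or is_blood = TRUE")
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 regions = regions), class = "phantom_spec")
}

# Logical mask for one region on the phantom grid.
.region_mask <- function(region, shape) {
  i <- slice.index(array(0, shape), 1L)
  j <- slice.index(array(0, shape), 2L)
  k <- slice.index(array(0, shape), 3L)
  c0 <- region$center; s <- region$semi_axes
  if (region$shape == "ellipsoid") {
    ((i - c0[1]) / s[1])^2 + ((j - c0[2]) / s[2])^2 + ((k - c0[3]) / s[3])^2 <= 1
  } else {
    abs(i - c0[1]) <= s[1] & abs(j - c0[2]) <= s[2] & abs(k - c0[3]) <= s[3]
  }
}

#' Default two-kidney phantom specification
#'
#' A coarse abdominal layout on a 48 x 48 x 24 grid of 3-mm voxels: a
#' central elongated aorta carrying the arterial curve (10-mm radius,
#' matching the calibre of the adult abdominal aorta so that its core
#' survives scanner-typical point-spread blur), left and right cortex
#' ellipsoids with high-flow kinetics (K1 3 mL/min/mL, k2 3.19 /min,
#' i.e. perfusion near 300 mL/min/100 mL), and lower-flow medulla
#' ellipsoids between cortex and aorta.
#'
#' @param cortex_left,cortex_right Optional [kinetic_params()] overrides
#'   for the two cortices.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(cortex_left = kinetic_params(3.0, 3.19, 0.15, 4),
                                 cortex_right = kinetic_params(2.8, 2.98, 0.15, 4)) {
  regions <- list(
    list(name = "aorta", label = 1L, shape = "ellipsoid",
         center = c(24, 24, 12), semi_axes = c(3.3, 3.3, 9), is_blood = TRUE),
    list(name = "cortex_left", label = 2L, shape = "ellipsoid",
         center = c(10, 24, 12), semi_axes = c(6, 8, 7), params = cortex_left),
    list(name = "cortex_right", label = 3L, shape = "ellipsoid",
         center = c(38, 24, 12), semi_axes = c(6, 8, 7), params = cortex_right),
    list(name = "medulla_left", label = 4L, shape = "ellipsoid",
         center = c(18.5, 24, 12), semi_axes = c(1.8, 3, 3),
         params = kinetic_params(1.2, 1.1, 0.15, 5)),
    list(name = "medulla_right", label = 5L, shape = "ellipsoid",
         center = c(29.5, 24, 12), semi_axes = c(1.8, 3, 3),
         params = kinetic_params(1.2, 1.1, 0.15, 5)))
  phantom_spec(c(48, 48, 24), 3, regions)
}

# Separable Gaussian blur of a 3D array, sigma per axis in voxels.
# Truncated-kernel band matrices with row renormalisation preserve the
# mean of constant images near the edges.
.gauss_blur3d <- function(vol, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(vol)[ax]
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    K <- exp(-d^2 / (2 * s^2))
    K[d > ceiling(4 * s)] <- 0
    K <- K / rowSums(K)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = dv[1])
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Build a dynamic PET phantom
#'
#' Assigns each region's noise-free frame-averaged 1TCM curve (or the
#' arterial curve, for blood regions) to its voxels, optionally blurs every
#' frame with an isotropic Gaussian point-spread function to emulate
#' scanner resolution and cross-region spill-over, and adds count-like
#' Gaussian noise per voxel and frame.
#'
#' @param spec A [phantom_spec()].
#' @param schedule A [frame_schedule()].
#' @param input An [aif()] driving all kinetics.
#' @param psf_fwhm Full width at half maximum of the PSF, mm.  Default 0
#'   (no blur).
#' @param noise_scale As in [simulate_tac()].  Default 0.
#' @param seed Integer seed for the noise.
#' @return List: `dynamic` (4D array), `labels` (integer 3D array),
#'   `region_tacs` (named list of noise-free [tac()]s), `schedule`,
#'   `input`, `spec`.
#' @export
build_pet_phantom <- function(spec, schedule, input, psf_fwhm = 0,
                              noise_scale = 0, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(schedule, "frame_schedule"),
            inherits(input, "aif"))
  if (psf_fwhm < 0 || noise_scale < 0)
    stop("psf_fwhm and noise_scale must be non-negative")
  shape <- spec$shape
  labels <- array(0L, shape)
  masks <- list()
  for (r in spec$regions) {
    m <- .region_mask(r, shape)
    if (any(labels[m] != 0L))
      stop("region masks overlap at region '", r$name, "'")
    labels[m] <- as.integer(r$label)
    masks[[r$name]] <- m
  }
  nf <- length(schedule$frame_starts)
  region_tacs <- list()
  curves <- matrix(0, nrow = length(spec$regions), ncol = nf)
  for (ii in seq_along(spec$regions)) {
    r <- spec$regions[[ii]]
    v <- if (isTRUE(r$is_blood)) .frame_means(input$values, input$time, schedule)
         else .predict_frames(r$params, input, schedule)
    curves[ii, ] <- v
    region_tacs[[r$name]] <- tac(v, schedule)
  }
  dynamic <- array(0, c(shape, nf))
  sigma_vox <- rep(psf_fwhm / 2.3548 / spec$voxel_size_mm, 3)
  for (f in seq_len(nf)) {
    vol <- array(0, shape)
    for (ii in seq_along(spec$regions))
      vol[masks[[spec$regions[[ii]]$name]]] <- curves[ii, f]
    if (psf_fwhm > 0) vol <- .gauss_blur3d(vol, sigma_vox)
    dynamic[, , , f] <- vol
  }
  if (noise_scale > 0) {
    set.seed(seed)
    sd <- sqrt(pmax(dynamic, 0) /
                 rep(schedule$frame_durations, each = prod(shape))) * noise_scale
    dynamic <- dynamic + array(stats::rnorm(length(dynamic), 0, sd), dim(dynamic))
  }
  list(dynamic = dynamic, labels = labels, region_tacs = region_tacs,
       schedule = schedule, input = input, spec = spec)
}

#' Simulate a FAIR-ASL control/label series from a known perfusion map
#'
#' Each pair's control-minus-label difference equals, voxel by voxel, the
#' forward FAIR difference signal obtained by inverting
#' [quantify_perfusion()] at the true perfusion with the same constants;
#' independent Gaussian noise of SD `noise_sd` is added to every control
#' and label image.  The proton-density image is `m0_map` exactly.
#'
#' @param true_perfusion Array of true perfusion values, mL/min/100 mL.
#' @param m0_map Equilibrium-magnetisation array, same shape.
#' @param params An [asl_params()].
#' @param n_pairs Number of control/label repetitions.  Default 20.
#' @param noise_sd Gaussian noise SD in signal units.  Default 0.
#' @param seed Integer seed.
#' @return An [asl_series()].
#' @export
build_asl_series <- function(true_perfusion, m0_map, params = asl_params(),
                             n_pairs = 20, noise_sd = 0, seed = 1) {
  if (!identical(dim(true_perfusion), dim(m0_map)) ||
      length(true_perfusion) != length(m0_map))
    stop("true_perfusion and m0_map must share a shape")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  spat <- dim(true_perfusion)
  if (is.null(spat)) spat <- length(true_perfusion)
  dm <- .forward_delta_m(true_perfusion, m0_map, params)
  nv <- prod(spat)
  set.seed(seed)
  control <- array(rep(as.numeric(m0_map), each = n_pairs), c(n_pairs, spat))
  label <- array(rep(as.numeric(m0_map - dm), each = n_pairs), c(n_pairs, spat))
  if (noise_sd > 0) {
    control <- control + stats::rnorm(n_pairs * nv, 0, noise_sd)
    label <- label + stats::rnorm(n_pairs * nv, 0, noise_sd)
  }
  asl_series(control, label, m0_map)
}

#' Study design for the agreement simulator
#'
#' The crossed/nested design of the dual-modality perfusion study:
#' participants each contribute two kidneys, three scans (scans 1 and 2 on
#' day 1, about 15 minutes apart; scan 3 on day 2) and two modalities
#' measured simultaneously at every scan.  Fixed effects are a modality
#' offset, scan-sequence offsets and their interaction, on top of a grand
#' mean.  Defaults emulate pooled healthy-kidney cortical perfusion values
#' (around 280-310 mL/min/100 mL, PET slightly above ASL).
#'
#' @param n_participants Number of participants.  Default 10.
#' @param grand_mean Reference cell mean (first modality, scan 1),
#'   mL/min/100 mL.
#' @param modality_effect Named offsets per modality, mL/min/100 mL.
#' @param scan_effect Offsets for scans 1-3, mL/min/100 mL.
#' @param interaction Matrix (modality x scan) of interaction offsets.
#' @return Object of class `agreement_design`.
#' @export
agreement_design <- function(n_participants = 10, grand_mean = 286,
                             modality_effect = c(ASL = 0, PET = 13),
                             scan_effect = c(0, -5, -1),
                             interaction = rbind(ASL = c(0, 0, 0),
                                                 PET = c(0, 1, 12))) {
  if (n_participants < 1) stop("need at least one participant")
  if (length(scan_effect) != 3L) stop("scan_effect must have 3 entries")
  stopifnot(identical(rownames(interaction), names(modality_effect)),
            ncol(interaction) == 3L)
  structure(list(n_participants = as.integer(n_participants),
                 grand_mean = grand_mean, modality_effect = modality_effect,
                 scan_effect = scan_effect, interaction = interaction,
                 kidneys = c("left", "right"),
                 scan_day = c(`1` = 1L, `2` = 1L, `3` = 2L)),
            class = "agreement_design")
}

#' True variance components for the agreement simulator
#'
#' Standard deviations of the random effects: participant (modality
#' specific), kidney within participant (shared between modalities), day
#' within kidney (modality specific) and residual scan-to-scan variation
#' (modality specific).  Defaults emulate the dispersion seen in healthy
#' renal cortex: residual SDs near 31 (ASL) and 25 (PET) mL/min/100 mL,
#' small day-to-day SDs, and between-participant SDs near 39.
#'
#' @param sd_participant Named vector per modality.
#' @param sd_kidney Scalar SD shared across modalities.
#' @param sd_day Named vector per modality.
#' @param sd_residual Named vector per modality.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(sd_participant = c(ASL = 39.4, PET = 39.4),
                                sd_kidney = 25,
                                sd_day = c(ASL = 8.4, PET = 8.5),
                                sd_residual = c(ASL = 30.8, PET = 25.0)) {
  if (any(c(sd_participant, sd_kidney, sd_day, sd_residual) < 0))
    stop("all SDs must be non-negative")
  structure(list(sd_participant = sd_participant, sd_kidney = sd_kidney,
                 sd_day = sd_day, sd_residual = sd_residual),
            class = "variance_components")
}

#' Simulate a long-format agreement table
#'
#' Draws modality-specific participant effects, shared kidney-within-
#' participant effects, modality-specific day-within-kidney effects and
#' modality-specific residuals, all independent Gaussian, and assembles
#' one row per (participant, kidney, day, scan, modality).
#'
#' @param design An [agreement_design()].
#' @param vc A [variance_components()].
#' @param seed Integer seed.
#' @param sd_participant_shared Optional SD of an additional participant
#'   effect shared between modalities (shared-plus-specific decomposition).
#'   Default 0.
#' @return `data.frame` with columns `participant`, `kidney`, `day`,
#'   `scan`, `modality`, `perfusion_ml_min_100ml`.
#' @export
simulate_agreement_dataset <- function(design, vc, seed = 1,
                                       sd_participant_shared = 0) {
  stopifnot(inherits(design, "agreement_design"),
            inherits(vc, "variance_components"))
  if (sd_participant_shared < 0) stop("shared participant SD must be >= 0")
  mods <- names(design$modality_effect)
  grid <- expand.grid(participant = seq_len(design$n_participants),
                      kidney = design$kidneys, scan = 1:3, modality = mods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$day <- design$scan_day[as.character(grid$scan)]
  set.seed(seed)
  np <- design$n_participants
  p_shared <- stats::rnorm(np, 0, sd_participant_shared)
  p_eff <- matrix(stats::rnorm(np * length(mods)), np,
                  dimnames = list(NULL, mods))
  p_eff <- sweep(p_eff, 2L, vc$sd_participant[mods], `*`)
  k_key <- expand.grid(participant = seq_len(np), kidney = design$kidneys,
                       stringsAsFactors = FALSE)
  k_eff <- stats::rnorm(nrow(k_key), 0, vc$sd_kidney)
  names(k_eff) <- paste(k_key$participant, k_key$kidney)
  d_key <- expand.grid(participant = seq_len(np), kidney = design$kidneys,
                       day = 1:2, modality = mods, stringsAsFactors = FALSE)
  d_eff <- stats::rnorm(nrow(d_key)) *
    vc$sd_day[d_key$modality]
  names(d_eff) <- paste(d_key$participant, d_key$kidney, d_key$day,
                        d_key$modality)
  resid <- stats::rnorm(nrow(grid)) * vc$sd_residual[grid$modality]

  mod_idx <- match(grid$modality, mods)
  fx <- design$grand_mean + design$modality_effect[grid$modality] +
    design$scan_effect[grid$scan] +
    design$interaction[cbind(mod_idx, grid$scan)]
  val <- fx + p_shared[grid$participant] +
    p_eff[cbind(grid$participant, mod_idx)] +
    k_eff[paste(grid$participant, grid$kidney)] +
    d_eff[paste(grid$participant, grid$kidney, grid$day, grid$modality)] +
    resid
  out <- data.frame(participant = grid$participant, kidney = grid$kidney,
                    day = grid$day, scan = grid$scan, modality = grid$modality,
                    perfusion_ml_min_100ml = as.numeric(val),
                    stringsAsFactors = FALSE)
  out[order(out$participant, out$kidney, out$scan, out$modality), ,
      drop = FALSE]
}
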