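#' FAIR-ASL quantification parameters
#'
#' Constants of the single-subtraction FAIR perfusion model.  Defaults are
#' the renal protocol values: blood T1 1600 ms, tissue T1 1400 ms (carried
#' for the optional vendor-style correction), partition coefficient
#' 0.9 mL/g, combined labelling/background-suppression efficiency 0.6375,
#' inflow time 1500 ms, and a 500 mL/min/100 mL voxel exclusion threshold
#' for cortical ROI means.
#'
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#' @param t1_tissue Longitudinal relaxation time of tissue, ms.
#' @param partition_coefficient Blood-tissue partition coefficient, mL/g.
#' @param efficiency Combined inversion/background-suppression efficiency,
#'   in (0, 1].
#' @param inflow_time Inversion-to-readout inflow time TI, ms.
#' @param exclusion_threshold ROI voxel exclusion threshold,
#'   mL/min/100 mL.
#' @param correction_factor Optional multiplicative correction applied to
#'   quantified perfusion (slot for a vendor-specific tissue-relaxation
#'   variant).  Default 1 (off).
#' @return Object of class `asl_params`.
#' @export
asl_params <- function(t1_blood = 1600, t1_tissue = 1400,
                       partition_coefficient = 0.9, efficiency = 0.6375,
                       inflow_time = 1500, exclusion_threshold = 500,
                       correction_factor = 1) {
  if (any(c(t1_blood, t1_tissue, partition_coefficient, inflow_time,
            exclusion_threshold, correction_factor) <= 0))
    stop("all ASL parameters must be positive")
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  if (inflow_time >= 5 * t1_blood)
    stop("inflow time must be well below 5 * t1_blood")
  structure(list(t1_blood = t1_blood, t1_tissue = t1_tissue,
                 partition_coefficient = partition_coefficient,
                 efficiency = efficiency, inflow_time = inflow_time,
                 exclusion_threshold = exclusion_threshold,
                 correction_factor = correction_factor),
            class = "asl_params")
}

#' ASL control/label series container
#'
#' @param control,label Arrays of shape (pairs, ...spatial...) holding the
#'   control and label images; first dimension indexes repetition pairs.
#' @param proton_density Spatial array (the trailing dimensions of
#'   control/label) with the equilibrium-magnetisation image.
#' @return Object of class `asl_series`.
#' @export
asl_series <- function(control, label, proton_density) {
  if (!identical(dim(control), dim(label)))
    stop("control and label stacks must share a shape")
  dc <- dim(control)
  if (is.null(dc) || dc[1] < 1L) stop("at least one control/label pair required")
  spat <- dc[-1L]
  pd_dim <- dim(proton_density)
  if (is.null(pd_dim)) pd_dim <- length(proton_density)
  if (!identical(as.integer(pd_dim), as.integer(spat)))
    stop("proton_density shape must match the spatial shape of the stacks")
  structure(list(control = control, label = label,
                 proton_density = proton_density),
            class = "asl_series")
}

#' Average repetition pairs into a perfusion-weighted difference image
#'
#' @param series An [asl_series()].
#' @return List with `delta_m` (voxelwise mean over pairs of
#'   control minus label) and `m0` (the proton-density image, passed
#'   through).
#' @export
average_pairs <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  d <- series$control - series$label
  spat <- dim(d)[-1L]
  dm <- apply(d, seq_along(dim(d))[-1L], mean)
  dim(dm) <- spat
  list(delta_m = dm, m0 = series$proton_density)
}

#' Quantify perfusion from an averaged difference image
#'
#' Single-subtraction FAIR quantification:
#' `f = 6000 lambda dM exp(TI / T1b) / (2 alpha TI M0)`
#' with TI in seconds, lambda in mL/g and the factor 6000 converting
#' mL/g/s to mL/min/100 g (reported as mL/min/100 mL at unit tissue
#' density).  Voxels with non-positive `m0` are marked invalid.
#'
#' @param delta_m Averaged control-minus-label image (signal units).
#' @param m0 Proton-density image, same shape.
#' @param params An [asl_params()].
#' @return Object of class `perfusion_map`: list with `values`
#'   (mL/min/100 mL, `NA` where invalid) and logical `valid`.
#' @examples
#' p <- quantify_perfusion(41.608, 1000, asl_params())
#' p$values    # 300 mL/min/100 mL
#' @export
quantify_perfusion <- function(delta_m, m0, params = asl_params()) {
  stopifnot(inherits(params, "asl_params"))
  if (!identical(dim(delta_m), dim(m0)) ||
      length(delta_m) != length(m0))
    stop("delta_m and m0 must share a shape")
  ti_s <- params$inflow_time / 1000
  if (ti_s <= 0) stop("inflow time must be positive")
  valid <- is.finite(m0) & m0 > 0
  f <- delta_m
  f[] <- NA_real_
  f[valid] <- 6000 * params$partition_coefficient * delta_m[valid] *
    exp(params$inflow_time / params$t1_blood) /
    (2 * params$efficiency * ti_s * m0[valid]) * params$correction_factor
  structure(list(values = f, valid = valid), class = "perfusion_map")
}

# Forward FAIR difference signal for a known perfusion map; the exact
# inverse of quantify_perfusion, used by the phantom generator.
.forward_delta_m <- function(perfusion, m0, params) {
  ti_s <- params$inflow_time / 1000
  perfusion * 2 * params$efficiency * ti_s * m0 *
    exp(-params$inflow_time / params$t1_blood) /
    (6000 * params$partition_coefficient * params$correction_factor)
}

#' Cortical ROI perfusion with voxel exclusion
#'
#' Mean perfusion over the ROI's valid voxels after removing voxels whose
#' value exceeds the exclusion threshold (default 500 mL/min/100 mL),
#' which suppresses large-vessel and artifactual voxels in renal cortex
#' ROIs.
#'
#' @param map A `perfusion_map` from [quantify_perfusion()].
#' @param roi_mask Array of the map's shape; voxels with `roi_mask > 0`
#'   belong to the ROI.
#' @param params An [asl_params()] supplying the threshold.
#' @return List: `mean` (mL/min/100 mL), `n_used`, `n_excluded`.
#' @examples
#' m <- structure(list(values = c(300, 400, 600),
#'                     valid = rep(TRUE, 3)), class = "perfusion_map")
#' roi_perfusion(m, c(1, 1, 1))   # mean 350, one voxel excluded
#' @export
roi_perfusion <- function(map, roi_mask, params = asl_params()) {
  stopifnot(inherits(map, "perfusion_map"))
  in_roi <- roi_mask > 0 & map$valid
  if (!any(in_roi)) stop("empty ROI after validity intersection")
  v <- map$values[in_roi]
  keep <- v <= params$exclusion_threshold
  if (!any(keep)) stop("empty ROI: all voxels exceed the exclusion threshold")
  list(mean = mean(v[keep]), n_used = sum(keep), n_excluded = sum(!keep))
}

#' Automated per-slice quality control
#'
#' Deterministic surrogate for visual slice rejection on perfusion-weighted
#' images.  Two statistics are computed per slice of the averaged
#' difference stack: the fraction of negative voxels (a pure-noise slice
#' with zero mean difference sits near 0.5) and the slice mean relative to
#' the median slice mean (vanishing relative signal indicates a failed
#' slice).  A slice is kept when both statistics pass.
#'
#' @param delta_m_stack 3D array (slice, row, col) of averaged difference
#'   images, or a list of 2D slices.
#' @param max_negative_fraction Exclude slices with more negative voxels
#'   than this fraction.  Default 0.4.  `NA` disables the check.
#' @param min_signal_fraction Exclude slices whose mean is below this
#'   fraction of the median slice mean.  Default 0.1.  `NA` disables.
#' @return Logical vector, `TRUE` for included slices.
#' @export
slice_qc <- function(delta_m_stack, max_negative_fraction = 0.4,
                     min_signal_fraction = 0.1) {
  if (is.list(delta_m_stack))
    delta_m_stack <- simplify2array(delta_m_stack, higher = TRUE)
  if (length(dim(delta_m_stack)) == 2L)
    dim(delta_m_stack) <- c(1L, dim(delta_m_stack))
  ns <- dim(delta_m_stack)[1]
  slice_vals <- lapply(seq_len(ns), function(s) as.numeric(delta_m_stack[s, , ]))
  neg_frac <- vapply(slice_vals, function(v) mean(v < 0), numeric(1))
  means <- vapply(slice_vals, mean, numeric(1))
  ref <- stats::median(means)
  include <- rep(TRUE, ns)
  if (!is.na(max_negative_fraction))
    include <- include & neg_frac <= max_negative_fraction
  if (!is.na(min_signal_fraction) && ref > 0)
    include <- include & means >= min_signal_fraction * ref
  include
}
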