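#' Default clearance-rate basis grid
#'
#' 50 logarithmically spaced clearance values in \[0.06, 6\] /min, bracketing
#' the physiological renal range (about 1-5 /min).
#'
#' @param n Number of grid nodes.  Default 50.
#' @param range Two-element clearance range, 1/min.
#' @return Sorted numeric vector of clearance rates.
#' @export
theta_grid_default <- function(n = 50, range = c(0.06, 6)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Basis-function parametric perfusion maps
#'
#' Voxelwise 1TCM estimation by the basis-function method: tissue response
#' curves `B_theta(t) = [Ca(. - delay) * exp(-theta .)](t)` are precomputed
#' on the clearance grid and frame-averaged over the fit window, reducing
#' each voxel to a one-parameter weighted linear solve for `K1` at every
#' `theta` (with the fixed `Va` blood term subtracted) followed by grid
#' selection of the clearance minimising weighted residual sum of squares.
#'
#' @param dynamic 4D array (x, y, z, frame).
#' @param input An [aif()].
#' @param schedule The [frame_schedule()] of the series.
#' @param delay Fixed arterial delay (s), typically taken from an ROI fit.
#' @param theta_grid Sorted positive clearance grid (1/min).  Default
#'   [theta_grid_default()].
#' @param va Fixed blood volume fraction.  Default 0.15.
#' @param config A [fit_config()]; supplies fit window, weights, partition
#'   coefficient and blood model.
#' @param mask Optional 3D mask; voxels outside it get `NA` maps.
#' @return List of 3D arrays `K1` (mL/min/mL), `k2` (1/min), `perfusion`
#'   (mL/min/100 mL) and `rss`, plus `theta_grid`.
#' @export
parametric_maps <- function(dynamic, input, schedule, delay = 0,
                            theta_grid = theta_grid_default(), va = 0.15,
                            config = fit_config(), mask = NULL) {
  stopifnot(length(dim(dynamic)) == 4L, inherits(input, "aif"))
  if (length(theta_grid) == 0L) stop("theta_grid must be non-empty")
  if (is.unsorted(theta_grid) || any(theta_grid <= 0))
    stop("theta_grid must be sorted and positive")
  dims <- dim(dynamic)
  mid <- frame_midtimes(schedule)
  keep <- which(mid <= config$fit_window + 1e-9)
  sched_w <- frame_schedule(schedule$frame_starts[keep],
                            schedule$frame_durations[keep])
  w <- if (config$weights == "duration") sched_w$frame_durations else
    rep(1, length(keep))
  w <- w / sum(w)
  tisw <- if (config$blood_model == "mixed") 1 - va else 1

  ca_d <- aif_at(input, input$time, delay = delay)
  ca_f <- .frame_means(ca_d, input$time, sched_w)
  basis <- vapply(theta_grid, function(th)
    tisw * .frame_means(.conv_exp(ca_d, input$dt, th / 60), input$time, sched_w),
    numeric(length(keep)))            # frames x n_theta

  vox_idx <- if (is.null(mask)) seq_len(prod(dims[1:3])) else which(mask > 0)
  ymat <- matrix(dynamic, ncol = dims[4])[vox_idx, keep, drop = FALSE]
  ymat <- sweep(ymat, 2L, va * ca_f)  # remove fixed blood contribution
  nv <- length(vox_idx)

  best_rss <- rep(Inf, nv); best_k1s <- numeric(nv); best_th <- numeric(nv)
  yw <- sweep(ymat, 2L, w, `*`)
  rss_y <- rowSums(yw * ymat)         # sum w y^2, constant across theta
  for (i in seq_along(theta_grid)) {
    b <- basis[, i]
    den <- sum(w * b * b)
    k1s <- if (den > 0) pmax(0, (yw %*% b)[, 1] / den) else numeric(nv)
    # rss = sum w (y - k1 b)^2 = rss_y - 2 k1 sum(w y b) + k1^2 den
    rss <- rss_y - 2 * k1s * (yw %*% b)[, 1] + k1s^2 * den
    upd <- rss < best_rss
    best_rss[upd] <- rss[upd]; best_k1s[upd] <- k1s[upd]
    best_th[upd] <- theta_grid[i]
  }

  shape3 <- dims[1:3]
  blank <- array(NA_real_, shape3)
  k1_map <- k2_map <- rss_map <- blank
  k1_map[vox_idx] <- best_k1s * 60
  k2_map[vox_idx] <- best_th
  rss_map[vox_idx] <- best_rss
  perf_map <- blank
  perf_map[vox_idx] <- perfusion_from_k2(best_th, config$partition_coefficient)
  list(K1 = k1_map, k2 = k2_map, perfusion = perf_map, rss = rss_map,
       theta_grid = theta_grid)
}

#' Image-derived input function by k-means clustering
#'
#' Voxel time-activity curves inside a search region are area-normalised
#' and partitioned by k-means; the arterial cluster is the one maximising
#' peak value over tail mean (ties broken by earliest time to peak), and
#' the IDIF is the mean raw curve over that cluster's voxels (optionally
#' restricted to the hottest fraction by peak value).
#'
#' @param dynamic 4D array (x, y, z, frame).
#' @param search_mask 3D mask of candidate voxels (e.g. a box around the
#'   abdominal aorta).
#' @param schedule The [frame_schedule()] of the series.
#' @param n_clusters Number of k-means clusters, `>= 2`.  Default 4.
#' @param keep_fraction Fraction of arterial-cluster voxels retained,
#'   hottest first.  Default 1 (all).
#' @param tail_fraction Fraction of late frames defining the tail mean used
#'   in cluster scoring.  Default 0.25.
#' @param seed Integer seed for the k-means initialisation.
#' @return List with `input` (an [aif()] interpolated from frame midtimes),
#'   `tac` (the arterial-cluster [tac()]), `mask` (logical 3D array of the
#'   selected voxels) and `cluster_labels` (integer labels over the search
#'   region, as a 3D array with 0 outside it).
#' @export
extract_idif <- function(dynamic, search_mask, schedule, n_clusters = 4,
                         keep_fraction = 1, tail_fraction = 0.25, seed = 1) {
  stopifnot(length(dim(dynamic)) == 4L)
  idx <- which(search_mask > 0)
  if (length(idx) == 0L) stop("empty search mask")
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (length(idx) < n_clusters)
    stop("fewer candidate voxels than clusters")
  nf <- dim(dynamic)[4]
  vox <- matrix(dynamic, ncol = nf)[idx, , drop = FALSE]

  dur <- schedule$frame_durations
  area <- as.numeric(vox %*% dur)
  norm <- vox / ifelse(abs(area) > 1e-12, area, 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(norm, centers = n_clusters, nstart = 5, iter.max = 50)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  mid <- frame_midtimes(schedule)
  tail_n <- max(1L, ceiling(tail_fraction * nf))
  tail_id <- seq.int(nf - tail_n + 1L, nf)
  score <- t2p <- numeric(n_clusters)
  for (k in seq_len(n_clusters)) {
    cur <- colMeans(vox[km$cluster == k, , drop = FALSE])
    pk <- max(cur)
    tl <- mean(cur[tail_id])
    score[k] <- if (tl > 1e-12) pk / tl else ifelse(pk > 0, Inf, 0)
    t2p[k] <- mid[which.max(cur)]
  }
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(t2p[best])]

  sel <- which(km$cluster == best)
  if (keep_fraction < 1) {
    peaks <- apply(vox[sel, , drop = FALSE], 1L, max)
    n_keep <- max(1L, ceiling(keep_fraction * length(sel)))
    sel <- sel[order(peaks, decreasing = TRUE)[seq_len(n_keep)]]
  }
  curve <- colMeans(vox[sel, , drop = FALSE])

  out_mask <- array(FALSE, dim(dynamic)[1:3])
  out_mask[idx[sel]] <- TRUE
  labels <- array(0L, dim(dynamic)[1:3])
  labels[idx] <- km$cluster
  list(input = aif_from_tac(curve, schedule),
       tac = tac(curve, schedule), mask = out_mask, cluster_labels = labels)
}
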