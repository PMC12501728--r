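#' Simple linear regression between two perfusion series
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination and a two-sided t test of the slope.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) < .Machine$double.eps * max(1, mean(x)^2))
    stop("degenerate input: x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `b - a`; bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96` sample SDs (denominator `n - 1`).
#'
#' @param a,b Numeric vectors of equal length, `n >= 2`.
#' @return List: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

# ---- REML variance-components model ---------------------------------------

# Build indicator cross-products per variance parameter for one participant
# block.  vp_defs is a list of lists(term, modality or NA); rows is the
# block's data rows (already ordered).
.block_rand_mats <- function(rows, vp_defs) {
  lapply(vp_defs, function(vp) {
    if (vp$term == "residual") return(NULL)
    g <- switch(vp$term,
                participant = rep("all", nrow(rows)),
                kidney = rows$kidney,
                day = paste(rows$kidney, rows$day))
    inc <- if (is.na(vp$modality)) rep(TRUE, nrow(rows)) else
      rows$modality == vp$modality
    lev <- unique(g[inc])
    Z <- outer(g, lev, `==`) * inc
    tcrossprod(Z)
  })
}

.reml_neg2ll <- function(log_sd, patterns, vp_defs, resid_idx) {
  sds <- exp(log_sd)
  p <- ncol(patterns[[1]]$X)
  XtViX <- matrix(0, p, p); XtViy <- numeric(p)
  ytViy <- 0; logdet <- 0
  for (pat in patterns) {
    nb <- nrow(pat$X)
    V <- diag(sds[resid_idx[pat$res_par]]^2, nb)
    for (v in seq_along(vp_defs)) {
      if (!is.null(pat$M[[v]])) V <- V + sds[v]^2 * pat$M[[v]]
    }
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    Xs <- backsolve(L, pat$X, transpose = TRUE)
    logdet <- logdet + 2 * sum(log(diag(L))) * length(pat$ys)
    XtViX <- XtViX + crossprod(Xs) * length(pat$ys)
    for (y in pat$ys) {
      ysv <- backsolve(L, y, transpose = TRUE)
      XtViy <- XtViy + crossprod(Xs, ysv)[, 1]
      ytViy <- ytViy + sum(ysv^2)
    }
  }
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, backsolve(ch, XtViy, transpose = TRUE))
  quad <- ytViy - sum(XtViy * beta)
  as.numeric(logdet + 2 * sum(log(diag(ch))) + quad)
}

# Fixed-effect GLS estimate at given variance parameters.
.reml_beta <- function(log_sd, patterns, vp_defs, resid_idx) {
  sds <- exp(log_sd)
  p <- ncol(patterns[[1]]$X)
  XtViX <- matrix(0, p, p); XtViy <- numeric(p)
  for (pat in patterns) {
    nb <- nrow(pat$X)
    V <- diag(sds[resid_idx[pat$res_par]]^2, nb)
    for (v in seq_along(vp_defs))
      if (!is.null(pat$M[[v]])) V <- V + sds[v]^2 * pat$M[[v]]
    L <- chol(V)
    Xs <- backsolve(L, pat$X, transpose = TRUE)
    XtViX <- XtViX + crossprod(Xs) * length(pat$ys)
    for (y in pat$ys)
      XtViy <- XtViy + crossprod(Xs, backsolve(L, y, transpose = TRUE))[, 1]
  }
  list(beta = solve(XtViX, XtViy), cov = solve(XtViX))
}

#' REML linear mixed-effects variance-components model
#'
#' Fits the agreement model for dual-modality repeated perfusion
#' measurements: fixed effects of modality, scan sequence and their
#' interaction; random effects for participant, kidney within participant
#' and day within kidney and participant; independent Gaussian residuals.
#' Participant, day and residual SDs may differ between modalities; the
#' kidney SD is shared.  Estimation is restricted maximum likelihood:
#' fixed effects are profiled out by generalised least squares and the
#' variance parameters (log-SD scale) are optimised by Nelder-Mead from a
#' method-of-moments start plus scaled restarts, over the block-diagonal
#' (per participant) marginal covariance implied by the random structure.
#'
#' @param table Long-format `data.frame` with columns `participant`,
#'   `kidney`, `day`, `scan`, `modality` and the response.
#' @param value_col Name of the response column.  Default
#'   `"perfusion_ml_min_100ml"`.
#' @param terms Random-effect terms to include, a subset of
#'   `c("participant", "kidney", "day")`.
#' @param modality_specific Named logical: which of participant, day,
#'   kidney and residual get one SD per modality.  Defaults mirror the
#'   agreement model (participant, day and residual modality-specific;
#'   kidney shared).
#' @param fixed Optional fixed-effects formula (right-hand side only, on
#'   `modality` and `scan`); by default `~ modality * scan` with factors
#'   collapsing automatically when a column has a single level.
#' @return Object of class `vc_fit`: `sds` (named SD estimates), `fixed`
#'   (coefficients), `reml_neg2ll`, `converged`, `n`, plus internals used
#'   by [derive_agreement()].
#' @export
fit_mixed_model <- function(table, value_col = "perfusion_ml_min_100ml",
                            terms = c("participant", "kidney", "day"),
                            modality_specific = c(participant = TRUE,
                                                  kidney = FALSE,
                                                  day = TRUE,
                                                  residual = TRUE),
                            fixed = NULL) {
  need <- c("participant", "kidney", "day", "scan", "modality", value_col)
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "))
  if (length(unique(table$participant)) < 2L)
    stop("need at least 2 participants")
  tab <- table[order(table$participant, table$kidney, table$day,
                     table$scan, table$modality), , drop = FALSE]
  tab$modality <- as.character(tab$modality)
  mods <- sort(unique(tab$modality))
  y_all <- tab[[value_col]]

  # variance-parameter catalogue
  vp_defs <- list()
  for (t in terms) {
    spec <- isTRUE(modality_specific[t]) && length(mods) > 1L
    if (spec) for (m in mods) vp_defs <- c(vp_defs, list(list(term = t, modality = m)))
    else vp_defs <- c(vp_defs, list(list(term = t, modality = NA)))
  }
  res_spec <- isTRUE(modality_specific["residual"]) && length(mods) > 1L
  res_names <- if (res_spec) mods else "all"
  vp_names <- c(vapply(vp_defs, function(v)
    if (is.na(v$modality)) v$term else paste(v$term, v$modality, sep = ":"),
    character(1)),
    if (res_spec) paste("residual", mods, sep = ":") else "residual")
  n_rand <- length(vp_defs)
  n_par <- n_rand + length(res_names)
  resid_idx <- stats::setNames(n_rand + seq_along(res_names), res_names)

  # fixed-effects design
  if (is.null(fixed)) {
    parts <- character(0)
    if (length(mods) > 1L) parts <- c(parts, "modality")
    if (length(unique(tab$scan)) > 1L) parts <- c(parts, "factor(scan)")
    fixed <- if (length(parts) == 2L)
      stats::as.formula("~ modality * factor(scan)")
    else if (length(parts) == 1L) stats::as.formula(paste("~", parts))
    else ~1
  }
  mf <- stats::model.frame(fixed, tab)
  X_all <- stats::model.matrix(fixed, mf)
  xlev <- stats::.getXlevels(stats::terms(fixed), mf)

  # per-participant blocks, cached by design pattern
  split_idx <- split(seq_len(nrow(tab)), tab$participant)
  patterns <- list()
  for (idx in split_idx) {
    rows <- tab[idx, , drop = FALSE]
    key <- paste(rows$kidney, rows$day, rows$scan, rows$modality,
                 collapse = "|")
    if (is.null(patterns[[key]])) {
      res_par <- if (res_spec) rows$modality else rep("all", nrow(rows))
      patterns[[key]] <- list(X = X_all[idx, , drop = FALSE],
                              M = .block_rand_mats(rows, vp_defs),
                              res_par = res_par, ys = list())
    }
    patterns[[key]]$ys <- c(patterns[[key]]$ys, list(y_all[idx]))
  }

  # method-of-moments start: OLS residual spread split across levels
  ols_res <- stats::lm.fit(X_all, y_all)$residuals
  start <- numeric(n_par)
  for (v in seq_len(n_par)) {
    nm <- vp_names[v]
    m <- sub("^[a-z]+:", "", nm)
    r <- if (grepl(":", nm)) ols_res[tab$modality == m] else ols_res
    s <- stats::sd(r) / 2
    start[v] <- log(max(s, 1e-3))
  }
  obj <- function(ls) .reml_neg2ll(ls, patterns, vp_defs, resid_idx)

  # degenerate data (pure fixed effects): REML is improper, all SDs sit at
  # the zero boundary and the GLS solution reduces to OLS
  if (stats::sd(ols_res) < 1e-8 * max(1, stats::sd(y_all))) {
    sds <- stats::setNames(rep(0, n_par), vp_names)
    beta <- stats::setNames(stats::lm.fit(X_all, y_all)$coefficients,
                            colnames(X_all))
    cell_means <- stats::aggregate(y_all,
                                   by = list(modality = tab$modality, scan = tab$scan),
                                   FUN = mean)
    names(cell_means)[3] <- "mean"
    return(structure(list(sds = sds, fixed = beta, reml_neg2ll = -Inf,
                          converged = TRUE, n = nrow(tab), modalities = mods,
                          fixed_formula = fixed, xlevels = xlev,
                          cell_means = cell_means, start_value = Inf),
                     class = "vc_fit"))
  }

  starts <- list(start, rep(log(max(stats::sd(ols_res), 1e-3)), n_par))
  best <- NULL
  for (s0 in starts) {
    op <- stats::optim(s0, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    op <- stats::optim(op$par, obj, method = "BFGS",
                       control = list(maxit = 200, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  op <- best
  sds <- exp(op$par)
  sds[sds < 1e-6 * stats::sd(y_all)] <- 0    # boundary: pin vanishing SDs
  names(sds) <- vp_names
  sd_floor <- 1e-7 * max(stats::sd(y_all), 1)
  gls <- .reml_beta(log(pmax(sds, sd_floor)), patterns, vp_defs, resid_idx)
  beta <- stats::setNames(gls$beta, colnames(X_all))

  cell_means <- stats::aggregate(y_all,
                                 by = list(modality = tab$modality, scan = tab$scan),
                                 FUN = mean)
  names(cell_means)[3] <- "mean"
  structure(list(sds = sds, fixed = beta, reml_neg2ll = op$value,
                 converged = op$convergence == 0, n = nrow(tab),
                 modalities = mods, fixed_formula = fixed, xlevels = xlev,
                 cell_means = cell_means, start_value = obj(start)),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<REML variance components>\n  SDs:\n")
  for (nm in names(x$sds)) cat(sprintf("    %-16s %8.3f\n", nm, x$sds[nm]))
  cat("  fixed effects:\n")
  for (nm in names(x$fixed)) cat(sprintf("    %-24s %8.3f\n", nm, x$fixed[nm]))
  invisible(x)
}

# Predicted fixed-effect mean for a (modality, scan) cell.
.predict_cell <- function(fit, modality, scan) {
  nd <- data.frame(modality = modality, scan = scan)
  tt <- stats::terms(fit$fixed_formula)
  X <- stats::model.matrix(tt, stats::model.frame(tt, nd, xlev = fit$xlevels))
  as.numeric(X %*% fit$fixed)
}

#' Specify which two measurements are being compared
#'
#' A comparison names the two measurement conditions whose differences the
#' agreement statistics describe: each side has a modality and a scan
#' number (1-3; scans 1 and 2 fall on day 1, scan 3 on day 2).  `scan = NA`
#' on both sides means simultaneous measurements averaged over the scan
#' sequence (the cross-modality comparison).
#'
#' @param modality_a,modality_b Modality of each side.
#' @param scan_a,scan_b Scan number of each side, or `NA`.
#' @param name Optional label.
#' @return Object of class `comparison_spec` with the derived set of
#'   levels that differ between the sides (`"scan-within-day"`, `"day"`,
#'   `"modality"`).
#' @export
comparison_spec <- function(modality_a, modality_b, scan_a = NA, scan_b = NA,
                            name = NULL) {
  day_of <- function(s) if (is.na(s)) NA_integer_ else if (s == 3) 2L else 1L
  differ <- character(0)
  if (!identical(modality_a, modality_b)) differ <- c(differ, "modality")
  da <- day_of(scan_a); db <- day_of(scan_b)
  if (!is.na(da) && !is.na(db) && da != db) differ <- c(differ, "day")
  if (!identical(scan_a, scan_b) || identical(modality_a, modality_b))
    differ <- c(differ, "scan-within-day")
  if (length(differ) == 0L ||
      (identical(modality_a, modality_b) && identical(scan_a, scan_b)))
    stop("comparison must differ in at least one level")
  structure(list(modality_a = modality_a, modality_b = modality_b,
                 scan_a = scan_a, scan_b = scan_b, differ = unique(differ),
                 name = name %||% paste0(modality_a, scan_a, "-vs-",
                                         modality_b, scan_b)),
            class = "comparison_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Same-day repeatability comparison (scans 1 and 2, one modality)
#' @param modality Modality label.
#' @return A [comparison_spec()].
#' @export
comparison_repeatability <- function(modality)
  comparison_spec(modality, modality, 1, 2,
                  name = paste0(modality, " repeatability"))

#' Between-day reproducibility comparison (scans 1 and 3, one modality)
#' @param modality Modality label.
#' @return A [comparison_spec()].
#' @export
comparison_reproducibility <- function(modality)
  comparison_spec(modality, modality, 1, 3,
                  name = paste0(modality, " reproducibility"))

#' Cross-modality comparison of simultaneous measurements
#' @param modality_a,modality_b The two modalities.
#' @return A [comparison_spec()].
#' @export
comparison_cross_modality <- function(modality_a = "ASL", modality_b = "PET")
  comparison_spec(modality_a, modality_b, NA, NA,
                  name = paste0(modality_a, "-vs-", modality_b))

# SD lookup helper: modality-specific name if present, else shared.
.vc_sd <- function(sds, term, modality) {
  nm <- paste(term, modality, sep = ":")
  if (nm %in% names(sds)) unname(sds[nm])
  else if (term %in% names(sds)) unname(sds[term]) else 0
}

#' Limits of agreement and coefficient of variation from variance components
#'
#' Applies the summation rule for agreement statistics: the SD of the
#' difference between the two compared measurements is the square root of
#' the sum of the squared SDs of every random component that differs
#' between them, counted once per measurement with the
#' modality-appropriate value.  Residual variation always differs; the
#' day component differs when the measurements are on different days or
#' from different modalities (day effects are modality-specific); the
#' participant component differs only across modalities.  Then
#' `LoA = 1.96 SD` and `CoV = 100 (SD / sqrt(2)) / reference_mean`.
#'
#' @param fit A `vc_fit` from [fit_mixed_model()], or a
#'   [variance_components()] truth object (then `bias` requires a fit and
#'   is returned as `NA`).
#' @param comparison A [comparison_spec()].
#' @param reference_mean Reference perfusion for the CoV
#'   (mL/min/100 mL); defaults to the mean of the observed cell means of
#'   the cells entering the comparison (fits only).
#' @return List: `name`, `bias`, `sd_diff`, `loa`, `cov_percent`,
#'   `reference_mean`.
#' @export
derive_agreement <- function(fit, comparison, reference_mean = NULL) {
  stopifnot(inherits(comparison, "comparison_spec"))
  if (length(comparison$differ) == 0L) stop("empty difference set")
  if (inherits(fit, "variance_components")) {
    sds <- c(stats::setNames(fit$sd_participant,
                             paste("participant", names(fit$sd_participant), sep = ":")),
             kidney = fit$sd_kidney,
             stats::setNames(fit$sd_day, paste("day", names(fit$sd_day), sep = ":")),
             stats::setNames(fit$sd_residual,
                             paste("residual", names(fit$sd_residual), sep = ":")))
    is_fit <- FALSE
  } else if (inherits(fit, "vc_fit")) {
    sds <- fit$sds; is_fit <- TRUE
  } else stop("fit must be a vc_fit or variance_components object")

  side_var <- function(modality) {
    v <- .vc_sd(sds, "residual", modality)^2
    if (any(comparison$differ %in% c("day", "modality")))
      v <- v + .vc_sd(sds, "day", modality)^2
    if ("modality" %in% comparison$differ)
      v <- v + .vc_sd(sds, "participant", modality)^2
    v
  }
  sd_diff <- sqrt(side_var(comparison$modality_a) +
                    side_var(comparison$modality_b))
  loa <- 1.96 * sd_diff

  bias <- NA_real_
  scans_all <- 1:3
  sa <- if (is.na(comparison$scan_a)) scans_all else comparison$scan_a
  sb <- if (is.na(comparison$scan_b)) scans_all else comparison$scan_b
  if (is_fit) {
    pa <- mean(vapply(sa, function(s)
      .predict_cell(fit, comparison$modality_a, s), numeric(1)))
    pb <- mean(vapply(sb, function(s)
      .predict_cell(fit, comparison$modality_b, s), numeric(1)))
    bias <- pb - pa
    if (is.null(reference_mean)) {
      cm <- fit$cell_means
      pick <- (cm$modality == comparison$modality_a & cm$scan %in% sa) |
        (cm$modality == comparison$modality_b & cm$scan %in% sb)
      reference_mean <- mean(cm$mean[pick])
    }
  }
  cov <- if (is.null(reference_mean)) NA_real_
  else if (loa == 0) 0 else cov_from_loa(loa, reference_mean)
  list(name = comparison$name, bias = bias, sd_diff = sd_diff, loa = loa,
       cov_percent = cov, reference_mean = reference_mean)
}

#' Coefficient of variation from a limit of agreement
#'
#' Inverts the LoA summation rule's CoV convention: the SD entering the
#' CoV is the LoA-SD divided by `sqrt(2)` (one measurement's share of a
#' paired difference), expressed as a percentage of a reference mean.
#'
#' @param loa 95% limit of agreement, mL/min/100 mL, `> 0`.
#' @param reference_mean Reference perfusion, mL/min/100 mL, `> 0`.
#' @return CoV in percent: `100 * (loa / 1.96) / sqrt(2) / reference_mean`.
#' @examples
#' cov_from_loa(85.4, 283.5)   # 10.9 %
#' @export
cov_from_loa <- function(loa, reference_mean) {
  if (any(loa <= 0) || any(reference_mean <= 0))
    stop("loa and reference_mean must be positive")
  100 * (loa / 1.96) / sqrt(2) / reference_mean
}

#' Bland-Altman scatter plot
#'
#' @param a,b Paired measurements.
#' @param xlab,ylab,main Plot labels.
#' @return The [bland_altman()] summary, invisibly.
#' @export
plot_bland_altman <- function(a, b, xlab = "Mean of measurements",
                              ylab = "Difference (b - a)",
                              main = "Bland-Altman") {
  ba <- bland_altman(a, b)
  graphics::plot((a + b) / 2, b - a, pch = 19, xlab = xlab, ylab = ylab,
                 main = main)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}
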