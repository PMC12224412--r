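#' Canonical HRF parameters
#'
#' Constants of the canonical double-gamma hemodynamic response
#' function: a positive gamma peaking around 5-6 s minus a scaled-down
#' undershoot gamma around 16 s. Defaults are the conventional values
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot ratio 6, 32 s kernel).
#'
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_disp,undershoot_disp Gamma dispersions.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel length in seconds.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       ratio = 6, length_s = 32) {
  if (peak_delay <= 0 || undershoot_delay <= 0) {
    abort("HRF delays must be > 0.", class = "lexrsa_error_parameter")
  }
  if (length_s <= peak_delay) {
    abort("Kernel length must exceed the peak delay.", class = "lexrsa_error_parameter")
  }
  structure(list(
    peak_delay = peak_delay, undershoot_delay = undershoot_delay,
    peak_disp = peak_disp, undershoot_disp = undershoot_disp,
    ratio = ratio, length_s = length_s
  ), class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' Difference of two gamma densities (shape `delay/dispersion`, scale
#' `dispersion`) sampled on a regular grid, peak-normalized to 1.
#'
#' @param dt Sampling interval in seconds (e.g. the TR, or a finer
#'   microtime grid), `> 0`.
#' @param params [hrf_params()].
#' @return Numeric kernel sampled at `0, dt, 2*dt, ...` up to `length_s`;
#'   value 0 at `t = 0`.
#' @export
canonical_hrf <- function(dt, params = hrf_params()) {
  if (dt <= 0) abort("`dt` must be > 0.", class = "lexrsa_error_parameter")
  t <- seq(0, params$length_s, by = dt)
  h <- dgamma(t, shape = params$peak_delay / params$peak_disp, scale = params$peak_disp) -
    dgamma(t, shape = params$undershoot_delay / params$undershoot_disp,
      scale = params$undershoot_disp
    ) / params$ratio
  h / max(h)
}

#' Validate an event table
#'
#' @param events Data frame with columns `onset`, `duration`,
#'   `condition` and optionally `run`.
#' @param single_run Require all events to belong to one run.
#' @return Validated tibble (a `run` column of 1s is added if absent).
#' @export
validate_events <- function(events, single_run = FALSE) {
  events <- tibble::as_tibble(events)
  need <- c("onset", "duration", "condition")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    abort(paste0("Event table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  if (!"run" %in% names(events)) events$run <- 1L
  if (any(events$duration <= 0)) abort("Event durations must be > 0.", class = "lexrsa_error_schema")
  if (any(events$onset < 0)) abort("Event onsets must be >= 0.", class = "lexrsa_error_schema")
  bad_order <- events |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(ok = all(diff(.data$onset) > 0) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_order)) {
    abort("Onsets must be strictly increasing within each run.", class = "lexrsa_error_schema")
  }
  if (single_run && length(unique(events$run)) != 1L) {
    abort("Expected events for a single run.", class = "lexrsa_error_schema")
  }
  events
}

# HRF-convolved task regressors, one column per condition, sampled at
# scan onsets via a microtime grid (dt = tr/16).
task_regressors <- function(events, n_scans, tr, hrf = hrf_params(),
                            conditions = NULL, baseline_label = "baseline") {
  events <- validate_events(events, single_run = TRUE)
  if (is.null(conditions)) {
    conditions <- setdiff(unique(events$condition), baseline_label)
  }
  dt <- tr / 16
  n_fine <- ceiling(n_scans * tr / dt) + 1L
  kernel <- canonical_hrf(dt, hrf)
  scan_idx <- floor((seq_len(n_scans) - 1L) * tr / dt) + 1L
  x <- matrix(0, n_scans, length(conditions))
  colnames(x) <- conditions
  for (ci in seq_along(conditions)) {
    ev <- events[events$condition == conditions[ci], ]
    u <- numeric(n_fine)
    for (k in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset[k] / dt) + 1L
      i1 <- min(ceiling((ev$onset[k] + ev$duration[k]) / dt), n_fine)
      if (i0 <= n_fine) u[i0:i1] <- 1
    }
    conv_full <- stats::convolve(u, rev(kernel), type = "open") * dt
    x[, ci] <- conv_full[scan_idx]
  }
  x
}

# discrete cosine drift basis: k = 1..K columns for periods >= highpass_s
dct_basis <- function(n_scans, tr, highpass_s = 128) {
  k_max <- floor(2 * n_scans * tr / highpass_s)
  if (k_max < 1) {
    return(matrix(numeric(0), n_scans, 0))
  }
  t <- seq_len(n_scans) - 1L
  x <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * (2 * t + 1) / (2 * n_scans))
  }, numeric(n_scans))
  colnames(x) <- paste0("dct", seq_len(k_max))
  x
}

#' Build an event-related GLM design matrix
#'
#' One HRF-convolved task regressor per condition (pooling all its
#' repetitions within the run), plus an intercept and a discrete-cosine
#' drift basis implementing a high-pass filter with the given cutoff.
#' Hash-mark baseline trials (`condition == baseline_label`) are left
#' unmodeled: they form the implicit baseline against which condition
#' t-values are later contrasted.
#'
#' @param events Single-run event tibble.
#' @param n_scans Number of scans in the run.
#' @param tr Repetition time, seconds.
#' @param hrf [hrf_params()].
#' @param highpass_s High-pass cutoff in seconds (default 128); drift
#'   columns `floor(2 * n_scans * tr / highpass_s)` are added.
#' @param baseline_label Condition label excluded from modeling.
#' @return A list of class `design_matrix`: `matrix` (scans x
#'   regressors), `task` (task column names), `tr`.
#' @export
build_design <- function(events, n_scans, tr, hrf = hrf_params(),
                         highpass_s = 128, baseline_label = "baseline") {
  events <- validate_events(events, single_run = TRUE)
  if (max(events$onset) > n_scans * tr) {
    abort("Events extend beyond the scan window.", class = "lexrsa_error_schema")
  }
  task <- task_regressors(events, n_scans, tr, hrf, baseline_label = baseline_label)
  x <- cbind(task, intercept = 1, dct_basis(n_scans, tr, highpass_s))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ), class = "lexrsa_error_design")
  }
  structure(list(matrix = x, task = colnames(task), tr = tr), class = "design_matrix")
}

#' Fit an ordinary least-squares GLM to voxel time series
#'
#' @param series Scans-by-voxels numeric matrix.
#' @param design A [build_design()] object (or bare matrix).
#' @return A list of class `lexrsa_glm`: `betas` (regressors x voxels),
#'   `sigma2` (residual variance per voxel), `dof`, `xtx_inv`, `design`.
#' @export
fit_glm <- function(series, design) {
  x <- if (inherits(design, "design_matrix")) design$matrix else as.matrix(design)
  series <- as.matrix(series)
  if (nrow(series) != nrow(x)) abort("Series and design disagree on scan count.", class = "lexrsa_error_schema")
  if (nrow(x) <= ncol(x)) abort("Need more scans than regressors.", class = "lexrsa_error_design")
  qrx <- qr(x)
  rank <- qrx$rank
  if (rank < ncol(x)) {
    warn("Singular design: using the Moore-Penrose pseudo-inverse.")
    xtx_inv <- MASS_ginv(crossprod(x))
    betas <- xtx_inv %*% crossprod(x, series)
  } else {
    betas <- qr.coef(qrx, series)
    xtx_inv <- chol2inv(chol(crossprod(x)))
  }
  fitted <- x %*% betas
  res <- series - fitted
  dof <- nrow(x) - rank
  sigma2 <- colSums(res^2) / dof
  rownames(betas) <- colnames(x)
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  structure(list(
    betas = betas, sigma2 = sigma2, dof = dof, xtx_inv = xtx_inv,
    design = if (inherits(design, "design_matrix")) design else NULL
  ), class = "lexrsa_glm")
}

# minimal Moore-Penrose inverse via SVD (degenerate-design fallback)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' t-statistics of one condition against the implicit baseline
#'
#' `t = beta_c / sqrt(sigma2 * c' (X'X)^{-1} c)` with the contrast
#' vector selecting the single condition column; scans not covered by
#' any task regressor form the implicit baseline.
#'
#' @param fit A [fit_glm()] object.
#' @param condition Task regressor name.
#' @return Numeric vector of t-values, one per voxel. Voxels with zero
#'   residual variance yield `Inf`/`-Inf`/`NaN` with a warning.
#' @export
tmap <- function(fit, condition) {
  stopifnot(inherits(fit, "lexrsa_glm"))
  if (fit$dof < 1) abort("No residual degrees of freedom.", class = "lexrsa_error_design")
  rn <- rownames(fit$betas)
  if (!condition %in% rn) {
    abort(paste0("No regressor named `", condition, "`."), class = "lexrsa_error_parameter")
  }
  ci <- match(condition, rn)
  se2 <- fit$sigma2 * fit$xtx_inv[ci, ci]
  if (any(se2 == 0)) {
    warn("Zero residual variance in some voxels: infinite t-values produced.")
  }
  as.numeric(fit$betas[ci, ] / sqrt(se2))
}

#' Estimate a condition t-pattern matrix from one run
#'
#' Convenience wrapper chaining [build_design()], [fit_glm()] and
#' [tmap()]: returns one row of t-values per (non-baseline) condition.
#'
#' @inheritParams build_design
#' @param series Scans-by-voxels matrix for the run.
#' @return Condition-by-voxel matrix of t-values with condition rownames.
#' @export
glm_patterns <- function(series, events, tr, hrf = hrf_params(),
                         highpass_s = 128, baseline_label = "baseline") {
  series <- as.matrix(series)
  design <- build_design(events, n_scans = nrow(series), tr = tr, hrf = hrf,
    highpass_s = highpass_s, baseline_label = baseline_label
  )
  fit <- fit_glm(series, design)
  t_rows <- vapply(design$task, function(cn) tmap(fit, cn), numeric(ncol(series)))
  out <- t(t_rows)
  rownames(out) <- design$task
  out
}
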