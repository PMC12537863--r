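#' Canonical HRF parameters
#'
#' Parameters of the canonical double-gamma hemodynamic response function:
#' a positive gamma density peaking around 5 s minus a delayed undershoot
#' gamma scaled by `peak_to_undershoot_ratio`. Defaults are the standard
#' published values of the canonical HRF used throughout event-related
#' fMRI modelling.
#'
#' @param peak_delay_s Delay of the response peak (gamma shape x scale), seconds.
#' @param undershoot_delay_s Delay of the undershoot, seconds.
#' @param peak_dispersion_s Dispersion (gamma scale) of the peak, seconds.
#' @param undershoot_dispersion_s Dispersion of the undershoot, seconds.
#' @param peak_to_undershoot_ratio Amplitude ratio peak:undershoot.
#' @param kernel_length_s Length of the sampled kernel, seconds.
#' @param microtime_bins_per_tr Temporal oversampling of the design per TR.
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     peak_to_undershoot_ratio = 6, kernel_length_s = 32,
                     microtime_bins_per_tr = 16L) {
  for (nm in c("peak_delay_s", "undershoot_delay_s", "peak_dispersion_s",
               "undershoot_dispersion_s", "peak_to_undershoot_ratio",
               "kernel_length_s", "microtime_bins_per_tr")) {
    check_number(get(nm), nm, lower = .Machine$double.eps)
  }
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_to_undershoot_ratio = peak_to_undershoot_ratio,
                 kernel_length_s = kernel_length_s,
                 microtime_bins_per_tr = as.integer(microtime_bins_per_tr)),
            class = "hrf_spec")
}

#' Sample the canonical double-gamma HRF
#'
#' Evaluates the difference-of-gammas kernel on the microtime grid
#' (`tr_s / microtime_bins_per_tr` spacing) over `kernel_length_s` seconds,
#' normalized so its peak value is 1.
#'
#' @param tr_s Repetition time in seconds.
#' @param spec An [hrf_spec()].
#' @return Numeric vector of kernel values, attribute `dt_s` holding the
#'   microtime step.
#' @export
canonical_hrf <- function(tr_s, spec = hrf_spec()) {
  check_number(tr_s, "tr_s", lower = .Machine$double.eps)
  dt <- tr_s / spec$microtime_bins_per_tr
  t <- seq(0, spec$kernel_length_s, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion_s,
                     scale = spec$peak_dispersion_s) -
    stats::dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion_s,
                  scale = spec$undershoot_dispersion_s) /
      spec$peak_to_undershoot_ratio
  h <- h / max(h)
  attr(h, "dt_s") <- dt
  h
}

#' Event list for design-matrix construction
#'
#' @param onsets_s Event onsets in seconds (volume 0 is acquired at t = 0).
#' @param durations_s Event durations in seconds; 0 yields stick (impulse)
#'   regressors, positive values yield boxcars. Scalar or per-event.
#' @param modulator Optional per-event parametric modulator values.
#' @param name Regressor name stem.
#' @return A list of class `event_list`.
#' @export
event_list <- function(onsets_s, durations_s = 0, modulator = NULL,
                       name = "events") {
  if (length(onsets_s) == 0L) stopf("event list '%s' is empty", name)
  if (any(!is.finite(onsets_s)) || any(onsets_s < 0))
    stopf("event onsets must be finite and non-negative")
  durations_s <- rep_len(durations_s, length(onsets_s))
  if (any(durations_s < 0)) stopf("event durations must be non-negative")
  if (!is.null(modulator) && length(modulator) != length(onsets_s))
    stopf("modulator length (%d) does not match event count (%d)",
          length(modulator), length(onsets_s))
  structure(list(onsets_s = as.numeric(onsets_s),
                 durations_s = as.numeric(durations_s),
                 modulator = modulator, name = name),
            class = "event_list")
}

# place an impulse/boxcar train with given heights on the microtime grid
# and convolve with the HRF kernel; returns values at volume times
convolve_train <- function(onsets_s, durations_s, heights, n_scans, tr_s,
                           hrf) {
  dt <- attr(hrf, "dt_s")
  bins_per_tr <- round(tr_s / dt)
  n_mt <- n_scans * bins_per_tr
  train <- numeric(n_mt)
  idx0 <- round(onsets_s / dt)  # 0-based microtime bin of onset
  nbin <- pmax(1L, round(durations_s / dt))
  for (i in seq_along(idx0)) {
    j <- (idx0[i] + 1L):min(idx0[i] + nbin[i], n_mt)
    train[j] <- train[j] + heights[i]
  }
  conv <- stats::convolve(train, rev(hrf), type = "open")[seq_len(n_mt)]
  conv[seq(1L, n_mt, by = bins_per_tr)]
}

#' Build HRF-convolved regressor columns from an event list
#'
#' Produces the unmodulated column (unit event heights) and, when the event
#' list carries a parametric modulator, a second column whose event heights
#' are the (optionally mean-centered) modulator values. Events are snapped
#' to the nearest microtime bin before convolution; volume i is sampled at
#' i * `tr_s` (0-based).
#'
#' @param events An [event_list()].
#' @param n_scans Number of volumes.
#' @param tr_s Repetition time in seconds.
#' @param hrf Kernel from [canonical_hrf()]; built from `tr_s` if `NULL`.
#' @param mean_center_modulator Center the modulator before convolution
#'   (default `TRUE`), so the parametric column is orthogonal to constant
#'   event height in the modulator domain.
#' @return Matrix with one or two named columns.
#' @export
build_regressor <- function(events, n_scans, tr_s, hrf = NULL,
                            mean_center_modulator = TRUE) {
  stopifnot(inherits(events, "event_list"))
  check_number(n_scans, "n_scans", lower = 1)
  if (any(events$onsets_s > n_scans * tr_s))
    stopf("event onsets exceed the scan span (%g s)", n_scans * tr_s)
  if (is.null(hrf)) hrf <- canonical_hrf(tr_s)
  unmod <- convolve_train(events$onsets_s, events$durations_s,
                          rep(1, length(events$onsets_s)), n_scans, tr_s, hrf)
  out <- cbind(unmod)
  colnames(out) <- events$name
  if (!is.null(events$modulator)) {
    m <- events$modulator
    if (mean_center_modulator) m <- m - mean(m)
    pmod <- convolve_train(events$onsets_s, events$durations_s, m,
                           n_scans, tr_s, hrf)
    out <- cbind(out, pmod)
    colnames(out) <- c(events$name, paste0(events$name, "_pmod"))
  }
  out
}

#' Discrete-cosine high-pass basis
#'
#' Orthonormal DCT columns spanning frequencies below `1/cutoff_s`,
#' including the constant; regressing them out implements the standard
#' fMRI high-pass filter (default cutoff 128 s).
#'
#' @param n_scans Number of volumes.
#' @param tr_s Repetition time, seconds.
#' @param cutoff_s High-pass cutoff period, seconds.
#' @return `n_scans` x K orthonormal matrix; column 1 is the constant.
#' @export
dct_highpass_basis <- function(n_scans, tr_s, cutoff_s = 128) {
  check_number(n_scans, "n_scans", lower = 1)
  n_scans <- as.integer(n_scans)
  if (n_scans * tr_s <= cutoff_s) {
    warning("run shorter than the high-pass cutoff; constant-only basis")
    K <- 1L
  } else {
    K <- floor(2 * n_scans * tr_s / cutoff_s) + 1L
  }
  i <- seq_len(n_scans) - 1L
  C <- matrix(0, n_scans, K)
  C[, 1] <- 1 / sqrt(n_scans)
  for (j in seq_len(K - 1L)) {
    C[, j + 1L] <- sqrt(2 / n_scans) * cos(pi * (2 * i + 1) * j / (2 * n_scans))
  }
  colnames(C) <- paste0("dct", seq_len(K) - 1L)
  C
}

#' Expand motion parameters into the 18-column nuisance set
#'
#' Six realignment parameters plus their first temporal derivatives
#' (backward differences, first row 0) and the squared derivatives.
#'
#' @param motion `n_scans` x 6 numeric matrix.
#' @return `n_scans` x 18 matrix.
#' @export
motion_nuisance <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion matrix must have 6 columns")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, d^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     paste0("dmot2_", 1:6))
  out
}

#' Fit a mass-univariate ordinary-least-squares GLM
#'
#' @param Y `n_scans` x `n_voxels` data matrix (a vector is treated as one
#'   voxel).
#' @param X Design matrix with named columns; must be full column rank.
#' @return List with `coefficients` (p x n_voxels), `residual_variance`
#'   (per voxel, n - p denominator), `df_residual`, and `fitted`.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X))
    stopf("Y has %d rows but X has %d", nrow(Y), nrow(X))
  if (anyNA(Y) || anyNA(X)) stopf("missing values in Y or X")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, Y)
  fitted <- X %*% beta
  res <- Y - fitted
  dfres <- nrow(X) - ncol(X)
  list(coefficients = beta,
       residual_variance = colSums(res^2) / dfres,
       df_residual = dfres,
       fitted = fitted)
}

#' Assemble a design matrix from task, nuisance, and high-pass blocks
#'
#' Binds the blocks column-wise and appends a single explicit intercept.
#' The high-pass basis' own constant column is dropped first — keeping
#' both would make the design rank deficient.
#'
#' @param task Task/parametric regressor columns.
#' @param nuisance Optional nuisance columns (e.g. [motion_nuisance()]).
#' @param highpass Optional basis from [dct_highpass_basis()].
#' @return The combined design matrix.
#' @export
assemble_design <- function(task, nuisance = NULL, highpass = NULL) {
  X <- task
  if (!is.null(nuisance)) X <- cbind(X, nuisance)
  if (!is.null(highpass)) X <- cbind(X, highpass[, -1, drop = FALSE])
  X <- cbind(X, intercept = 1)
  X
}
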