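#' Subject scan container
#'
#' One scan's ROI time series plus its frame-to-frame motion trace and
#' per-volume keep mask. The mask starts all-TRUE; censoring operations only
#' ever clear entries.
#'
#' @param scan_id Scan label.
#' @param timeseries ROI x volume numeric matrix.
#' @param translation_delta Per-volume frame-to-frame translation (mm).
#' @param rotation_delta Per-volume frame-to-frame rotation (degrees).
#' @param tr_seconds Repetition time (s).
#' @param keep_mask Optional initial logical mask (defaults to all TRUE).
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(scan_id, timeseries, translation_delta,
                         rotation_delta, tr_seconds,
                         keep_mask = rep(TRUE, ncol(timeseries))) {
  timeseries <- as.matrix(timeseries)
  nv <- ncol(timeseries)
  if (length(translation_delta) != nv || length(rotation_delta) != nv)
    stop("motion trace length must match the volume count")
  if (length(keep_mask) != nv) stop("keep_mask length must match the volume count")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(scan_id = scan_id, timeseries = timeseries,
                 translation_delta = translation_delta,
                 rotation_delta = rotation_delta,
                 tr_seconds = tr_seconds,
                 keep_mask = as.logical(keep_mask)),
            class = "subject_scan")
}

#' Retained volumes of a scan
#' @param scan A [subject_scan()].
#' @return Integer count of volumes still in the keep mask.
#' @export
retained_volumes <- function(scan) sum(scan$keep_mask)

#' Censor high-motion volumes
#'
#' A volume whose frame-to-frame translation exceeds `trans_thresh_mm` or
#' whose rotation exceeds `rot_thresh_deg` is removed from the keep mask,
#' together with the immediately preceding volume (the frame during which
#' the movement began). The first volume has no predecessor.
#'
#' @param scan A [subject_scan()].
#' @param trans_thresh_mm Translation threshold in mm.
#' @param rot_thresh_deg Rotation threshold in degrees.
#' @return The scan with an updated `keep_mask`.
#' @export
censor_motion <- function(scan, trans_thresh_mm = 1.0, rot_thresh_deg = 1.5) {
  stopifnot(inherits(scan, "subject_scan"))
  if (trans_thresh_mm <= 0 || rot_thresh_deg <= 0) stop("thresholds must be > 0")
  bad <- scan$translation_delta > trans_thresh_mm |
    scan$rotation_delta > rot_thresh_deg
  drop <- bad
  if (length(bad) > 1) drop[-length(bad)] <- drop[-length(bad)] | bad[-1]
  scan$keep_mask <- scan$keep_mask & !drop
  scan
}

#' Censor volumes by robust signal deviation
#'
#' A volume is removed when more than `voxel_frac` of ROI signals deviate
#' from their own time-series median by more than `mad_k` times the median
#' absolute deviation (scaled MAD, consistent with a normal SD). The
#' comparison is strict on both sides: exactly 10% deviating keeps the
#' volume. Constant series (MAD 0) never count as deviating.
#'
#' @param scan A [subject_scan()].
#' @param voxel_frac Fraction of ROI signals that must deviate, in (0,1).
#' @param mad_k Deviation multiplier.
#' @return The scan with an updated `keep_mask`.
#' @export
censor_mad <- function(scan, voxel_frac = 0.10, mad_k = 3.0) {
  stopifnot(inherits(scan, "subject_scan"))
  if (voxel_frac <= 0 || voxel_frac >= 1) stop("voxel_frac must be in (0,1)")
  ts <- scan$timeseries
  med <- apply(ts, 1, stats::median)
  madv <- apply(ts, 1, stats::mad)
  dev <- abs(ts - med) > mad_k * madv & madv > 0
  frac <- colMeans(dev)
  scan$keep_mask <- scan$keep_mask & !(frac > voxel_frac)
  scan
}

#' Band-pass filter ROI time series
#'
#' Order-2 Butterworth band-pass (default 0.009-0.08 Hz) applied forward and
#' backward (zero phase) on the full volume grid; censored volumes are
#' linearly interpolated before filtering so spikes do not ring into retained
#' data, then re-masked afterwards.
#'
#' @param scan A [subject_scan()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @return The scan with filtered `timeseries` (mask unchanged).
#' @export
bandpass_filter <- function(scan, low_hz = 0.009, high_hz = 0.08) {
  stopifnot(inherits(scan, "subject_scan"))
  fs <- 1 / scan$tr_seconds
  ny <- fs / 2
  hi <- min(high_hz, 0.99 * ny)
  bf <- signal::butter(2, c(low_hz, hi) / ny, type = "pass")
  ts <- scan$timeseries
  idx <- seq_len(ncol(ts))
  keep <- scan$keep_mask
  out <- t(apply(ts, 1, function(y) {
    if (!all(keep) && sum(keep) >= 2)
      y[!keep] <- stats::approx(idx[keep], y[keep], xout = idx[!keep],
                                rule = 2)$y
    as.numeric(signal::filtfilt(bf, y))
  }))
  dimnames(out) <- dimnames(ts)
  scan$timeseries <- out
  scan
}

#' Nuisance regression on retained volumes
#'
#' Ordinary least squares of each ROI series on the supplied regressor
#' matrix, fit over retained volumes only; returns per-ROI residuals for
#' those volumes.
#'
#' @param scan A [subject_scan()].
#' @param regressors Volume x k numeric matrix including an intercept column;
#'   defaults to intercept plus the motion trace, its first difference and
#'   quadratic.
#' @return The scan with `timeseries` reduced to the retained volumes and
#'   replaced by residuals (`keep_mask` becomes all TRUE over those volumes).
#' @export
nuisance_regress <- function(scan, regressors = default_regressors(scan)) {
  stopifnot(inherits(scan, "subject_scan"))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != ncol(scan$timeseries))
    stop("regressor rows must match the volume count")
  keep <- scan$keep_mask
  x <- regressors[keep, , drop = FALSE]
  if (qr(x)$rank < ncol(x)) stop("rank-deficient regressor matrix")
  y <- t(scan$timeseries[, keep, drop = FALSE])
  res <- stats::lm.fit(x, y)$residuals
  scan$timeseries <- t(as.matrix(res))
  scan$translation_delta <- scan$translation_delta[keep]
  scan$rotation_delta <- scan$rotation_delta[keep]
  scan$keep_mask <- rep(TRUE, sum(keep))
  scan
}

#' @rdname nuisance_regress
#' @export
default_regressors <- function(scan) {
  nv <- ncol(scan$timeseries)
  tr <- scan$translation_delta
  ro <- scan$rotation_delta
  cbind(intercept = 1,
        trend = seq_len(nv) - (nv + 1) / 2,
        trans = tr, rot = ro,
        dtrans = c(0, diff(tr)), drot = c(0, diff(ro)),
        trans2 = tr^2, rot2 = ro^2)
}

#' Scan inclusion decision
#'
#' A scan is included when its retained data span at least `min_minutes`
#' minutes: `retained_volumes * tr_seconds >= min_minutes * 60`.
#'
#' @param scan A [subject_scan()].
#' @param min_minutes Minimum retained duration in minutes.
#' @return Logical: include the scan?
#' @export
check_inclusion <- function(scan, min_minutes = 4.0) {
  stopifnot(inherits(scan, "subject_scan"))
  retained_volumes(scan) * scan$tr_seconds >= min_minutes * 60
}

#' Full QC chain for one scan
#'
#' Motion censoring, MAD-based censoring, optional band-pass, nuisance
#' regression, then the inclusion decision.
#'
#' @param scan A [subject_scan()].
#' @param trans_thresh_mm,rot_thresh_deg,voxel_frac,mad_k,min_minutes QC
#'   parameters, see the individual operations.
#' @param bandpass Apply the Butterworth band-pass before regression?
#' @return List with the processed `scan` and a logical `include`.
#' @export
qc_scan <- function(scan, trans_thresh_mm = 1.0, rot_thresh_deg = 1.5,
                    voxel_frac = 0.10, mad_k = 3.0, min_minutes = 4.0,
                    bandpass = TRUE) {
  scan <- censor_motion(scan, trans_thresh_mm, rot_thresh_deg)
  scan <- censor_mad(scan, voxel_frac, mad_k)
  include <- check_inclusion(scan, min_minutes)
  if (include) {
    if (bandpass) scan <- bandpass_filter(scan)
    scan <- nuisance_regress(scan)
  }
  list(scan = scan, include = include)
}
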