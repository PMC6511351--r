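#' Drop initial volumes of a BOLD run
#'
#' Removes the first `n_discard` volumes (scanner equilibration period);
#' affine and TR are unchanged. The reference acquisition records 240
#' volumes of which the first four are discarded.
#'
#' @param run A [bold4d()] object.
#' @param n_discard Number of leading volumes to drop.
#' @return The shortened `bold4d`.
#' @export
discard_initial_volumes <- function(run, n_discard = 4) {
  stopifnot(inherits(run, "bold4d"), n_discard >= 0)
  n_t <- dim(run$data)[4]
  if (n_discard >= n_t)
    stop("cannot discard ", n_discard, " volumes from a run of ", n_t)
  if (n_discard == 0) return(run)
  bold4d(run$data[, , , (n_discard + 1):n_t, drop = FALSE],
         run$affine, run$tr)
}

#' Motion quality control
#'
#' Flags a run for exclusion when any translation exceeds
#' `max_translation_mm` or any rotation exceeds `max_rotation_deg` in
#' absolute value ("over 2 mm or 2 degrees", read as strictly greater, so
#' a value of exactly 2 passes). Columns are compared in their native
#' units; rotations are not converted to arc displacement.
#'
#' @param trace Motion table: 6 columns `tx, ty, tz` (mm) and
#'   `rx, ry, rz` (degrees), one row per volume.
#' @param max_translation_mm,max_rotation_deg Exclusion thresholds.
#' @return List with `pass` (logical), `offending` (volume indices that
#'   exceed a threshold), `max_translation` and `max_rotation`.
#' @examples
#' tr <- as.data.frame(matrix(0, 10, 6))
#' names(tr) <- c("tx", "ty", "tz", "rx", "ry", "rz")
#' motion_qc(tr)$pass
#' @export
motion_qc <- function(trace, max_translation_mm = 2, max_rotation_deg = 2) {
  m <- as.matrix(trace)
  if (nrow(m) < 1) stop("motion trace is empty")
  if (ncol(m) != 6)
    stop("motion trace must have 6 columns (3 translations, 3 rotations), ",
         "got ", ncol(m))
  trans <- abs(m[, 1:3, drop = FALSE])
  rot <- abs(m[, 4:6, drop = FALSE])
  bad <- apply(trans, 1, max) > max_translation_mm |
    apply(rot, 1, max) > max_rotation_deg
  list(pass = !any(bad),
       offending = which(bad),
       max_translation = max(trans),
       max_rotation = max(rot))
}

#' Temporal band-pass filter
#'
#' Retains fluctuations between `low_hz` and `high_hz` (defaults
#' 0.01--0.08 Hz, the conventional resting-state band) in every voxel or
#' ROI time series. The default realization is zero-phase and exactly
#' linear: slow components below `low_hz` are first removed by projecting
#' out a discrete cosine (DCT-II) basis of sub-band frequencies — the
#' half-bin frequency resolution of the DCT suppresses drift that is not
#' aligned with a DFT bin and would otherwise leak through a hard
#' frequency cut — then an ideal FFT-domain filter zeroes every frequency
#' bin outside the band (the DC component is always removed). A
#' zero-phase 4th-order Butterworth (`method = "butterworth"`,
#' forward-backward via [signal::filtfilt()]) is available for smoother
#' roll-off.
#'
#' @param x A [bold4d()], a `roi_timeseries`, a numeric matrix with time
#'   along columns, or a numeric vector.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 1/(2 tr)`.
#' @param tr Sampling interval (seconds); taken from `x` when it carries
#'   one.
#' @param method `"fft"` (ideal filter) or `"butterworth"`.
#' @return The filtered object, same class as the input.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.08, tr = NULL,
                     method = c("fft", "butterworth")) {
  method <- match.arg(method)
  if (inherits(x, "bold4d")) {
    d <- dim(x$data)
    m <- matrix(x$data, prod(d[1:3]), d[4])
    out <- bandpass_core(m, low_hz, high_hz, x$tr, method)
    return(bold4d(array(out, d), x$affine, x$tr))
  }
  if (inherits(x, "roi_timeseries")) {
    out <- bandpass_core(x$matrix, low_hz, high_hz, x$tr, method)
    return(roi_timeseries(out, x$roi_ids, x$tr))
  }
  if (is.null(tr)) stop("`tr` is required for plain numeric input")
  if (is.matrix(x)) return(bandpass_core(x, low_hz, high_hz, tr, method))
  drop(bandpass_core(matrix(x, 1), low_hz, high_hz, tr, method))
}

# x: series x time matrix
bandpass_core <- function(x, low_hz, high_hz, tr, method) {
  n_t <- ncol(x)
  if (n_t < 16) stop("need at least 16 time points to band-pass filter")
  nyquist <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist))
    stop(sprintf(
      "invalid band [%g, %g] Hz: need 0 <= low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyquist))
  if (method == "fft") {
    # 1. project out the sub-band DCT-II subspace (frequencies k/(2 n tr)
    #    below low_hz, k = 0 being the mean): removes slow drift at
    #    half-bin resolution, where a hard DFT cut alone leaks badly
    kmax <- floor(2 * n_t * tr * low_hz - 1e-9)
    if (kmax >= 0) {
      B <- vapply(0:kmax,
                  function(k) cos(pi * (2 * seq_len(n_t) - 1) * k / (2 * n_t)),
                  numeric(n_t))
      coef <- (x %*% B) / rep(colSums(B^2), each = nrow(x))
      x <- x - tcrossprod(coef, B)
    }
    # 2. ideal filter: zero every DFT bin outside [low_hz, high_hz]
    freq <- (seq_len(n_t) - 1) / (n_t * tr)
    freq <- pmin(freq, 1 / tr - freq)           # fold to [0, Nyquist]
    keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
    xf <- mvfft(t(x))
    xf[!keep, ] <- 0
    t(Re(mvfft(xf, inverse = TRUE))) / n_t
  } else {
    bf <- signal::butter(4, c(low_hz, high_hz) / nyquist, type = "pass")
    t(apply(x, 1, function(s) signal::filtfilt(bf, s - mean(s))))
  }
}

#' Spatial Gaussian smoothing
#'
#' Isotropic Gaussian convolution of a 3D volume with kernel width given
#' as full width at half maximum: `sigma = fwhm / (2 sqrt(2 ln 2))`
#' (about `fwhm / 2.3548`). Implemented as separable 1D convolutions with
#' nearest-edge replication at the boundary; the discrete kernel is
#' normalized to unit sum, so the total intensity of an interior point
#' source is conserved. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array, or a `gm_map`/`bold4d` (each volume of
#'   a 4D run is smoothed independently).
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @return Smoothed object of the same class/shape.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  if (inherits(volume, "gm_map")) {
    volume$data <- smooth_gaussian(volume$data, fwhm_mm, voxel_size_mm)
    return(volume)
  }
  if (inherits(volume, "bold4d")) {
    d <- dim(volume$data)
    for (t in seq_len(d[4]))
      volume$data[, , , t] <- smooth_gaussian(volume$data[, , , t],
                                              fwhm_mm, voxel_size_mm)
    return(volume)
  }
  stopifnot(is.array(volume), length(dim(volume)) == 3, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  radius <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(seq(-radius, radius))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  out <- volume
  for (axis in 1:3) out <- conv_axis_replicate(out, w, axis)
  out
}

#' @rdname smooth_gaussian
#' @export
fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

# 1D convolution along one axis of a 3D array, nearest-edge replication.
conv_axis_replicate <- function(arr, w, axis) {
  d <- dim(arr)
  n <- d[axis]
  radius <- (length(w) - 1L) / 2L
  out <- array(0, d)
  for (j in -radius:radius) {
    idx <- pmin(pmax(seq_len(n) + j, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + w[j + radius + 1L] * shifted
  }
  out
}

#' Preprocess one BOLD run
#'
#' Applies the standard stage order: discard initial volumes, motion QC
#' (an excluded run is returned with `qc$pass = FALSE` and no further
#' processing), temporal band-pass, then spatial smoothing.
#'
#' @param run A [bold4d()].
#' @param motion Motion trace matching the *undiscarded* run.
#' @param n_discard Leading volumes to drop.
#' @param low_hz,high_hz Band edges (Hz).
#' @param fwhm_mm Smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param voxel_size_mm Voxel size (mm).
#' @param max_translation_mm,max_rotation_deg Motion exclusion thresholds.
#' @param method Filter realization, see [bandpass()].
#' @return List with `run` (preprocessed `bold4d`, or `NULL` if excluded)
#'   and `qc` (the [motion_qc()] result).
#' @export
preprocess_run <- function(run, motion, n_discard = 4,
                           low_hz = 0.01, high_hz = 0.08,
                           fwhm_mm = 6, voxel_size_mm = 4,
                           max_translation_mm = 2, max_rotation_deg = 2,
                           method = "fft") {
  qc <- motion_qc(motion, max_translation_mm, max_rotation_deg)
  if (!qc$pass) return(list(run = NULL, qc = qc))
  run <- discard_initial_volumes(run, n_discard)
  run <- bandpass(run, low_hz, high_hz, method = method)
  if (fwhm_mm > 0) run <- smooth_gaussian(run, fwhm_mm, voxel_size_mm)
  list(run = run, qc = qc)
}
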