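# Smoothness metrics: velocity ratio, velocity-peak count, acceleration
# zero-crossings, log dimensionless jerk, spectral arc length.

#' Velocity-peak detection parameters
#'
#' @param delta Amplitude threshold in mm/s: a peak must exceed the preceding
#'   local minimum by more than `delta`. Default 20 mm/s.
#' @param tau Refractory interval in seconds: accepted peaks must be at least
#'   `tau` apart. Default 0.150 s.
#' @return A `peak_params` list.
#' @export
peak_params <- function(delta = 20, tau = 0.150) {
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  structure(list(delta = delta, tau = tau), class = "peak_params")
}

#' Spectral arc-length parameters
#'
#' @param omega_c Spectral cutoff in rad/s; default `40 * pi` (20 Hz), the
#'   band relevant to voluntary human movement.
#' @param pad_level Zero-padding exponent: the FFT length is
#'   `2^(ceiling(log2(n)) + pad_level)`. Default 4.
#' @param amp_threshold Normalized-magnitude threshold for the adaptive
#'   cutoff. Default 0.05.
#' @param resample_rate Rate (Hz) used to resample non-uniformly sampled
#'   profiles before the FFT; `NULL` (default) uses the profile's median rate.
#' @return A `sparc_params` list.
#' @export
sparc_params <- function(omega_c = 40 * pi, pad_level = 4L, amp_threshold = 0.05,
                         resample_rate = NULL) {
  if (omega_c <= 0) stop("omega_c must be positive", call. = FALSE)
  if (amp_threshold <= 0 || amp_threshold >= 1) {
    stop("amp_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(list(omega_c = omega_c, pad_level = as.integer(pad_level),
                 amp_threshold = amp_threshold, resample_rate = resample_rate),
            class = "sparc_params")
}

#' Ratio of mean to peak velocity
#'
#' MV/PV in (0, 1]: how evenly speed is distributed over the segment.
#' 1 means constant speed; lower values indicate a speed burst followed by
#' slower corrective phases.
#'
#' @inheritParams mean_velocity
#' @return Dimensionless ratio.
#' @export
velocity_ratio <- function(profile) {
  pv <- peak_velocity(profile)
  if (pv == 0) stop("undefined ratio: all-zero speed profile", call. = FALSE)
  mean_velocity(profile) / pv
}

# collapse runs of equal consecutive values to their first sample
.collapse_plateaus <- function(t, v) {
  keep <- c(TRUE, diff(v) != 0)
  list(t = t[keep], v = v[keep])
}

#' Count velocity peaks
#'
#' Counts local maxima of the speed profile that pass an amplitude and a
#' refractory criterion, scanning left to right. A candidate at time t_i is
#' accepted iff (1) it is a strict local maximum (plateaus are collapsed to
#' their first sample), (2) it exceeds the most recent preceding local
#' minimum (or the segment start) by more than `delta`, and (3) it is at
#' least `tau` after the previously accepted peak. A candidate rejected by
#' the refractory rule does not reset the refractory clock. The count is a
#' proxy for the number of submovements.
#'
#' @param profile Speed profile as a [scalar_profile()].
#' @param params [peak_params()].
#' @return Integer count.
#' @export
count_velocity_peaks <- function(profile, params = peak_params()) {
  v <- .profile_values(profile)
  tt <- .profile_times(profile)
  if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  cp <- .collapse_plateaus(tt, v)
  t <- cp$t; y <- cp$v
  m <- length(y)
  if (m < 3L) return(0L)
  interior <- 2:(m - 1L)
  is_max <- y[interior - 1L] < y[interior] & y[interior] > y[interior + 1L]
  is_min <- y[interior - 1L] > y[interior] & y[interior] < y[interior + 1L]
  max_idx <- interior[is_max]
  min_idx <- c(1L, interior[is_min])  # segment start acts as the initial minimum
  count <- 0L
  t_last <- -Inf
  for (i in max_idx) {
    prev_min <- max(min_idx[min_idx < i])
    if (y[i] - y[prev_min] > params$delta && t[i] - t_last >= params$tau) {
      count <- count + 1L
      t_last <- t[i]
    }
  }
  count
}

#' Zero-crossings of an acceleration signal
#'
#' Counts sign changes of a signed acceleration series (tangential
#' acceleration of the hand path, or angular acceleration of a joint).
#' Exact-zero samples are skipped so that a sign change passing through
#' zero counts once and a touch-without-crossing counts zero. More
#' crossings indicate more corrective submovements.
#'
#' @param accel Signed acceleration as a [scalar_profile()] or numeric vector.
#' @return Integer count.
#' @export
zero_crossings_accel <- function(accel) {
  a <- .profile_values(accel)
  if (!length(a)) stop("empty acceleration signal", call. = FALSE)
  a <- a[a != 0]
  if (length(a) < 2L) return(0L)
  sum(a[-length(a)] * a[-1L] < 0)
}

#' Log dimensionless jerk
#'
#' Integrated squared jerk magnitude over the segment, normalized by
#' movement duration and path length to a dimensionless quantity, with a
#' negative natural log applied:
#' `-ln( (MT^5 / PL^2) * integral ||j(t)||^2 dt )`.
#' Jerk is the magnitude of the third time-derivative of 3D position; the
#' integral uses the trapezoidal rule. More negative values mean less
#' smooth movement; an ideal minimum-jerk reach gives `-ln(720)`.
#'
#' @param path End-effector [path3d()] (at least 4 samples).
#' @param seg Optional segment (`t0`/`t1` and row `start`/`end`); defaults
#'   to the whole path.
#' @return Dimensionless value.
#' @export
log_dimensionless_jerk <- function(path, seg = NULL) {
  if (!inherits(path, "path3d")) stop("path must be a path3d", call. = FALSE)
  if (!is.null(seg)) {
    idx <- which(path$times >= seg$t0 & path$times <= seg$t1)
    if (length(idx) < 4L) stop("segment overlaps fewer than 4 samples", call. = FALSE)
    path <- path3d(path$times[idx], path$points[idx, , drop = FALSE])
    mt <- movement_time(seg)
  } else {
    mt <- diff(range(path$times))
  }
  if (length(path$times) < 4L) stop("need at least 4 samples", call. = FALSE)
  pl <- path_length(path)
  if (pl <= 0) stop("zero path length: LDJ undefined", call. = FALSE)
  if (mt <= 0) stop("zero movement duration: LDJ undefined", call. = FALSE)
  jerk <- differentiate(path, 3L)
  j2 <- rowSums(jerk$points^2)
  -log(mt^5 / pl^2 * .trapz(path$times, j2))
}

# shared spectral machinery: normalized magnitude spectrum up to the
# adaptive cutoff. Returns list(f, v) on the selected band.
.sparc_band <- function(freq, mag, fc, amp_threshold) {
  v0 <- mag[1L]
  if (v0 == 0) stop("V(0) = 0: SPARC undefined for a zero-mean signal", call. = FALSE)
  vhat <- mag / v0
  sel <- which(freq <= fc)
  f_s <- freq[sel]; v_s <- vhat[sel]
  above <- which(v_s >= amp_threshold)
  keep <- above[1L]:above[length(above)]
  list(f = f_s[keep], v = v_s[keep])
}

.arc_length_spectrum <- function(f, v) {
  if (length(f) < 2L) stop("degenerate spectrum band for SPARC", call. = FALSE)
  span <- f[length(f)] - f[1L]
  -sum(sqrt((diff(f) / span)^2 + diff(v)^2))
}

#' Spectral arc length (SPARC)
#'
#' Negative arc length of the normalized Fourier magnitude spectrum of the
#' speed profile, `V_hat(w) = V(w)/V(0)`, over the frequency band up to an
#' adaptive cutoff: the largest frequency not exceeding `omega_c` beyond
#' which the normalized magnitude stays below `amp_threshold`. The spectrum
#' comes from a zero-padded FFT; arc length is measured on the normalized
#' frequency scale. Values closer to -1 indicate smoother movement.
#' Non-uniformly sampled profiles (interval jitter above 1% of the median)
#' are linearly resampled first.
#'
#' @param profile Speed profile as a [scalar_profile()] (at least 8 samples).
#' @param params [sparc_params()].
#' @return Dimensionless value, always <= -1.
#' @export
sparc <- function(profile, params = sparc_params()) {
  if (!inherits(profile, "scalar_profile")) {
    stop("profile must be a scalar_profile", call. = FALSE)
  }
  if (length(profile$times) < 8L) stop("need at least 8 samples", call. = FALSE)
  dt <- diff(profile$times)
  if (stats::sd(dt) / stats::median(dt) > 0.01) {
    rate <- if (is.null(params$resample_rate)) 1 / stats::median(dt) else params$resample_rate
    profile <- resample_uniform(profile, rate)
    dt <- diff(profile$times)
  }
  fs <- 1 / stats::median(dt)
  v <- profile$values
  n <- length(v)
  nfft <- 2^(ceiling(log2(n)) + params$pad_level)
  mag <- Mod(stats::fft(c(v, rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1L) * fs / nfft
  fc <- params$omega_c / (2 * pi)
  band <- .sparc_band(freq, mag, fc, params$amp_threshold)
  .arc_length_spectrum(band$f, band$v)
}
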