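# Shared fixtures and independent oracles, built in code at test time.

# default reference reach: D = 300 mm, T = 1 s, 200 Hz, noise-free,
# single submovement, both arms, 3 iterations
ref_reach <- generate_reach(synth_spec())

# segment-1 end-effector path and speed profile of one side
seg_path <- function(gen, side = "right", seg_index = 1L) {
  rec <- gen$recording
  seg <- split_segments(rec)[seg_index, ]
  code <- if (side == "left") "LWR" else "RWR"
  idx <- seg$start:seg$end
  list(seg = seg,
       path = path3d(rec$times[idx], rec$positions[[code]][idx, , drop = FALSE]))
}

ref_seg <- seg_path(ref_reach)
ref_speed <- speed_profile(ref_seg$path)

# a single-iteration right-arm reach with given submovement layout
sub_reach <- function(D = 300, T = 1, k = 1L, offsets = NULL, seed = 1L,
                      noise_sd = 0) {
  generate_reach(synth_spec(amplitude = D, duration = T, n_submovements = k,
                            submovement_offsets = offsets, noise_sd = noise_sd,
                            seed = seed, arm_side = "right", n_iterations = 1L))
}

# rotation matrix about an arbitrary axis (Rodrigues), angle in radians
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# apply a rigid transform to a path3d
transform_path <- function(path, R = diag(3), shift = c(0, 0, 0)) {
  path3d(path$times, path$points %*% t(R) +
           matrix(shift, nrow(path$points), 3, byrow = TRUE))
}

# independent SPARC oracle: direct DFT of the speed samples on a dense
# uniform frequency grid up to the cutoff, same normalization and adaptive
# band rule, arc length on the normalized frequency scale
sparc_oracle <- function(v, fs, fc = 20, amp_th = 0.05, n_freq = 20001L) {
  k <- seq_along(v) - 1L
  fgrid <- seq(0, fc, length.out = n_freq)
  mag <- vapply(fgrid, function(f) Mod(sum(v * exp(-2i * pi * f * k / fs))), 0)
  vhat <- mag / mag[1L]
  above <- which(vhat >= amp_th)
  sel <- above[1L]:above[length(above)]
  f_s <- fgrid[sel]; v_s <- vhat[sel]
  -sum(sqrt((diff(f_s) / (f_s[length(f_s)] - f_s[1L]))^2 + diff(v_s)^2))
}

# brute-force strict-local-maximum count with plateaus collapsed
brute_peak_count <- function(v) {
  v2 <- v[c(TRUE, diff(v) != 0)]
  m <- length(v2)
  if (m < 3L) return(0L)
  sum(v2[2:(m - 1L)] > v2[1:(m - 2L)] & v2[2:(m - 1L)] > v2[3:m])
}

# small valid recording built directly (n frames, all 8 landmarks static
# except the right wrist moving linearly), labels supplied by the caller
toy_recording <- function(n = 10L, labels = rep("1", n), rate = 100) {
  t <- (0:(n - 1)) / rate
  const <- function(p) matrix(p, n, 3, byrow = TRUE)
  wr <- const(c(200, -100, 1050)) + cbind(0, 10 * t, 0)
  recording(t, list(
    RWR = wr, LWR = const(c(-200, -100, 1050)),
    REL = const(c(190, -50, 1180)), LEL = const(c(-190, -50, 1180)),
    RSH = const(c(180, 0, 1400)), LSH = const(c(-180, 0, 1400)),
    TRK = const(c(0, 0, 1150)), NK = const(c(0, 0, 1450))
  ), labels)
}
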