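# Synthetic recordings with analytically known kinematics.
#
# The canonical smooth reach is the minimum-jerk trajectory
# x(tau) = D * (10 tau^3 - 15 tau^4 + 6 tau^5), tau = t/T, for which every
# smoothness metric has a closed form or a unique qualitative signature:
# MV = D/T, PV = 1.875 D/T, MV/PV = 8/15, TPV = 50%, LDJ = -ln(720),
# one velocity peak, one tangential-acceleration zero crossing, HPR = 1.
# Arm geometry is a rigid two-link chain (upper arm 300 mm, forearm 280 mm,
# adult averages); the metrics under test are either invariant to the
# segment lengths or scripted through them.

.UPPER_ARM <- 300
.FOREARM <- 280
.SHOULDER_R <- c(180, 0, 1400)
.TRUNK <- c(0, 0, 1150)
.NECK <- c(0, 0, 1450)
# wrist start relative to the shoulder: slightly behind the frontal plane
# and below, so that forward reaches of up to ~700 mm total stay inside the
# two-link workspace (the path crosses the frontal plane close to the trunk)
.WRIST_START_OFFSET <- c(0, -250, -350)
.EPOCH_BASE <- 1.7e9                    # UNIX-epoch base for generated timestamps

#' Minimum-jerk displacement
#'
#' Scalar displacement along the movement direction at time `t` of a
#' minimum-jerk reach of amplitude `D` and duration `T`:
#' `D * (10 tau^3 - 15 tau^4 + 6 tau^5)` with `tau = t/T`.
#'
#' @param D Amplitude in mm (> 0).
#' @param T Duration in s (> 0).
#' @param t Time(s) in `[0, T]`; values outside are an error.
#' @return Displacement(s) in mm, monotone from 0 to `D`.
#' @export
min_jerk_position <- function(D, T, t) {
  if (D <= 0 || T <= 0) stop("D and T must be positive", call. = FALSE)
  if (any(t < 0 | t > T)) stop("t outside [0, T]", call. = FALSE)
  tau <- t / T
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# clamped variant for composing submovements
.mj_clamped <- function(D, T, t) {
  tau <- pmin(1, pmax(0, t / T))
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Synthetic reach specification
#'
#' Defaults are the reference test conditions: a single noise-free
#' minimum-jerk reach of 300 mm in 1 s sampled at 200 Hz, three iterations,
#' both arms moving (mirrored).
#'
#' @param amplitude Reach amplitude D per submovement, mm.
#' @param duration Submovement duration T, s.
#' @param rate Sampling rate, Hz.
#' @param direction 3-vector movement direction (normalized internally).
#' @param n_submovements Number of composed minimum-jerk submovements (>= 1).
#' @param submovement_offsets Onset times (s) of the submovements, relative
#'   to segment start; non-negative, increasing, first must be 0. Default:
#'   onsets spaced `duration/2` apart.
#' @param noise_sd Isotropic Gaussian marker noise sd, mm (0 = none).
#' @param seed RNG seed for the noise.
#' @param arm_side `"both"` (mirrored movement), `"left"` or `"right"`
#'   (other arm static).
#' @param n_iterations Number of movement iterations.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(amplitude = 300, duration = 1, rate = 200,
                       direction = c(0, 1, 0), n_submovements = 1L,
                       submovement_offsets = NULL, noise_sd = 0, seed = 1L,
                       arm_side = c("both", "left", "right"), n_iterations = 3L) {
  arm_side <- match.arg(arm_side)
  if (amplitude <= 0 || duration <= 0 || rate <= 0) {
    stop("amplitude, duration and rate must be positive", call. = FALSE)
  }
  n_submovements <- as.integer(n_submovements)
  if (n_submovements < 1L) stop("n_submovements must be >= 1", call. = FALSE)
  if (is.null(submovement_offsets)) {
    submovement_offsets <- (seq_len(n_submovements) - 1L) * duration / 2
  }
  if (length(submovement_offsets) != n_submovements ||
      submovement_offsets[1L] != 0 ||
      (n_submovements > 1L && any(diff(submovement_offsets) <= 0))) {
    stop("submovement_offsets must start at 0 and be increasing, one per submovement",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, duration = duration, rate = rate,
                 direction = as.numeric(direction),
                 n_submovements = n_submovements,
                 submovement_offsets = as.numeric(submovement_offsets),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 arm_side = arm_side, n_iterations = as.integer(n_iterations)),
            class = "synth_spec")
}

# two-link inverse kinematics: elbow position given shoulder and wrist.
# The elbow bends in the plane spanned by the shoulder->wrist axis and the
# global downward direction (fallback +y when the axis is vertical).
.elbow_ik <- function(shoulder, wrist) {
  n <- nrow(wrist)
  sw <- wrist - matrix(shoulder, n, 3, byrow = TRUE)
  d <- .row_norms(sw)
  if (any(d > .UPPER_ARM + .FOREARM - 1e-9) || any(d < abs(.UPPER_ARM - .FOREARM) + 1e-9)) {
    stop("wrist out of reach of the two-link arm chain", call. = FALSE)
  }
  e1 <- sw / d
  ref <- matrix(c(0, 0, -1), n, 3, byrow = TRUE)
  proj <- ref - e1 * as.vector(e1 %*% c(0, 0, -1))
  pn <- .row_norms(proj)
  vertical <- pn < 1e-9
  if (any(vertical)) {
    ref2 <- matrix(c(0, 1, 0), n, 3, byrow = TRUE)
    proj2 <- ref2 - e1 * as.vector(e1 %*% c(0, 1, 0))
    proj[vertical, ] <- proj2[vertical, ]
    pn <- .row_norms(proj)
  }
  e2 <- proj / pn
  cosg <- (.UPPER_ARM^2 + d^2 - .FOREARM^2) / (2 * .UPPER_ARM * d)
  sing <- sqrt(pmax(0, 1 - cosg^2))
  matrix(shoulder, n, 3, byrow = TRUE) + .UPPER_ARM * (cosg * e1 + sing * e2)
}

#' Generate a synthetic reach recording
#'
#' Builds a schema-conformant recording in which the wrist follows a
#' (possibly composed) minimum-jerk path from a fixed start pose; the elbow
#' and shoulder are placed by a rigid two-link chain, and trunk and neck are
#' stationary. Iteration labels mark each reach; rest-labelled rows cover
#' the return movement and a short pause between iterations. Movement
#' samples span `[0, T_total]` inclusively so the segment duration equals
#' the nominal duration exactly. The recording carries `target_x/y/z`
#' columns at the reach endpoint of the moving (right-preferred) arm.
#'
#' @param spec A [synth_spec()].
#' @return List with `recording` (a [recording()]) and `truth`, the
#'   closed-form ground-truth metric values for the noise-free
#'   single-submovement case (elements: `MV`, `PV`, `velocity_ratio`,
#'   `TPV`, `LDJ`, `NPV`, `HPR`, `MT`, `target`).
#' @export
generate_reach <- function(spec = synth_spec()) {
  if (!inherits(spec, "synth_spec")) stop("spec must be a synth_spec", call. = FALSE)
  D <- spec$amplitude; Tm <- spec$duration; rate <- spec$rate
  dir <- spec$direction / sqrt(sum(spec$direction^2))
  offs <- spec$submovement_offsets
  motion_dur <- max(offs) + Tm
  D_tot <- D * spec$n_submovements

  n_move <- as.integer(round(motion_dur * rate))
  n_ret <- as.integer(round(Tm * rate))
  n_pause <- max(1L, as.integer(round(0.2 * rate)))
  block <- n_move + n_ret + n_pause
  K <- spec$n_iterations * block  # index of last sample
  k <- 0:K
  t <- k / rate
  within <- k %% block
  iter_of <- k %/% block
  in_move <- within <= n_move & iter_of < spec$n_iterations
  in_ret <- within > n_move & within <= n_move + n_ret

  s <- numeric(length(k))
  t_rel <- within / rate
  if (any(in_move)) {
    tm <- t_rel[in_move]
    s[in_move] <- Reduce(`+`, lapply(offs, function(o) .mj_clamped(D, Tm, tm - o)))
  }
  s[in_ret] <- D_tot * (1 - .mj_clamped(1, Tm, t_rel[in_ret] - motion_dur))

  labels <- rep("rest", length(k))
  labels[in_move] <- as.character(iter_of[in_move] + 1L)

  sh_r <- .SHOULDER_R
  sh_l <- sh_r * c(-1, 1, 1)
  wr_r0 <- sh_r + .WRIST_START_OFFSET
  wr_r <- matrix(wr_r0, length(k), 3, byrow = TRUE) + s %*% t(dir)
  mirror_x <- function(m) { m[, 1] <- -m[, 1]; m }
  static_r <- matrix(wr_r0, length(k), 3, byrow = TRUE)
  wrists <- switch(spec$arm_side,
    both = list(RWR = wr_r, LWR = mirror_x(wr_r)),
    right = list(RWR = wr_r, LWR = mirror_x(static_r)),
    left = list(RWR = static_r, LWR = mirror_x(wr_r)))

  positions <- list(
    RWR = wrists$RWR, LWR = wrists$LWR,
    REL = .elbow_ik(sh_r, wrists$RWR), LEL = .elbow_ik(sh_l, wrists$LWR),
    RSH = matrix(sh_r, length(k), 3, byrow = TRUE),
    LSH = matrix(sh_l, length(k), 3, byrow = TRUE),
    TRK = matrix(.TRUNK, length(k), 3, byrow = TRUE),
    NK = matrix(.NECK, length(k), 3, byrow = TRUE)
  )

  moving_end <- if (spec$arm_side == "left") {
    mirror_x(matrix(wr_r0 + D_tot * dir, 1, 3))[1, ]
  } else {
    wr_r0 + D_tot * dir
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    positions <- lapply(positions, function(m) {
      m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow(m), 3)
    })
  }

  rec <- recording(.EPOCH_BASE + t, positions, labels,
                   meta = list(source = "armkin::generate_reach",
                               synth = unclass(spec)))
  rec$target <- matrix(moving_end, length(k), 3, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y", "z")))

  truth <- list(MT = motion_dur, target = moving_end, NPV = spec$n_submovements)
  if (spec$n_submovements == 1L) {
    truth <- c(truth, list(
      MV = D / Tm, PV = 1.875 * D / Tm, velocity_ratio = 8 / 15,
      TPV = 50, LDJ = -log(720), HPR = 1
    ))
  }
  list(recording = rec, truth = truth)
}

#' Generate a scripted joint-angle sweep
#'
#' Forward-kinematic recording in which one joint angle follows a raised
#' cosine between `min_angle` and `max_angle` (starting at `min_angle`),
#' with all other joints static. Used as a ground-truth oracle for
#' [angle_series()] and [rom_range()]; emulates, e.g., a shoulder-flexion
#' rehabilitation exercise.
#'
#' @param joint One of `"left_elbow"`, `"right_elbow"`, `"left_shoulder"`,
#'   `"right_shoulder"`.
#' @param min_angle,max_angle Sweep bounds in degrees, `0 <= min < max <= 180`.
#' @param cycles Number of full min -> max -> min cycles (0 = constant at
#'   `min_angle`).
#' @param rate Sampling rate, Hz.
#' @param duration Recording duration in s; default 2 s per cycle.
#' @return A [recording()] with a single iteration label.
#' @export
generate_angle_sweep <- function(joint, min_angle, max_angle, cycles = 1,
                                 rate = 100, duration = NULL) {
  joint <- match.arg(joint, JOINT_IDS)
  if (min_angle < 0 || max_angle > 180 || min_angle >= max_angle) {
    stop("require 0 <= min_angle < max_angle <= 180", call. = FALSE)
  }
  if (is.null(duration)) duration <- 2 * max(cycles, 1)
  n <- as.integer(round(duration * rate))
  t <- (0:n) / rate
  theta <- if (cycles == 0) rep(min_angle, n + 1L) else
    min_angle + (max_angle - min_angle) * (1 - cos(2 * pi * cycles * t / duration)) / 2
  th <- theta * pi / 180

  side <- if (startsWith(joint, "left")) "L" else "R"
  sh_r <- .SHOULDER_R
  sh <- if (side == "L") sh_r * c(-1, 1, 1) else sh_r
  sh_other <- sh * c(-1, 1, 1)
  lateral <- (sh - .NECK) * c(1, 1, 0)
  lateral <- lateral / sqrt(sum(lateral^2))  # horizontal neck -> shoulder
  np <- length(t)
  const <- function(p) matrix(p, np, 3, byrow = TRUE)

  if (endsWith(joint, "elbow")) {
    u <- c(0, 0, -1)                       # upper arm hangs down
    w_perp <- c(0, 1, 0)
    el <- const(sh + .UPPER_ARM * u)
    fore_dir <- outer(cos(th), u) + outer(sin(th), w_perp)
    wr <- el + .FOREARM * fore_dir
  } else {
    # arm kept straight; upper arm rotates from the lateral direction
    # toward vertical-down, so the shoulder angle equals theta
    arm_dir <- outer(cos(th), lateral) + outer(sin(th), c(0, 0, -1))
    el <- const(sh) + .UPPER_ARM * arm_dir
    wr <- const(sh) + (.UPPER_ARM + .FOREARM) * arm_dir
  }

  # static opposite arm, hanging down with a slight elbow bend
  el_o <- sh_other + .UPPER_ARM * c(0, 0, -1)
  wr_o <- el_o + .FOREARM * c(0, 0.3, -sqrt(1 - 0.09)) * 1

  positions <- list(TRK = const(.TRUNK), NK = const(.NECK),
                    RSH = const(if (side == "R") sh else sh_other),
                    LSH = const(if (side == "L") sh else sh_other))
  positions[[paste0(side, "EL")]] <- el
  positions[[paste0(side, "WR")]] <- wr
  other <- setdiff(c("L", "R"), side)
  positions[[paste0(other, "EL")]] <- const(el_o)
  positions[[paste0(other, "WR")]] <- const(wr_o)

  recording(.EPOCH_BASE + t, positions, rep("1", np),
            meta = list(source = "armkin::generate_angle_sweep"))
}
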