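test_that("elbow angle covers extended, right-angle and folded poses", {
  sh <- c(0, 0, 0); el <- c(0, -300, 0)
  expect_equal(elbow_angle(sh, el, c(0, -600, 0)), 0, tolerance = 1e-9)
  expect_equal(elbow_angle(sh, el, c(300, -300, 0)), 90, tolerance = 1e-9)
  expect_equal(elbow_angle(sh, el, c(0, 0, 0)), 180, tolerance = 1e-9)
  expect_error(elbow_angle(sh, el, el), "zero-length")
})

test_that("virtual trunk point lies horizontally from the shoulder", {
  vt <- virtual_trunk_point(c(0, 0, 1400), c(200, 0, 1400), offset = 100)
  expect_equal(as.vector(vt), c(300, 0, 1400), tolerance = 1e-12)
  # vertical component of the neck->shoulder direction is discarded
  vt2 <- virtual_trunk_point(c(0, 0, 1500), c(200, 0, 1400), offset = 100)
  expect_equal(as.vector(vt2), c(300, 0, 1400), tolerance = 1e-12)
  expect_error(virtual_trunk_point(c(200, 0, 1500), c(200, 0, 1400)),
               "horizontal direction undefined")
  # sign flag reverses the reference direction
  vt3 <- virtual_trunk_point(c(0, 0, 1400), c(200, 0, 1400), offset = 100,
                             direction = "shoulder_to_neck")
  expect_equal(as.vector(vt3), c(100, 0, 1400), tolerance = 1e-12)
})

test_that("shoulder angle matches simple poses and ignores the trunk offset", {
  nk <- c(0, 0, 1400); sh <- c(200, 0, 1400)
  # arm hanging straight down vs the lateral trunk direction
  expect_equal(shoulder_angle(sh, sh + c(0, 0, -300), nk), 90, tolerance = 1e-9)
  # arm abducted along the neck->shoulder direction
  expect_equal(shoulder_angle(sh, sh + c(300, 0, 0), nk), 0, tolerance = 1e-9)
  set.seed(41)
  el <- sh + c(120, 200, -150)
  base <- shoulder_angle(sh, el, nk, offset = 50)
  for (off in runif(10, 1, 500)) {
    expect_equal(shoulder_angle(sh, el, nk, offset = off), base, tolerance = 1e-9)
  }
})

test_that("angle operations are invariant under rotation about the up axis and translation", {
  nk <- c(10, -5, 1400); sh <- c(200, 40, 1390); el <- sh + c(100, 180, -200)
  wr <- el + c(-50, 230, -90)
  Rz <- rot_about(c(0, 0, 1), 0.71)
  shift <- c(-31, 12, 77)
  tr <- function(p) as.vector(Rz %*% p + shift)
  expect_equal(elbow_angle(tr(sh), tr(el), tr(wr)), elbow_angle(sh, el, wr),
               tolerance = 1e-9)
  expect_equal(shoulder_angle(tr(sh), tr(el), tr(nk)),
               shoulder_angle(sh, el, nk), tolerance = 1e-9)
  # the elbow angle is invariant under arbitrary rotations too
  R <- rot_about(c(1, 1, 0), 1.2)
  expect_equal(elbow_angle(as.vector(R %*% sh), as.vector(R %*% el), as.vector(R %*% wr)),
               elbow_angle(sh, el, wr), tolerance = 1e-9)
})

test_that("angle series recover scripted joint motion", {
  # constant elbow angle
  sw0 <- generate_angle_sweep("right_elbow", 90, 91, cycles = 0)
  ser0 <- angle_series(sw0, "right_elbow")
  expect_equal(ser0$angles, rep(90, length(ser0$angles)), tolerance = 1e-6)

  # sinusoidal flexion sweep 20 -> 110 degrees
  sw <- generate_angle_sweep("right_elbow", 20, 110, cycles = 1, rate = 100)
  ser <- angle_series(sw, "right_elbow")
  expect_equal(min(ser$angles), 20, tolerance = 0.5)
  expect_equal(max(ser$angles), 110, tolerance = 0.5)

  # shoulder sweep via the virtual trunk construction
  sw2 <- generate_angle_sweep("left_shoulder", 0, 90, cycles = 1)
  ser2 <- angle_series(sw2, "left_shoulder")
  expect_equal(min(ser2$angles), 0, tolerance = 0.5)
  expect_equal(max(ser2$angles), 90, tolerance = 0.5)

  rec <- sw
  rec$positions$LEL <- NULL
  expect_error(angle_series(rec, "left_elbow"), "LEL")
})

test_that("the neck falls back to estimation for shoulder angles", {
  sw <- generate_angle_sweep("right_shoulder", 10, 80)
  no_nk <- sw
  no_nk$positions$NK <- NULL
  a <- angle_series(sw, "right_shoulder")
  b <- angle_series(no_nk, "right_shoulder")
  # estimated neck is the shoulder midpoint: same horizontal direction,
  # so the angles agree
  expect_equal(a$angles, b$angles, tolerance = 1e-9)
})

test_that("range of motion summarises an angle series", {
  sw <- generate_angle_sweep("right_elbow", 20, 110, cycles = 1, rate = 100)
  ser <- angle_series(sw, "right_elbow")
  rr <- rom_range(ser)
  expect_equal(rr$rom, 90, tolerance = 1)
  expect_equal(rr$min_angle, 20, tolerance = 0.5)
  expect_equal(rr$max_angle, 110, tolerance = 0.5)

  const <- angle_series(generate_angle_sweep("right_elbow", 45, 46, cycles = 0),
                        "right_elbow")
  expect_equal(rom_range(const)$rom, 0, tolerance = 1e-9)

  # time reversal leaves the ROM unchanged
  rev_ser <- structure(list(times = ser$times,
                            angles = rev(ser$angles), joint = ser$joint),
                       class = "angle_series")
  expect_equal(rom_range(rev_ser)$rom, rr$rom, tolerance = 1e-12)

  # segment windowing: first half of one cycle holds the upswing only
  seg <- list(t0 = ser$times[1], t1 = ser$times[1] + 1.0)
  half <- rom_range(ser, seg)
  expect_equal(half$max_angle, 110, tolerance = 0.5)
  expect_error(rom_range(ser, list(t0 = ser$times[length(ser$times)] + 10,
                                   t1 = ser$times[length(ser$times)] + 20)),
               "overlap")
})
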