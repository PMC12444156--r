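test_that("write/read round trip reproduces a recording", {
  rec <- ref_reach$recording
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_setequal(names(back$positions), names(rec$positions))
  for (code in names(rec$positions)) {
    expect_lt(max(abs(back$positions[[code]] - rec$positions[[code]])), 1e-9)
  }
  expect_identical(back$iteration, rec$iteration)
  expect_lt(max(abs(back$times - rec$times)), 1e-6)
  expect_lt(max(abs(back$target - rec$target)), 1e-9)
})

test_that("the neck landmark is optional and its absence is visible", {
  rec <- ref_reach$recording
  rec$positions$NK <- NULL
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_length(back$positions, 7L)
  expect_false("NK" %in% names(back$positions))
  expect_equal(nrow(validate_schema(f)), 0L)
})

test_that("schema validation catches malformed files", {
  rec <- toy_recording()
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  expect_equal(nrow(validate_schema(f)), 0L)

  df <- utils::read.csv(f, check.names = FALSE)

  # non-monotonic timestamps
  bad <- df
  bad$timestamp[1:3] <- c(5, 4, 6)
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  iss <- validate_schema(f2)
  expect_true(any(iss$severity == "error" & grepl("non-monotonic", iss$message)))
  expect_error(read_recording(f2), "non-monotonic")

  # incomplete triplet names the missing column
  bad <- df[, setdiff(names(df), "RWRy")]
  utils::write.csv(bad, f2, row.names = FALSE)
  iss <- validate_schema(f2)
  expect_true(any(iss$severity == "error" & iss$column == "RWRy"))

  # non-numeric coordinate reports the row
  bad <- df
  bad$RWRx[4] <- "oops"
  utils::write.csv(bad, f2, row.names = FALSE)
  iss <- validate_schema(f2)
  expect_true(any(iss$severity == "error" & iss$column == "RWRx" &
                    grepl("row 4", iss$message)))

  # duplicated timestamps are a warning, not an error
  bad <- df[c(1, 1, 2:nrow(df)), ]
  utils::write.csv(bad, f2, row.names = FALSE)
  iss <- validate_schema(f2)
  expect_true(any(iss$severity == "warning" & grepl("duplicat", iss$message)))
  expect_false(any(iss$severity == "error"))
  expect_warning(b <- read_recording(f2), "duplicated")
  expect_equal(length(b$times), nrow(df))

  # unreadable file -> single error issue
  iss <- validate_schema(file.path(tempdir(), "does-not-exist.csv"))
  expect_equal(nrow(iss), 1L)
  expect_equal(iss$severity, "error")
})

test_that("a user column mapping adapts foreign dialects", {
  rec <- toy_recording()
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  df <- utils::read.csv(f, check.names = FALSE)
  names(df)[names(df) == "timestamp"] <- "time_s"
  names(df)[names(df) %in% c("RWRx", "RWRy", "RWRz")] <- c("wx", "wy", "wz")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_recording(f2), "timestamp")
  mp <- list(timestamp = "time_s", RWR = c("wx", "wy", "wz"))
  back <- read_recording(f2, mapping = mp)
  expect_lt(max(abs(back$positions$RWR - rec$positions$RWR)), 1e-9)
})

test_that("neck estimation is the shoulder midpoint and translation-equivariant", {
  n <- 5L
  mk <- function(lsh, rsh) {
    const <- function(p) matrix(p, n, 3, byrow = TRUE)
    recording((0:(n - 1)) / 100,
              list(RWR = const(c(200, -100, 1050)), LSH = const(lsh), RSH = const(rsh)),
              rep("1", n))
  }
  rec <- mk(c(-200, 0, 1400), c(200, 0, 1400))
  est <- estimate_neck(rec)
  expect_equal(est$positions$NK[1, ], c(0, 0, 1400), ignore_attr = TRUE)

  degenerate <- mk(c(0, 0, 0), c(0, 0, 0))
  expect_equal(estimate_neck(degenerate)$positions$NK[1, ], c(0, 0, 0),
               ignore_attr = TRUE)

  rec_no_sh <- rec; rec_no_sh$positions$LSH <- NULL
  expect_error(estimate_neck(rec_no_sh), "LSH")

  shift <- c(13.5, -7.2, 101)
  rec2 <- rec
  rec2$positions <- lapply(rec$positions, function(m) m + matrix(shift, n, 3, byrow = TRUE))
  est2 <- estimate_neck(rec2)
  expect_equal(est2$positions$NK,
               est$positions$NK + matrix(shift, n, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("segments are maximal runs of non-rest labels", {
  rec <- toy_recording(7L, labels = c("rest", "1", "1", "1", "rest", "2", "2"))
  segs <- split_segments(rec)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$end - segs$start + 1L, c(3L, 2L))
  expect_equal(segs$label, c("1", "2"))
  expect_equal(segs$t0, rec$times[c(2, 6)])
  expect_equal(segs$t1, rec$times[c(4, 7)])

  expect_error(split_segments(toy_recording(4L, labels = rep("rest", 4))),
               "no movement iterations")

  # non-contiguous reuse of a label forms distinct segments
  segs <- split_segments(toy_recording(4L, labels = c("1", "1", "rest", "1")))
  expect_equal(nrow(segs), 2L)
})

test_that("segments partition exactly the non-rest rows (random labels)", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(5:40, 1)
    labels <- as.character(sample(c("rest", "1", "2", "3"), n, replace = TRUE))
    rec <- toy_recording(n, labels = labels)
    non_rest <- which(labels != "rest")
    if (!length(non_rest)) {
      expect_error(split_segments(rec), "no movement iterations")
      next
    }
    segs <- split_segments(rec)
    covered <- unlist(mapply(seq, segs$start, segs$end, SIMPLIFY = FALSE))
    expect_identical(sort(covered), non_rest)
    # brute-force run count over non-rest positions
    runs <- sum(diff(c(-10, non_rest)) > 1) +
      sum(labels[non_rest][-1] != labels[non_rest][-length(non_rest)] &
            diff(non_rest) == 1)
    expect_equal(nrow(segs), runs)
  }
})

test_that("writing an empty recording fails", {
  empty <- recording(numeric(0),
                     list(RWR = matrix(numeric(0), 0, 3)), character(0))
  expect_error(write_recording(empty, tempfile()), "empty")
})

test_that("rest labels are preserved verbatim through a round trip", {
  rec <- toy_recording(6L, labels = c("rest", "1", "1", "rest", "2", "rest"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  expect_identical(read_recording(f)$iteration, rec$iteration)
})
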