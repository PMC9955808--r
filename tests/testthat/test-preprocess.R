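# independent brute-force sliding-window oracle with mirror reflection
brute_window <- function(x, i, h) {
  n <- length(x)
  j <- (i - h):(i + h)
  j[j < 1] <- 2 - j[j < 1]
  j[j > n] <- 2 * n - j[j > n]
  x[j]
}

test_that("resultant angle is the Euclidean combination of the two planes", {
  expect_equal(resultant_angle(3, 4), 5)
  expect_equal(resultant_angle(0, 0), 0)
  expect_equal(resultant_angle(30, 0), 30)
  expect_equal(resultant_angle(c(3, 0), c(4, 2)), c(5, 2))
  expect_error(resultant_angle(1:3, 1:2), "equal length")
})

test_that("median filter matches a brute-force sliding median", {
  expect_equal(median_filter(rep(2.5, 20), 5), rep(2.5, 20))
  expect_equal(median_filter(c(0, 0, 100, 0, 0), 5)[3], 0)
  expect_error(median_filter(1:10, 4), "odd")
  set.seed(42)
  x <- rnorm(300)
  got <- median_filter(x, 5)
  want <- vapply(seq_along(x), function(i) median(brute_window(x, i, 2)),
                 numeric(1))
  expect_equal(got, want)
})

test_that("mean filter matches a brute-force sliding mean", {
  expect_equal(mean_filter(rep(-1.2, 20), 5), rep(-1.2, 20))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(sum(mean_filter(imp, 5) == 0.2), 5)
  set.seed(43)
  x <- rnorm(300)
  got <- mean_filter(x, 5)
  want <- vapply(seq_along(x), function(i) mean(brute_window(x, i, 2)),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fix-zero levelling removes the baseline offset", {
  x <- rep(2.3, 500)
  out <- fix_zero_levelling(x, fs = 1000)
  expect_equal(out, rep(0, 500))
  y <- c(rep(0, 100), rnorm(100))
  expect_equal(fix_zero_levelling(y, fs = 1000), y, tolerance = 1e-12)
  # ramp with offset: closed form
  n <- 1000
  ramp <- 1 + 10 * (seq_len(n) - 1) / (n - 1)
  out <- fix_zero_levelling(ramp, fs = 1000, baseline_s = 0.1)
  base <- 1 + 10 * mean(0:99) / (n - 1)
  expect_equal(out[1], 1 - base)
  expect_equal(out[n], 11 - base)
  expect_error(fix_zero_levelling(rnorm(50), fs = 1000), "baseline")
})

test_that("sEMG conditioning yields the analytic envelope of a sinusoid", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  # constant input: mean removal leaves zero
  expect_equal(semg_condition(rep(0.7, fs), fs = fs), rep(0, fs))
  # rectification symmetry: sign flip leaves the envelope unchanged
  x <- sin(2 * pi * 50 * t) * (1 + 0.3 * sin(2 * pi * 1 * t))
  expect_equal(semg_condition(x, fs = fs), semg_condition(-x, fs = fs))
  # |A sin(2 pi 50 t)| has DC 2A/Pi; the 100+ Hz harmonics are crushed by
  # the squared (zero-phase) 4th-order 10 Hz response, so the mid-section
  # should sit at 2A/Pi
  A <- 0.8
  env <- semg_condition(A * sin(2 * pi * 50 * t), fs = fs)
  mid <- env[(fs %/% 2):(3 * fs %/% 2)]
  expect_lt(max(abs(mid - 2 * A / pi)) / (2 * A / pi), 0.05)
  expect_error(semg_condition(rnorm(10), fs = fs), "too short")
})

test_that("sEMG alignment decimates onto the low-rate timebase", {
  env <- seq_len(4000)
  out <- align_semg(env, 2000)
  expect_equal(out, env[seq(1, 4000, by = 2)])
  expect_equal(align_semg(rep(3, 4000), 2000), rep(3, 2000))
  t_hi <- (0:3999) / 2000
  env <- sin(2 * pi * 5 * t_hi)
  out <- align_semg(env, 2000)
  expect_equal(out, sin(2 * pi * 5 * (0:1999) / 1000), tolerance = 1e-9)
  expect_error(align_semg(rnorm(1000), 2000), "does not match")
})

test_that("window detection recovers planted staircase boundaries", {
  st <- ramp_staircase()
  w <- detect_stretch_windows(st$angle, fs = st$fs, min_prominence = 10)
  expect_identical(nrow(w), 6L)
  expect_true(all(abs(w$start_idx - st$starts) <= 5))
  expect_true(all(abs(w$end_idx - st$ends) <= 5))
  # windows ordered and non-overlapping
  expect_true(all(diff(as.vector(t(as.matrix(w)))) > 0))

  # monotone single rise
  w1 <- detect_stretch_windows(c(seq(0, 50, length.out = 500)), fs = 1000)
  expect_identical(nrow(w1), 1L)
  expect_lte(w1$start_idx, 5L)
  expect_gte(w1$end_idx, 496L)

  # flat series
  expect_identical(nrow(detect_stretch_windows(rep(3, 1000), fs = 1000)), 0L)
})

test_that("noisy staircase boundaries are recovered within 30 ms at 20 dB SNR", {
  clean <- ramp_staircase()
  sig_sd <- sd(clean$angle - mean(clean$angle))
  for (seed in 1:3) {
    st <- ramp_staircase(noise_sd = sig_sd / 10, seed = seed)  # 20 dB SNR
    filt <- mean_filter(median_filter(st$angle, 5), 5)
    w <- detect_stretch_windows(filt, fs = st$fs, min_prominence = 10,
                                refine = TRUE)
    expect_identical(nrow(w), 6L)
    expect_true(all(abs(w$start_idx - st$starts) <= 30))
    expect_true(all(abs(w$end_idx - st$ends) <= 30))
  }
})

test_that("session segmentation yields six speed-tagged stretches", {
  s <- nf_session("1+")
  expect_length(s$segs, 6L)
  expect_identical(vapply(s$segs, `[[`, character(1), "speed"),
                   c("slow", "slow", "slow", "fast", "fast", "fast"))
  expect_true(all(vapply(s$segs, `[[`, numeric(1), "rom") >= 0))
  expect_true(all(s$proc$angle >= 0))
  expect_true(all(s$proc$semg_env >= 0))
  # boundaries within 10 ms of the planted ground truth on noise-free data
  expect_true(all(abs(vapply(s$segs, `[[`, numeric(1), "start_idx") -
                        s$gt$start_idx) <= 10))
  expect_true(all(abs(vapply(s$segs, `[[`, numeric(1), "end_idx") -
                        s$gt$end_idx) <= 10))
})

test_that("surplus low-amplitude windows are pruned, deficits are errors", {
  st <- ramp_staircase()
  # append a 15-degree artefact rise after the staircase
  artefact <- c(rep(0, 800), seq(0, 15, length.out = 500), rep(15, 800))
  ang <- c(st$angle, 10 + artefact)
  proc <- structure(list(time = (seq_along(ang) - 1) / 1000, angle = ang,
                         force = rep(1, length(ang)),
                         semg_env = rep(0.1, length(ang)), fs = 1000),
                    class = "processed_session")
  segs <- suppressWarnings(segment_session(proc, adaptive_prominence = FALSE))
  expect_length(segs, 6L)
  expect_true(all(vapply(segs, `[[`, numeric(1), "rom") > 50))

  # only four rises present
  short <- st$angle[1:(st$ends[4] + 900)]
  proc4 <- structure(list(time = (seq_along(short) - 1) / 1000, angle = short,
                          force = rep(1, length(short)),
                          semg_env = rep(0.1, length(short)), fs = 1000),
                     class = "processed_session")
  expect_error(suppressWarnings(segment_session(proc4)), "found 4 of 6")
})

test_that("the filtering chain is not idempotent (single application matters)", {
  set.seed(7)
  x <- cumsum(rnorm(500))
  once <- mean_filter(median_filter(x, 5), 5)
  twice <- mean_filter(median_filter(once, 5), 5)
  expect_false(isTRUE(all.equal(once, twice)))
})
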