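test_that("tidal image equals the amplitude map on an unfiltered noise-free phantom", {
  # RR 20 at 20 Hz: the period is exactly 60 samples, so breath landmarks
  # fall on exact waveform extrema and DI recovers A_xy to machine precision
  spec <- uniform_phantom_spec(amp = 2.5, rr = 20, duration = 45)
  ph <- generate_phantom(spec)
  seg <- detect_breaths(compute_global_curve(ph$frames))
  img <- tidal_image(ph$frames, seg)
  expect_lt(max(abs(img$di - spec$lung_amplitude_map)), 1e-6)
})

test_that("tidal image of a constant movie is zero and averaging is idempotent", {
  fr <- array(5, dim = c(200, 4, 4))
  seq <- frame_sequence(fr, 20)
  seg <- make_seg(starts = c(1, 61), peaks = c(31, 91), ends = c(61, 121))
  expect_true(all(tidal_image(seq, seg)$di == 0))
  # two breaths with identical frames leave DI unchanged vs one breath
  set.seed(1)
  fr2 <- array(rnorm(16), dim = c(1, 4, 4))[rep(1, 200), , , drop = FALSE]
  fr2 <- array(fr2, dim = c(200, 4, 4))
  seq2 <- frame_sequence(fr2, 20)
  one <- tidal_image(seq2, make_seg(1, 31, 61))
  two <- tidal_image(seq2, seg)
  expect_equal(one$di, two$di)
  seg_none <- make_seg(1, 31, 61, selected = FALSE)
  expect_error(tidal_image(seq2, seg_none), "no selected breaths")
})

test_that("lung mask thresholds maximum DI with an inclusive boundary", {
  di <- matrix(0, 4, 4); di[2, 2] <- 10
  mask <- build_lung_mask(make_tidal(di), 0.2)
  expect_equal(sum(mask$member), 1)
  expect_true(mask$member[2, 2])
  di[3, 3] <- 1.9; di[4, 4] <- 2.0
  mask2 <- build_lung_mask(make_tidal(di), 0.2)
  expect_false(mask2$member[3, 3])  # 1.9 < 0.2 * 10
  expect_true(mask2$member[4, 4])   # boundary inclusive
  # max is taken across sessions
  di_b <- matrix(0, 4, 4); di_b[1, 1] <- 5
  mask3 <- build_lung_mask(list(make_tidal(di), make_tidal(di_b)), 0.2)
  expect_true(mask3$member[1, 1])
  expect_error(build_lung_mask(make_tidal(matrix(0, 4, 4))), "non-positive")
})

test_that("phantom mask recovers the programmed ellipse support", {
  spec <- uniform_phantom_spec(rr = 20, duration = 45)
  ph <- generate_phantom(spec)
  seg <- detect_breaths(compute_global_curve(ph$frames))
  mask <- build_lung_mask(tidal_image(ph$frames, seg), 0.2)
  expect_identical(mask$member, lung_ellipses())
})

test_that("impedance ratio follows the printed band arithmetic", {
  # band sums 30, 20, 25, 25 over a 32-row image -> (30+20)/(25+25) = 1
  di <- matrix(0, 32, 32)
  di[1, 1] <- 30; di[9, 1] <- 20; di[17, 1] <- 25; di[25, 1] <- 25
  expect_equal(impedance_ratio(make_tidal(di), roi_partition(32)), 1)
  di2 <- matrix(1, 32, 32)  # ventral/dorsal mirror symmetric
  expect_equal(impedance_ratio(make_tidal(di2), roi_partition(32)), 1)
  # division contract: zero dorsal sum is undefined, zero ventral sum is 0
  di3 <- matrix(0, 32, 32); di3[2, ] <- 1  # ventral-only
  expect_error(impedance_ratio(make_tidal(di3), roi_partition(32)),
               "IR undefined")
  di4 <- matrix(0, 32, 32); di4[30, ] <- 1  # dorsal-only
  expect_equal(impedance_ratio(make_tidal(di4), roi_partition(32)), 0)
})

test_that("mirroring an image ventral-dorsal inverts the impedance ratio", {
  set.seed(3)
  for (i in 1:5) {
    di <- matrix(rexp(32 * 32), 32, 32)
    ir <- impedance_ratio(make_tidal(di), roi_partition(32))
    ir_m <- impedance_ratio(make_tidal(di[32:1, ]), roi_partition(32))
    expect_equal(ir_m, 1 / ir, tolerance = 1e-12)
  }
})

test_that("adapted partition splits the ventilated extent with dorsal remainder", {
  mk_mask <- function(rows) {
    m <- matrix(FALSE, 32, 32); m[rows, 5] <- TRUE
    make_mask(m)
  }
  p <- adapted_partition(mk_mask(9:24))  # 16 rows -> 4 bands of 4
  expect_equal(p$bands, list(9:12, 13:16, 17:20, 21:24))
  p2 <- adapted_partition(mk_mask(11:20))  # 10 rows -> heights 2,2,3,3
  expect_equal(p2$bands, list(11:12, 13:14, 15:17, 18:20))
  p3 <- adapted_partition(mk_mask(1:32))  # full extent = static partition
  expect_equal(p3$bands, roi_partition(32)$bands)
  expect_error(adapted_partition(mk_mask(10:12)), "4 required")
})

test_that("TIV averages breath swings and references the baseline", {
  # two breaths with swings 1.5 and 1.38 AU -> mean 1.44; baseline 2 -> 72%
  x <- rep(0, 200)
  x[31] <- 1.5; x[91] <- 1.38
  curve <- make_curve(x)
  seg <- make_seg(starts = c(1, 61), peaks = c(31, 91), ends = c(61, 121))
  res <- tiv(curve, seg, baseline_tiv_au = 2, min_breaths = 2)
  expect_equal(res$tiv_au, 1.44)
  expect_equal(res$tiv_percent, 72)
  expect_equal(tiv(curve, seg, NULL, min_breaths = 2)$tiv_percent, 100)
  expect_error(tiv(curve, seg, min_breaths = 10), ">= 10 selected")
  xneg <- -x
  expect_error(tiv(make_curve(xneg), seg, min_breaths = 2),
               "invalid breath landmarks")
})

test_that("dEELI normalizes the baseline shift by baseline TIV", {
  # end-expiration minima sit 1.3 AU below the baseline EELI; baseline TIV 2
  x <- rep(-1.3, 200); x[c(31, 91)] <- 1
  curve <- make_curve(x)
  seg <- make_seg(starts = c(1, 61), peaks = c(31, 91), ends = c(61, 121))
  res <- delta_eeli(curve, seg, baseline_eeli_au = 0, baseline_tiv_au = 2)
  expect_equal(res$eeli_au, -1.3)
  expect_equal(res$delta_eeli_percent, -65)
  expect_equal(delta_eeli(curve, seg)$delta_eeli_percent, 0)
  expect_error(delta_eeli(curve, seg, baseline_eeli_au = 0), "baseline TIV")
})

test_that("GI matches hand computation and the brute-force oracle", {
  mask3 <- make_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  img3 <- make_tidal(matrix(c(1, 1, 3, 99), 2, 2))  # off-mask pixel ignored
  g <- gi_index(img3, mask3)
  expect_equal(g$gi, 0.4)
  expect_equal(g$gi_reported, 40)
  # uniform image -> 0
  expect_equal(gi_index(make_tidal(matrix(2, 2, 2)),
                        make_mask(matrix(TRUE, 2, 2)))$gi, 0)
  set.seed(11)
  for (i in 1:100) {
    di <- matrix(rexp(12, rate = 1 / 5), 3, 4)
    mask <- make_mask(matrix(runif(12) < 0.8, 3, 4))
    if (!any(mask$member)) next
    expect_equal(gi_index(make_tidal(di), mask)$gi,
                 brute_force_gi(di[mask$member]), tolerance = 1e-12)
  }
  expect_error(gi_index(make_tidal(matrix(-1, 2, 2)),
                        make_mask(matrix(TRUE, 2, 2))), "GI undefined")
})

test_that("GI is scale invariant and zero only for uniform ventilation", {
  set.seed(4)
  di <- matrix(rexp(64), 8, 8)
  mask <- make_mask(matrix(TRUE, 8, 8))
  g1 <- gi_index(make_tidal(di), mask)$gi
  g2 <- gi_index(make_tidal(di * 7.3), mask)$gi
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_gt(g1, 0)
})

test_that("spRVD is zero for uniform delays and grows with delay spread", {
  base <- function(d_map) {
    spec <- uniform_phantom_spec(rr = 15, frac = 0.5, duration = 56,
                                 delay_map = d_map)  # Ti = 2 s
    ph <- generate_phantom(spec)
    seg <- detect_breaths(compute_global_curve(ph$frames))
    mask <- make_mask(lung_ellipses())
    vapply(c(40, 60, 80), function(th)
      sp_rvd(ph$frames, seg, mask, th, "sd")$value, numeric(1))
  }
  support <- lung_ellipses()
  unif <- matrix(0, 32, 32); unif[support] <- 0.5
  expect_true(all(base(unif) < 1))  # uniform delay: no spatial heterogeneity
  half <- matrix(FALSE, 32, 32)
  half[support] <- seq_len(sum(support)) %% 2 == 0
  sds <- sapply(c(0.15, 0.3, 0.6), function(d) {
    dm <- matrix(0, 32, 32); dm[half] <- d
    base(dm)[1]
  })
  expect_true(all(diff(sds) > 0))  # monotone in the spread
  expect_gt(sds[3], 10)            # 0.6 s spread in 2 s inspiration is large
})

test_that("spRVD clamps and counts pixels that never reach threshold", {
  fr <- array(0, dim = c(100, 2, 2))
  t <- (0:99) / 20
  fr[, 1, 1] <- breath_waveform(t, 3, 0.5)  # fr[, 1, 2] stays flat
  seq <- frame_sequence(fr, 20)
  seg <- make_seg(1, 31, 61)
  mask <- make_mask(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))  # one flat pixel
  expect_warning(res <- sp_rvd(seq, seg, mask, 40, "mean"), "never reached")
  expect_equal(res$n_unreached, 1L)
})

test_that("RSBI_EIT is rate over normalized TIV", {
  expect_equal(rsbi_eit(23.5, 100), 23.5)
  expect_equal(rsbi_eit(26, 72), 36.1, tolerance = 0.02)
  expect_error(rsbi_eit(20, 0), "> 0")
})

test_that("indices are invariant to a global impedance offset", {
  spec <- uniform_phantom_spec(amp = 1.8, rr = 20, duration = 45)
  ph <- generate_phantom(spec)
  shifted <- ph$frames
  shifted$frames <- shifted$frames + 123.4
  cfg <- eit_config()
  a <- analyze_session(ph$frames, config = cfg)
  b <- analyze_session(shifted, config = cfg)
  for (col in c("tiv_au", "tiv_percent", "ir", "ir_adapt", "gi",
                "rr", "rsbi_eit", "sp_rvd_sd_40"))
    expect_equal(b[[col]], a[[col]], tolerance = 1e-6, label = col)
  # eeli_au shifts with the offset, but the baseline-referenced dEELI of a
  # uniformly offset study is unchanged
  expect_equal(b$eeli_au - a$eeli_au, 123.4 * sum(lung_ellipses()),
               tolerance = 1e-6)
})

test_that("analyze_session enforces the baseline contract", {
  spec <- uniform_phantom_spec(rr = 20, duration = 45)
  ph <- generate_phantom(spec, session_label = "t1")
  expect_error(analyze_session(ph$frames), "baseline")
  base <- analyze_session(generate_phantom(spec)$frames)
  expect_equal(base$tiv_percent, 100)
  expect_equal(base$delta_eeli_percent, 0)
})
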