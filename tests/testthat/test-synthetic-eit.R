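test_that("noise-free uniform phantom is a pure superposition of one waveform", {
  spec <- uniform_phantom_spec(amp = 1, rr = 20, duration = 45)
  ph <- generate_phantom(spec)
  m <- sum(spec$lung_amplitude_map > 0)
  mat <- matrix(ph$frames$frames, nrow = dim(ph$frames$frames)[1])
  lung_cols <- which(as.vector(spec$lung_amplitude_map) > 0)
  ref <- mat[, lung_cols[1]]
  for (j in lung_cols[-1]) expect_equal(mat[, j], ref, tolerance = 1e-12)
  curve <- compute_global_curve(ph$frames)
  expect_equal(max(curve$values) - min(curve$values), m * 1, tolerance = 1e-9)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  s1 <- uniform_phantom_spec(noise_sd = 0.1, seed = 42L)
  s2 <- uniform_phantom_spec(noise_sd = 0.1, seed = 42L)
  expect_identical(generate_phantom(s1)$frames$frames,
                   generate_phantom(s2)$frames$frames)
  s3 <- uniform_phantom_spec(noise_sd = 0.1, seed = 43L)
  expect_false(identical(generate_phantom(s1)$frames$frames,
                         generate_phantom(s3)$frames$frames))
})

test_that("analytic ground truth follows the phantom parameters", {
  # uniform 0.5 s delay in a 2.0 s inspiration -> delay map 25% everywhere
  delays <- matrix(0, 32, 32)
  delays[lung_ellipses()] <- 0.5
  spec <- uniform_phantom_spec(rr = 15, frac = 0.5, duration = 60,
                               delay_map = delays)  # T = 4 s, Ti = 2 s
  tr <- generate_phantom(spec)$truth
  expect_true(all(abs(tr$expected_rvd_map[tr$lung_mask] - 25) < 1e-9))
  expect_identical(tr$lung_mask, lung_ellipses())
  expect_equal(tr$expected_tiv, sum(spec$lung_amplitude_map))
  expect_equal(tr$expected_gi, 0)  # uniform amplitude map
  expect_equal(tr$expected_ir, 1, tolerance = 1e-12)  # mirror-symmetric lungs
  expect_equal(tr$expected_rr, 15)
  # per-breath EELI offsets scale with the mask size
  spec2 <- uniform_phantom_spec(eeli = c(0, -0.5), duration = 45)
  tr2 <- generate_phantom(spec2)$truth
  m <- sum(tr2$lung_mask)
  expect_equal(tr2$expected_eeli_offsets[1:2], c(0, -0.5) * m)
})

test_that("phantom spec rejects invalid physiology", {
  expect_error(uniform_phantom_spec(rr = 20, duration = 30), "12")
  a <- matrix(0, 32, 32); a[lung_ellipses()] <- 1; a[16, 16] <- -1
  expect_error(phantom_spec(lung_amplitude_map = a), "negative amplitude")
  d <- matrix(0.1, 32, 32)  # nonzero delay outside the lungs
  expect_error(uniform_phantom_spec(delay_map = d), "zero where the amplitude")
})

test_that("cohort labels follow the deterioration fraction and VT model", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 9L),
                        include_phantoms = FALSE)
  sc <- cohort_scores(co)
  expect_equal(mean(sc$deteriorated), 13 / 31, tolerance = 0.15)
  # VT changes encode the label exactly (drop >= 20 ml iff deteriorated)
  expect_identical(deterioration_label(sc$vt_t0, sc$vt_t2), sc$deteriorated)
  # group-conditional score separation in the designed direction
  expect_gt(mean(sc$gi_score[sc$deteriorated]),
            mean(sc$gi_score[!sc$deteriorated]))
})

test_that("cohort generation is reproducible and refuses degenerate groups", {
  a <- generate_cohort(cohort_spec(n_patients = 20, seed = 5L),
                       include_phantoms = FALSE)
  b <- generate_cohort(cohort_spec(n_patients = 20, seed = 5L),
                       include_phantoms = FALSE)
  expect_identical(cohort_scores(a), cohort_scores(b))
  expect_error(cohort_spec(n_patients = 3), "at least 2")
  expect_error(generate_cohort(cohort_spec(n_patients = 6,
                                           deterioration_fraction = 0.001,
                                           seed = 1L),
                               include_phantoms = FALSE),
               ">= 2 per group")
})

test_that("t1 phantom parameters realize the session effects analytically", {
  co <- generate_cohort(cohort_spec(n_patients = 4, seed = 2L))
  p <- co$patients[[1]]
  tiv0 <- sum(p$specs$t0$lung_amplitude_map)
  tiv1 <- sum(p$specs$t1$lung_amplitude_map)
  expect_equal(tiv1 / tiv0, 0.72, tolerance = 1e-9)
  expect_equal(p$specs$t1$respiratory_rate - p$specs$t0$respiratory_rate, 2.5)
  # t1 per-pixel EELI offset sums to -0.65 baseline TIV over the support
  m <- sum(p$specs$t0$lung_amplitude_map > 0)
  expect_equal(p$specs$t1$eeli_trajectory * m / tiv0, -0.65, tolerance = 1e-9)
  # amplitude maps realize the latent GI (analytic, support = mask)
  a0 <- p$specs$t0$lung_amplitude_map
  g0 <- brute_force_gi(a0[a0 > 0])
  expect_equal(100 * g0, min(max(p$gi_score, 5), 58), tolerance = 1e-6)
})

test_that("theoretical binormal AUC is stored with the cohort", {
  cs <- cohort_spec()
  expect_equal(cs$theoretical_auc,
               pnorm((46 - 41) / sqrt(5.77^2 + 5.77^2)))
  expect_equal(cs$theoretical_auc, 0.73, tolerance = 0.001)
})
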