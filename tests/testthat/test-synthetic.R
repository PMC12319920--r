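test_that("substrate ground truth matches closed-form MD and K0", {
  gt <- karger_ground_truth(karger_substrate(c(0.5, 0.5), c(1.0, 0.5), 50), 20)
  expect_equal(gt$md, 0.75)
  expect_equal(gt$k0, 1 / 3)  # 3 f1 f2 (D1-D2)^2 / MD^2
  one <- karger_ground_truth(karger_substrate(1, 0.7, 50), c(5, 20, 80))
  expect_equal(one$md, 0.7)
  expect_equal(one$mk, c(0, 0, 0))
  expect_error(karger_substrate(c(0.6, 0.5), c(1, 1), 50), "sum to 1")
  expect_error(karger_substrate(c(0.5, 0.5), c(1, -1), 10), "diffusivities")
  # all-zero diffusivities: MD = 0 with zero variance is a valid degenerate case
  zero <- karger_ground_truth(karger_substrate(c(0.5, 0.5), c(0, 0), 10), 5)
  expect_equal(zero$mk, 0)
})

test_that("exchange kurtosis decay matches the series oracle and its limits", {
  k0 <- 0.86; tex <- 53.8
  deltas <- c(9.5, 15, 20, 25, 30)
  sub <- karger_substrate(c(0.5, 0.5), c(1.07479, 0.32521), tex)
  mk <- karger_ground_truth(sub, deltas)$mk
  expect_equal(mk, oracle_karger_mk(karger_ground_truth(sub, 1)$k0, tex, deltas),
               tolerance = 1e-12)
  expect_equal(eval_model("karger_mk", c(K0 = k0, t_ex = tex), 9.5),
               0.8115, tolerance = 5e-4)
  # short-time limit, monotone decrease, K0 ceiling
  grid <- c(1e-6, 1e-3, 1, 5, deltas, 100, 1000)
  v <- eval_model("karger_mk", c(K0 = k0, t_ex = tex), grid)
  expect_lt(abs(v[1] - k0), 1e-6)
  expect_true(all(diff(v) < 0))
  expect_true(all(v <= k0))
  # long-time asymptote 2 K0 t_ex / Delta within 1% at Delta = 100 t_ex
  d <- 100 * tex
  expect_equal(eval_model("karger_mk", c(K0 = k0, t_ex = tex), d),
               2 * k0 * tex / d, tolerance = 0.01)
  # MK depends on Delta only through Delta / t_ex
  a <- eval_model("karger_mk", c(K0 = k0, t_ex = 10), 25)
  b <- eval_model("karger_mk", c(K0 = k0, t_ex = 40), 100)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless synthesis is deterministic and exact at b0", {
  sub <- karger_substrate(c(0.5, 0.5), c(1.1, 0.3), 45)
  ph <- phantom_spec(c(3, 3, 1), rep(1L, 9),
                     list(r = list(label = 1L, rest = sub, stimulus = sub,
                                   snr = 12)), s0 = 80)
  sch <- build_default_scheme(15)
  sched <- schedule_block(block_design(3, 28, 28, 2), sch)
  s1 <- synthesize_dwi(ph, sch, sched, seed = 1, noise = FALSE)
  s2 <- synthesize_dwi(ph, sch, sched, seed = 999, noise = FALSE)
  expect_identical(s1, s2)
  b0_cols <- which(sched$measurement_id %in% 1:3)
  expect_true(all(s1[, b0_cols] == 80))
  # with noise: same seed reproduces, different seed does not
  n1 <- synthesize_dwi(ph, sch, sched, seed = 7)
  n2 <- synthesize_dwi(ph, sch, sched, seed = 7)
  n3 <- synthesize_dwi(ph, sch, sched, seed = 8)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("Rician noise biases the b0 magnitude upward by less than 1.5% at SNR 20", {
  sub <- karger_substrate(1, 0.7, 50)
  nv <- 4000L
  ph <- phantom_spec(c(nv, 1, 1), rep(1L, nv),
                     list(r = list(label = 1L, rest = sub, stimulus = sub,
                                   snr = 20)), s0 = 100)
  sch <- build_default_scheme(15)
  sched <- schedule_block(block_design(3, 28, 28, 2), sch)
  series <- synthesize_dwi(ph, sch, sched, seed = 3)
  b0 <- series[, sched$measurement_id %in% 1:3]
  bias <- mean(b0) - 100
  expect_gt(bias, 0)
  expect_lt(bias / 100, 0.015)
})

test_that("BOLD synthesis follows its boxcar + drift + noise contract", {
  d <- block_design(6, 28, 28, 1)
  flat <- synthesize_bold(bold_series_spec(d, baseline = 100,
                                           amplitude_pct = 0))
  expect_true(all(flat == 100))
  box <- synthesize_bold(bold_series_spec(d, amplitude_pct = 1.2))
  sched <- schedule_block(d, 1)
  expect_true(all(box[sched$condition == "stimulus"] == 101.2))
  expect_true(all(box[sched$condition == "rest"] == 100))
  a <- synthesize_bold(bold_series_spec(d, amplitude_pct = 1, noise_pct = 2,
                                        seed = 5))
  b <- synthesize_bold(bold_series_spec(d, amplitude_pct = 1, noise_pct = 2,
                                        seed = 5))
  expect_identical(a, b)
})

test_that("substrate perturbation hits its MD / MK percent targets", {
  base <- karger_substrate(c(0.5, 0.5), c(1.07479, 0.32521), 53.8)
  for (tgt in list(c(-1.1, -4.9), c(1.9, 2.4), c(0, 0), c(1.5, 11))) {
    pert <- perturb_substrate(base, tgt[1], tgt[2], delta_ref = 20)
    g0 <- karger_ground_truth(base, 20)
    g1 <- karger_ground_truth(pert, 20)
    expect_equal(100 * (g1$md / g0$md - 1), tgt[1], tolerance = 1e-8)
    expect_equal(100 * (g1$mk / g0$mk - 1), tgt[2], tolerance = 1e-6)
  }
  # MK decrease implemented through a shorter exchange time
  pert <- perturb_substrate(base, 0, -4.9, delta_ref = 20)
  expect_lt(pert$t_ex, base$t_ex)
})

test_that("study manifest reproduces the run arithmetic of the design", {
  st <- make_study(default_study_config(grid = c(6, 6, 2)), seed = 1)
  expect_equal(nrow(st$runs), 48L)  # 10 rats x 5 runs, two rats with 4
  expect_equal(sum(st$runs$laterality == "contra"), 24L)
  expect_equal(length(st$deltas), 5L)
  # smallest study: every series accessible, deterministic under the seed
  st1 <- make_study(tiny_config(n_rats = 2L, runs_per_rat = 1L), seed = 9)
  s_a <- study_dwi_series(st1, 1, 9.5)
  st2 <- make_study(tiny_config(n_rats = 2L, runs_per_rat = 1L), seed = 9)
  expect_identical(s_a, study_dwi_series(st2, 1, 9.5))
  expect_false(identical(s_a, study_dwi_series(st1, 2, 9.5)))
  expect_equal(dim(study_bold_series(st1, 1)), c(300L, 336L))
})
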