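test_that("two-shell closed form inverts the cumulant model exactly", {
  # D = 0.7, K = 0.6 forward-evaluated by hand: y = bD - b^2 D^2 K / 6
  est <- two_shell_closed_form(0.651, 1.204, 1, 2)
  expect_equal(est$d, 0.7)
  expect_equal(est$k, 0.6)
  # monoexponential decay gives zero kurtosis
  est0 <- two_shell_closed_form(0.5, 1.0, 1, 2)
  expect_equal(est0$d, 0.5)
  expect_equal(est0$k, 0)
  # flat attenuation (y1 = y2): strong upward curvature, positive kurtosis,
  # and a b->0 slope above the b1 secant (D = 1.5 y1 / b1 for b = 1, 2)
  y <- 0.4
  estf <- two_shell_closed_form(y, y, 1, 2)
  expect_gt(estf$k, 0)
  expect_gt(estf$d, y / 1)
  expect_equal(estf$d, 1.5 * y)
  # signal increasing with b: flagged negative diffusivity
  estn <- two_shell_closed_form(-0.1, -0.3, 1, 2)
  expect_true(estn$flag)
})

test_that("direction-set gate passes the shipped set and rejects bad ones", {
  rep <- verify_direction_set(default_directions())
  expect_true(rep$pass)
  expect_lt(rep$residual_2nd, 1e-9)
  expect_lt(rep$residual_4th, 1e-9)
  # 3 axes + 6 face diagonals: isotropic to 2nd order but <nx^4>/<nx^2 ny^2> = 4
  axes <- diag(3)
  diag6 <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                 c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  bad <- verify_direction_set(rbind(axes, diag6))
  expect_false(bad$pass)
  expect_lt(bad$residual_2nd, 1e-9)
  expect_gt(bad$residual_4th, 1e-3)
  expect_error(verify_direction_set(diag(3)), "at least 9")
})

test_that("estimation is the exact inverse of noiseless cumulant signals", {
  md <- 0.67; mk <- 0.60
  sub <- karger_substrate(c(0.5, 0.5), c(md + sqrt(mk / 3) * md,
                                         md - sqrt(mk / 3) * md), 1e9)
  gt <- karger_ground_truth(sub, 20)
  expect_equal(gt$md, md, tolerance = 1e-12)
  expect_equal(gt$mk, mk, tolerance = 1e-6)
  ph <- phantom_spec(c(2, 2, 1), rep(1L, 4),
                     list(r = list(label = 1L, rest = sub, stimulus = sub,
                                   snr = 20)), s0 = 100)
  sch <- build_default_scheme(20)
  sched <- schedule_block(block_design(3, 28, 28, 2), sch)
  sets <- average_conditions(synthesize_dwi(ph, sch, sched, noise = FALSE),
                             sched, sch)
  for (conv in c("tensor-mean", "plain-mean")) {
    map <- estimate_md_mk(sets$rest, sch, mk_convention = conv)
    expect_equal(map$md, rep(gt$md, 4), tolerance = 1e-9)
    expect_equal(map$mk, rep(gt$mk, 4), tolerance = 1e-9)
    expect_true(all(map$valid))
  }
})

test_that("anisotropic voxels agree with a 60-direction full-tensor oracle", {
  set.seed(13)
  # two-tensor mixture: anisotropic D and a full kurtosis tensor
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  D1 <- R %*% diag(c(1.6, 0.4, 0.3)) %*% t(R)
  D2 <- R %*% diag(c(0.5, 0.9, 0.25)) %*% t(R)
  mix <- oracle_mixture_tensors(0.45, D1, D2)
  ph <- phantom_spec(c(1, 1, 1), 1L,
                     list(r = list(label = 1L,
                                   rest = karger_substrate(1, mix$md, 50),
                                   stimulus = karger_substrate(1, mix$md, 50),
                                   snr = 20, tensor = mix$D,
                                   wtensor = mix$W)), s0 = 100)
  sch <- build_default_scheme(20)
  sched <- schedule_block(block_design(3, 28, 28, 2), sch)
  sets <- average_conditions(synthesize_dwi(ph, sch, sched, noise = FALSE),
                             sched, sch)
  map <- estimate_md_mk(sets$rest, sch)
  # oracle: 60 directions x 3 shells, brute-force linear DKI fit
  dirs60 <- oracle_sphere_dirs(60)
  bv <- rep(c(0.5, 1, 2), each = 60)
  dd <- rbind(dirs60, dirs60, dirs60)
  lnS <- -bv * oracle_dn(mix$D, dd) +
    (bv^2 * mix$md^2 / 6) * oracle_wn(mix$W, dd)
  orc <- oracle_dki_fit(100 * exp(lnS), 100, bv, dd)
  expect_equal(map$md, sum(diag(mix$D)) / 3, tolerance = 1e-6)
  expect_equal(map$md, orc$md, tolerance = 1e-6)
  expect_equal(map$mk, orc$wbar, tolerance = 1e-6)
})

test_that("unphysical voxels are excluded by the validity mask", {
  map <- structure(list(md = c(0.7, 0.6, -0.1, 0.5),
                        mk = c(0.6, -0.1, 0.4, NaN),
                        valid = rep(TRUE, 4),
                        condition = "rest", delta_big = 20,
                        mk_convention = "tensor-mean", dims = NULL),
                   class = "parametric_map")
  out <- mask_unphysical(map)
  expect_equal(out$valid, c(TRUE, FALSE, FALSE, FALSE))
  # an all-noise voxel whose signal grows with b yields negative D -> masked
  sch <- build_default_scheme(20)
  sched <- schedule_block(block_design(3, 28, 28, 2), sch)
  sub <- karger_substrate(1, 0.7, 50)
  ph <- phantom_spec(c(1, 1, 1), 1L,
                     list(r = list(label = 1L, rest = sub, stimulus = sub,
                                   snr = 20)), s0 = 100)
  sets <- average_conditions(synthesize_dwi(ph, sch, sched, noise = FALSE),
                             sched, sch)
  sets$rest$dwi[] <- 150  # above S0: signal "increases" with b
  bad <- mask_unphysical(estimate_md_mk(sets$rest, sch))
  expect_false(any(bad$valid))
})

test_that("masked-voxel fraction at low SNR is nonzero and falls with SNR", {
  sub <- karger_substrate(c(0.5, 0.5), c(1.07479, 0.32521), 53.8)
  frac <- vapply(c(10, 15, 20), function(snr) {
    nv <- 3000L
    ph <- phantom_spec(c(nv, 1, 1), rep(1L, nv),
                       list(r = list(label = 1L, rest = sub, stimulus = sub,
                                     snr = snr)), s0 = 100)
    sch <- build_default_scheme(30)
    sched <- schedule_block(block_design(3, 28, 28, 2), sch)
    sets <- average_conditions(synthesize_dwi(ph, sch, sched, seed = 21),
                               sched, sch)
    map <- mask_unphysical(estimate_md_mk(sets$rest, sch))
    mean(!map$valid)
  }, numeric(1))
  expect_gt(frac[1], 0)
  expect_true(all(diff(frac) < 0))
})
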