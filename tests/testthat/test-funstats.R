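test_that("percent change and its max-amplitude convention behave", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1.000, 0.989), -1.1)
  expect_warning(pc <- percent_change(0, 1), "zero rest mean")
  expect_true(is.na(pc))
  mx <- max_abs_change(c(0.2, -1.1, 0.9, -0.3, 0.5), c(9.5, 15, 20, 25, 30))
  expect_equal(mx$value, -1.1)
  expect_equal(mx$delta_big, 15)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(fdr_adjust(0.013), 0.013)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    q <- fdr_adjust(p)
    expect_true(all(q >= p))               # step-up can only inflate
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12)) # monotone in sorted order
  }
})

test_that("ROI aggregation respects the validity mask", {
  labels <- rep(c(1L, 2L), each = 10)
  map <- structure(list(md = rep(c(0.7, 0.8), each = 10),
                        mk = rep(0.6, 20),
                        valid = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
                        condition = "rest", delta_big = 15,
                        mk_convention = "tensor-mean", dims = NULL),
                   class = "parametric_map")
  rows <- roi_aggregate(map, labels, c(a = 1L, b = 2L), run = 1, subject = 1,
                        laterality = "contra")
  a_md <- rows[rows$roi == "a" & rows$metric == "MD", ]
  expect_equal(a_md$mean, 0.7)
  expect_equal(a_md$sd, 0)
  expect_equal(rows$n_vox[rows$roi == "b"][1], 5L)  # half masked out
  map$valid[11:20] <- FALSE
  expect_warning(roi_aggregate(map, labels, c(a = 1L, b = 2L)), "empty")
})

test_that("mixed-effects condition test rejects at the injected effect and guards preconditions", {
  make_rows <- function(effect, seed) {
    with_seed(seed, {
      grid <- expand.grid(subject = 1:4, run_in = 1:4,
                          delta_big = c(9.5, 15, 20, 25, 30),
                          condition = c("rest", "stimulus"))
      grid$run <- paste(grid$subject, grid$run_in)
      bs <- rnorm(4, 0, 0.004)[grid$subject]
      br <- rnorm(16, 0, 0.004)[as.integer(factor(grid$run))]
      grid$mean <- 0.7 + 0.002 * as.integer(factor(grid$delta_big)) +
        bs + br + rnorm(nrow(grid), 0, 0.004) +
        ifelse(grid$condition == "stimulus", effect, 0)
      grid
    })
  }
  out <- condition_mixed_test(make_rows(-0.007, 11))  # a -1% MD effect
  expect_lt(out$p, 0.001)
  single <- make_rows(0, 1)
  single <- single[single$subject == 1, ]
  expect_error(condition_mixed_test(single), "2 subjects")
})

test_that("epoch normalization and condition averaging follow the baseline convention", {
  d <- block_design(6, 28, 28, 1)
  const <- rep(250, 336)
  nrm <- bold_epoch_normalize(const, d)
  expect_true(all(nrm$response == 1))
  box <- synthesize_bold(bold_series_spec(d, amplitude_pct = 1.2))
  nb <- bold_epoch_normalize(box, d)
  expect_true(all(abs(nb$response[nb$stim_window] - 1.012) < 1e-12))
  avg <- bold_condition_average(box, d)
  expect_equal(avg$change_pct, 1.2, tolerance = 1e-9)
  expect_equal(avg$rest_mean, 1)
  # drift only: baseline level removed, within-epoch slope remains
  drift <- synthesize_bold(bold_series_spec(d, amplitude_pct = 0,
                                            drift_pct_per_min = 3))
  nd <- bold_epoch_normalize(drift, d)
  base_idx <- which(nd$time >= 14 & nd$time < 28)
  expect_equal(mean(nd$response[base_idx]), 1, tolerance = 1e-6)
  expect_gt(nd$response[56] - nd$response[1], 0)
  # swapped condition roles flip the sign of the change
  swapped <- rep(100, 336)
  sched <- schedule_block(d, 1)
  swapped[sched$condition == "rest"] <- 101.2
  expect_lt(bold_condition_average(swapped, d)$change_pct, 0)
})

test_that("high-pass filtering removes slow drift but keeps the boxcar", {
  d <- block_design(6, 28, 28, 1)
  drifty <- synthesize_bold(bold_series_spec(d, amplitude_pct = 1.2,
                                             drift_pct_per_min = 2))
  sched <- schedule_block(d, 1)
  box <- as.numeric(sched$condition == "stimulus")
  filt <- highpass_dct(drifty, 1, protect = box)
  diffs <- mean(filt[box == 1]) - mean(filt[box == 0])
  expect_equal(diffs, 1.2, tolerance = 1e-6)
  resid_drift <- coef(lm(filt ~ sched$time + box))[2]
  expect_lt(abs(resid_drift), 1e-9)
  # drift-only series: the protected boxcar absorbs none of the drift
  null_series <- synthesize_bold(bold_series_spec(d, amplitude_pct = 0,
                                                  drift_pct_per_min = 2))
  nf <- highpass_dct(null_series, 1, protect = box)
  expect_lt(abs(mean(nf[box == 1]) - mean(nf[box == 0])), 1e-9)
})

test_that("boxcar GLM detects exact activation and controls family-wise error", {
  d <- block_design(6, 28, 28, 1)
  sched <- schedule_block(d, 1)
  nv <- 60L
  box <- as.numeric(sched$condition == "stimulus")
  # noise-free activation in voxels 1:10 -> the mask is exactly that block
  series <- matrix(100, nv, 336)
  series[1:10, ] <- 100 + outer(rep(2, 10), box)
  res <- bold_glm(series, d, dims = c(nv, 1, 1))
  expect_equal(which(res$active), 1:10)
  expect_equal(res$cluster_sizes, 10L)
  # pure noise: familywise false-positive rate stays near the nominal level
  fp <- vapply(1:200, function(i) {
    noise <- with_seed(6000 + i, matrix(rnorm(nv * 336, 100, 1), nv))
    any(bold_glm(noise, d)$active)
  }, logical(1))
  expect_lte(mean(fp), 0.08)
  # power grows with amplitude
  det <- vapply(c(0.05, 0.15, 0.4), function(a) {
    s <- with_seed(77, matrix(rnorm(nv * 336, 100, 1), nv)) +
      outer(rep(a, nv), box)
    mean(bold_glm(s, d)$active)
  }, numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("the depth mask drops voxels below 10% of the cortical signal", {
  d <- block_design(6, 28, 28, 1)
  series <- matrix(100, 20, 336)
  series[16:20, ] <- 5  # deep voxels at 5% of cortex
  res <- bold_glm(series, d, cortex_mask = c(rep(TRUE, 15), rep(FALSE, 5)))
  expect_true(all(res$analysis_mask[1:15]))
  expect_false(any(res$analysis_mask[16:20]))
})
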