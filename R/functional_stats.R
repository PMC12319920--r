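#' Aggregate a parametric map (or series) over ROIs
#'
#' Per-ROI mean, SD and SE over valid voxels only. Empty ROIs (after
#' masking) are dropped with a warning.
#'
#' @param map a \code{parametric_map}, or a numeric voxel vector.
#' @param labels integer label vector aligned with the voxel grid.
#' @param roi_names optional named integer vector mapping names to labels.
#' @param run,subject,laterality annotations copied into the rows.
#' @return data.frame rows: roi, metric, condition, delta_big, run,
#'   subject, laterality, mean, sd, se, n_vox.
#' @export
roi_aggregate <- function(map, labels, roi_names = NULL,
                          run = NA, subject = NA, laterality = NA) {
  if (inherits(map, "parametric_map")) {
    vals <- list(MD = map$md, MK = map$mk)
    valid <- map$valid
    condition <- map$condition; delta_big <- map$delta_big
  } else {
    vals <- list(value = as.numeric(map))
    valid <- rep(TRUE, length(vals[[1]]))
    condition <- NA_character_; delta_big <- NA_real_
  }
  if (is.null(roi_names)) {
    labs <- setdiff(sort(unique(labels)), 0L)
    roi_names <- setNames(labs, paste0("roi", labs))
  }
  rows <- list()
  for (metric in names(vals)) {
    v <- vals[[metric]]
    for (nm in names(roi_names)) {
      sel <- labels == roi_names[[nm]] & valid & is.finite(v)
      if (!any(sel)) {
        warning("ROI '", nm, "' empty after masking; row dropped")
        next
      }
      x <- v[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        roi = nm, metric = metric, condition = condition,
        delta_big = delta_big, run = run, subject = subject,
        laterality = laterality, mean = mean(x), sd = sd(x),
        se = sd(x) / sqrt(length(x)), n_vox = length(x))
    }
  }
  do.call(rbind, rows)
}

#' Percent signal change, stimulus relative to rest
#'
#' @param rest_mean,stim_mean condition means (vectors allowed).
#' @return \code{100 (stim - rest) / rest}; NA with a warning where the rest
#'   mean is zero.
#' @export
percent_change <- function(rest_mean, stim_mean) {
  out <- 100 * (stim_mean - rest_mean) / rest_mean
  if (any(rest_mean == 0)) {
    warning("zero rest mean: percent change undefined")
    out[rest_mean == 0] <- NA_real_
  }
  out
}

#' Signed maximum-amplitude change across diffusion times
#'
#' @param changes percent changes, one per diffusion time.
#' @param delta_big the diffusion times.
#' @return list \code{value} (the elementwise-maximum |change|, sign kept)
#'   and \code{delta_big} (where it occurs).
#' @export
max_abs_change <- function(changes, delta_big) {
  i <- which.max(abs(changes))
  list(value = changes[i], delta_big = delta_big[i])
}

#' Mixed-effects rest-vs-stimulus test for one ROI / metric
#'
#' Fits a linear mixed model with condition and diffusion time (categorical)
#' as fixed effects and random intercepts for run and subject, and returns
#' the condition-effect p-value from a likelihood-ratio test of nested ML
#' fits. If the full fit fails or is singular, random terms are dropped in
#' turn (run first, then subject, finally a fixed-effects-only fit); the
#' diffusion-time fixed effect is always retained so that time-dependence
#' variance cannot leak into the condition contrast. The fallback level is
#' flagged in the result.
#'
#' @param rows data.frame with columns \code{mean} (or \code{value}),
#'   \code{condition}, \code{delta_big}, \code{run}, \code{subject}.
#' @param require_groups if TRUE (default) error when fewer than 2 subjects
#'   or runs are present.
#' @return list \code{p}, \code{statistic} (LRT chi-square), \code{df},
#'   \code{fallback} (0 = full model).
#' @export
condition_mixed_test <- function(rows, require_groups = TRUE) {
  val <- if ("mean" %in% names(rows)) rows$mean else rows$value
  dat <- data.frame(y = val,
                    condition = factor(rows$condition),
                    run = factor(rows$run),
                    subject = factor(rows$subject))
  has_delta <- "delta_big" %in% names(rows) &&
    length(unique(rows$delta_big[!is.na(rows$delta_big)])) > 1L
  if (has_delta) dat$delta <- factor(rows$delta_big)
  if (nlevels(dat$condition) != 2L)
    stop("both conditions must be present")
  if (require_groups &&
      (nlevels(dat$subject) < 2L || nlevels(dat$run) < 2L))
    stop("need at least 2 subjects and 2 runs for the mixed model")
  fx <- if (has_delta) "delta" else "1"
  forms <- list(
    c(sprintf("y ~ condition + %s + (1|run) + (1|subject)", fx),
      sprintf("y ~ %s + (1|run) + (1|subject)", fx)),
    c(sprintf("y ~ condition + %s + (1|subject)", fx),
      sprintf("y ~ %s + (1|subject)", fx)))
  for (lvl in seq_along(forms)) {
    res <- tryCatch({
      full <- suppressMessages(lme4::lmer(as.formula(forms[[lvl]][1]),
                                          data = dat, REML = FALSE))
      if (lme4::isSingular(full, tol = 1e-5)) stop("singular fit")
      null <- suppressMessages(lme4::lmer(as.formula(forms[[lvl]][2]),
                                          data = dat, REML = FALSE))
      lrt <- anova(null, full)
      list(p = lrt$`Pr(>Chisq)`[2], statistic = lrt$Chisq[2],
           df = lrt$Df[2], fallback = lvl - 1L)
    }, error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  # fixed-effects-only last resort
  f1 <- lm(as.formula(sprintf("y ~ condition + %s", fx)), data = dat)
  f0 <- lm(as.formula(sprintf("y ~ %s", fx)), data = dat)
  lrt <- anova(f0, f1)
  list(p = lrt$`Pr(>F)`[2], statistic = lrt$F[2], df = 1L, fallback = 2L)
}

#' Benjamini-Hochberg FDR adjustment for one metric family
#'
#' @param pvalues p-values of one family (one metric's ROI set).
#' @return step-up q-values in input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  p.adjust(pvalues, method = "BH")
}

.stars <- function(q) ifelse(q < 0.001, "***",
                      ifelse(q < 0.01, "**",
                       ifelse(q < 0.05, "*", "")))

#' ROI-level rest-vs-stimulus change report
#'
#' For each ROI and metric: the percent change per diffusion time (from
#' condition means pooled across runs), the signed maximum-amplitude change
#' across diffusion times, the mixed-model condition p-value, and the FDR
#' q-value (BH within each metric family) with significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param roi_table rows from \code{\link{roi_aggregate}} across runs,
#'   diffusion times and conditions (one laterality group).
#' @param alpha significance level applied to q-values.
#' @return a \code{change_report}: list with \code{per_delta} (long
#'   data.frame of percent changes) and \code{summary} (one row per
#'   roi x metric: max_change, at_delta, p, q, stars, significant).
#' @export
change_report <- function(roi_table, alpha = 0.05) {
  stopifnot(all(c("roi", "metric", "condition", "mean") %in% names(roi_table)))
  combos <- unique(roi_table[, c("roi", "metric")])
  per_delta <- list(); summ <- list()
  for (i in seq_len(nrow(combos))) {
    roi <- combos$roi[i]; metric <- combos$metric[i]
    sub <- roi_table[roi_table$roi == roi & roi_table$metric == metric, ]
    deltas <- sort(unique(sub$delta_big))
    ch <- vapply(deltas, function(d) {
      r <- mean(sub$mean[sub$delta_big == d & sub$condition == "rest"])
      s <- mean(sub$mean[sub$delta_big == d & sub$condition == "stimulus"])
      percent_change(r, s)
    }, numeric(1))
    per_delta[[i]] <- data.frame(roi = roi, metric = metric,
                                 delta_big = deltas, change_pct = ch)
    mx <- max_abs_change(ch, deltas)
    tst <- condition_mixed_test(sub)
    summ[[i]] <- data.frame(roi = roi, metric = metric,
                            max_change_pct = mx$value,
                            at_delta = mx$delta_big,
                            p = tst$p, fallback = tst$fallback)
  }
  summ <- do.call(rbind, summ)
  summ$q <- NA_real_
  for (metric in unique(summ$metric)) {
    sel <- summ$metric == metric
    summ$q[sel] <- fdr_adjust(summ$p[sel])
  }
  summ$stars <- .stars(summ$q)
  summ$significant <- summ$q < alpha
  structure(list(per_delta = do.call(rbind, per_delta), summary = summ,
                 alpha = alpha),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  s <- x$summary
  cat("Rest vs. stimulus amplitude changes (max |%| across diffusion times)\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %-4s %+6.2f%% (Delta = %g ms)  q = %.3g %s\n",
                s$roi[i], s$metric[i], s$max_change_pct[i], s$at_delta[i],
                s$q[i], s$stars[i]))
  invisible(x)
}

#' Normalize BOLD epochs to their pre-stimulus baseline
#'
#' Each epoch is divided by the mean signal over the \code{baseline_s}
#' seconds immediately preceding stimulation; the response function is the
#' pointwise mean across epochs.
#'
#' @param series numeric vector (one value per volume).
#' @param design the \code{\link{block_design}} of the series.
#' @param baseline_s baseline window length, s.
#' @return list \code{epochs} (epochs x samples-per-epoch matrix of
#'   normalized signal), \code{response} (pointwise mean across epochs),
#'   \code{time} (s within epoch), \code{stim_window} (logical per sample).
#' @export
bold_epoch_normalize <- function(series, design, baseline_s = 14) {
  sched <- schedule_block(design, design$tr)
  if (length(series) != nrow(sched))
    stop("series length ", length(series), " does not match the design (",
         nrow(sched), " volumes)")
  per <- as.integer(round((design$rest_s + design$stim_s) / design$tr))
  n_base <- as.integer(round(baseline_s / design$tr))
  if (n_base < 1 || baseline_s > design$rest_s)
    stop("baseline window must fit inside the rest interval")
  epochs <- matrix(series, nrow = design$n_epochs, ncol = per, byrow = TRUE)
  t_in <- (seq_len(per) - 1) * design$tr
  base_idx <- which(t_in >= design$rest_s - baseline_s & t_in < design$rest_s)
  keep <- rep(TRUE, design$n_epochs)
  for (e in seq_len(design$n_epochs)) {
    b <- mean(epochs[e, base_idx])
    if (!is.finite(b) || b == 0) {
      warning("epoch ", e, " has no usable baseline; dropped")
      keep[e] <- FALSE
    } else epochs[e, ] <- epochs[e, ] / b
  }
  epochs <- epochs[keep, , drop = FALSE]
  list(epochs = epochs, response = colMeans(epochs), time = t_in,
       stim_window = t_in >= design$rest_s)
}

#' Condition-averaged BOLD amplitudes
#'
#' Averages the baseline-normalized signal across all rest and all stimulus
#' timepoints, yielding one amplitude estimate (+/- SE across epochs) per
#' condition, the percent change, and a paired condition test across
#' epochs.
#'
#' @param series numeric vector.
#' @param design the \code{\link{block_design}}.
#' @param baseline_s baseline window, s.
#' @return list \code{rest_mean}, \code{stim_mean}, \code{rest_se},
#'   \code{stim_se}, \code{change_pct}, \code{p}, and per-epoch condition
#'   means (\code{epoch_rest}, \code{epoch_stim}).
#' @export
bold_condition_average <- function(series, design, baseline_s = 14) {
  nrm <- bold_epoch_normalize(series, design, baseline_s)
  stim <- nrm$stim_window
  er <- rowMeans(nrm$epochs[, !stim, drop = FALSE])
  es <- rowMeans(nrm$epochs[, stim, drop = FALSE])
  rest_mean <- mean(er); stim_mean <- mean(es)
  p <- if (length(er) >= 2 && sd(es - er) > 0)
    t.test(es, er, paired = TRUE)$p.value else NA_real_
  list(rest_mean = rest_mean, stim_mean = stim_mean,
       rest_se = sd(er) / sqrt(length(er)),
       stim_se = sd(es) / sqrt(length(es)),
       change_pct = percent_change(rest_mean, stim_mean), p = p,
       epoch_rest = er, epoch_stim = es)
}

#' High-pass filter a time series with a discrete cosine basis
#'
#' Regresses out cosine components below the cutoff frequency (drifts and
#' other slow trends) and restores the series mean. Mirrors the 0.01 Hz
#' high-pass applied to BOLD time courses before quantification.
#'
#' @param series numeric vector, or matrix with time along columns.
#' @param tr sample spacing, s.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param protect optional regressors (e.g. the task boxcar) included in the
#'   drift fit but not removed, so that drift estimation cannot absorb
#'   task-locked signal. Vector or column matrix, one row per timepoint.
#' @export
highpass_dct <- function(series, tr, cutoff_hz = 0.01, protect = NULL) {
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, 1) else as.matrix(series)
  drift <- .drift_basis(ncol(m), tr, cutoff_hz)
  X <- cbind(1, drift)
  n_keep <- 1L
  if (!is.null(protect)) {
    X <- cbind(1, protect, drift)
    n_keep <- 1L + NCOL(protect)
  }
  beta <- qr.coef(qr(X), t(m))
  drift_part <- t(X[, -seq_len(n_keep), drop = FALSE] %*%
                    beta[-seq_len(n_keep), , drop = FALSE])
  m <- m - drift_part
  if (vec) as.numeric(m) else m
}

# nuisance regressors for slow signal drift: a linear trend plus discrete
# cosine components below the cutoff frequency
.drift_basis <- function(n_t, tr, cutoff_hz = 0.01) {
  lin <- seq_len(n_t) - (n_t + 1) / 2
  cbind(lin / n_t, .dct_basis(n_t, tr, cutoff_hz))
}

# discrete cosine high-pass basis: components with frequency below cutoff_hz
.dct_basis <- function(n_t, tr, cutoff_hz = 0.01) {
  t <- seq_len(n_t) - 0.5
  n_comp <- max(0L, floor(2 * n_t * tr * cutoff_hz))
  if (n_comp == 0L) return(NULL)
  sapply(seq_len(n_comp), function(k) cos(pi * k * t / n_t))
}

#' Voxel-wise boxcar GLM on a BOLD series with FWE thresholding
#'
#' Least squares of each voxel's time course on [intercept, boxcar], with a
#' discrete-cosine high-pass basis (cutoff 0.01 Hz) absorbing slow drifts.
#' Significance by two-sided t-test with Bonferroni family-wise correction
#' over in-mask voxels at \code{alpha}; no cluster-size threshold. Voxels
#' whose mean signal falls below 10 percent of the mean cortical signal are
#' excluded first (surface-coil depth mask).
#'
#' @param series matrix, voxels x timepoints.
#' @param design the \code{\link{block_design}}.
#' @param mask logical analysis mask per voxel.
#' @param cortex_mask logical mask defining the cortical reference signal
#'   for the 10 percent depth cut (default: the analysis mask itself).
#' @param alpha FWE level.
#' @param cutoff_hz high-pass cutoff, Hz.
#' @param dims optional grid dims for cluster labelling.
#' @return a \code{glm_result}: \code{beta} (boxcar coefficient), \code{t},
#'   \code{p_fwe}, \code{active} (logical), \code{analysis_mask},
#'   \code{cluster_sizes}.
#' @export
bold_glm <- function(series, design, mask = NULL, cortex_mask = NULL,
                     alpha = 0.05, cutoff_hz = 0.01, dims = NULL) {
  series <- as.matrix(series)
  sched <- schedule_block(design, design$tr)
  if (ncol(series) != nrow(sched))
    stop("series has ", ncol(series), " timepoints but the design schedules ",
         nrow(sched))
  nv <- nrow(series)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (is.null(cortex_mask)) cortex_mask <- mask
  mean_sig <- rowMeans(series)
  depth_ok <- mean_sig >= 0.10 * mean(mean_sig[cortex_mask])
  amask <- mask & depth_ok
  box <- as.numeric(sched$condition == "stimulus")
  X <- cbind(1, box, .drift_basis(ncol(series), design$tr, cutoff_hz))
  qrX <- qr(X)
  coefs <- t(qr.coef(qrX, t(series[amask, , drop = FALSE])))
  resid <- series[amask, , drop = FALSE] - coefs %*% t(X)
  dfree <- ncol(series) - ncol(X)
  s2 <- rowSums(resid^2) / dfree
  xtxi <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(s2 * xtxi[2, 2], 0))
  beta <- coefs[, 2]
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * pt(abs(tval), dfree, lower.tail = FALSE)
  p_fwe <- pmin(p * sum(amask), 1)
  beta_full <- t_full <- p_full <- rep(NA_real_, nv)
  beta_full[amask] <- beta; t_full[amask] <- tval; p_full[amask] <- p_fwe
  active <- !is.na(p_full) & p_full < alpha
  cl <- if (!is.null(dims)) .cluster_sizes(active, dims) else
    if (any(active)) sum(active) else integer(0)
  structure(list(beta = beta_full, t = t_full, p_fwe = p_full,
                 active = active, analysis_mask = amask,
                 cluster_sizes = cl, alpha = alpha),
            class = "glm_result")
}

# 6-connected component sizes of a logical volume
.cluster_sizes <- function(active, dims) {
  arr <- array(active, dims)
  lab <- array(0L, dims); cur <- 0L
  idx <- which(arr)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[d] <- nb[d] + s
        if (nb[d] < 1L || nb[d] > dims[d]) next
        j <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (arr[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  if (cur == 0L) integer(0) else tabulate(lab[lab > 0L], cur)
}
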