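#' Default study configuration
#'
#' Encodes the study conditions the simulator emulates: 10 rats with 5
#' functional runs each (two rats contribute only 4), forepaw alternating
#' between runs; per run, five diffusion acquisitions at Delta = 9.5, 15,
#' 20, 25, 30 ms (3 epochs of 28 s rest / 28 s stimulus at TR = 2 s; 84
#' volumes each) and one BOLD series (6 epochs at TR = 1 s; 336 volumes).
#' Regions mimic the somatosensory ROI vocabulary with region-specific
#' rest-vs-stimulus effects (MD/MK decrease in the S1FL-like region,
#' increases in S2-like and subcortical-like regions, null in control
#' regions) and a surface-coil-like b0 SNR profile from 20 (cortex) down to
#' 10 (deep regions). The baseline substrate is a two-compartment exchange
#' medium with MD = 0.70 um^2/ms, K0 = 0.86 and t_ex = 53.8 ms.
#'
#' The \code{md_*} / \code{mk_*} columns are the target percent changes the
#' *measured* (estimated) maps should show. Rician noise plus the
#' unphysical-voxel mask attenuate estimated contrasts at low SNR, so the
#' generator divides each target by a frozen attenuation gain
#' (\code{gain_md}, \code{gain_mk}; calibrated once per SNR level by
#' large-voxel Monte Carlo at the reference diffusion time) when building
#' the stimulus substrates.
#'
#' @param grid voxel grid dimensions (the region sizes scale with it).
#' @return a config list consumed by \code{\link{make_study}}.
#' @export
default_study_config <- function(grid = c(20, 20, 6)) {
  regions <- data.frame(
    name  = c("s1fl", "s2", "tha", "cpu", "hip", "m2", "rsc"),
    label = 1:7,
    share = c(300, 300, 600, 400, 400, 200, 200) / 2400,
    snr   = c(20, 20, 10, 15, 12, 20, 20),
    class = c("cortical", "cortical", "deep", "intermediate",
              "intermediate", "cortical", "cortical"),
    md_contra = c(-1.1, 1.5, 1.9, 1.3, 1.4, 0, 0),
    mk_contra = c(-4.9, 0.0, 2.4, 1.8, 2.2, 0, 0),
    md_ipsi   = c(-0.6, 1.6, 1.9, 1.3, 1.4, 0, 0),
    mk_ipsi   = c( 0.0, 3.1, 2.4, 1.8, 0.0, 0, 0),
    # estimator attenuation at this SNR (measured change / injected change)
    gain_md = c(0.943, 0.943, 0.728, 0.864, 0.787, 0.943, 0.943),
    gain_mk = c(0.949, 0.949, 0.465, 0.779, 0.605, 0.949, 0.949),
    bold_contra = c(1.2, 0.3, 0, -0.1, 0, 0, 0),
    bold_ipsi   = c(0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  list(
    n_rats = 10L, runs_per_rat = 5L, short_rats = 2L,
    deltas = c(9.5, 15, 20, 25, 30),
    scheme = list(delta_small = 4, te = 48, tr = 2, n_b0 = 3, n_reps = 2,
                  bvalues = c(1, 2)),
    dwi_design = list(n_epochs = 3L, rest_s = 28, stim_s = 28, tr = 2),
    bold_design = list(n_epochs = 6L, rest_s = 28, stim_s = 28, tr = 1),
    grid = grid, s0 = 100, delta_ref = 20,
    substrate = list(fractions = c(0.5, 0.5),
                     diffusivities = c(1.07479, 0.32521), t_ex = 53.8),
    regions = regions,
    bold = list(baseline = 100, noise_pct = 1, noise_common_pct = 0.2,
                drift_pct_per_min = 0.2),
    estimator = list(mk_convention = "tensor-mean", signal_floor = 1e-6),
    fitting = list(weighted = FALSE),
    stats = list(alpha = 0.05),
    noise = TRUE, include_bold = TRUE,
    seed = 20260928L)
}

#' Build a synthetic study
#'
#' Assembles the run manifest (rats x runs with alternating stimulated
#' forepaw), the acquisition schemes and schedules, and the rest/stimulus
#' phantoms per laterality. Volume series are generated on demand by
#' \code{\link{study_dwi_series}} / \code{\link{study_bold_series}} from
#' per-series seeds derived from the master seed, so any single series is
#' reproducible in isolation.
#'
#' @param config a config list (see \code{\link{default_study_config}}).
#' @param seed master seed; defaults to \code{config$seed}.
#' @return a \code{synthetic_study}.
#' @export
make_study <- function(config = default_study_config(), seed = config$seed) {
  rg <- config$regions
  n_vox <- prod(config$grid)
  sizes <- round(rg$share * n_vox)
  sizes[length(sizes)] <- n_vox - sum(sizes[-length(sizes)])
  if (any(sizes < 1)) stop("grid too small for the configured regions")
  labels <- rep(rg$label, times = sizes)
  runs_per <- rep(config$runs_per_rat, config$n_rats)
  if (config$short_rats > 0)
    runs_per[seq(config$n_rats - config$short_rats + 1, config$n_rats)] <-
      config$runs_per_rat - 1L
  runs <- do.call(rbind, lapply(seq_len(config$n_rats), function(r)
    data.frame(rat = r, run = seq_len(runs_per[r]))))
  # the stimulated forepaw alternates between runs, and the starting side
  # alternates between rats, so the two laterality groups end up balanced
  # (24 runs each under the default design)
  start_right <- (runs$rat %% 2L) == 1L
  runs$forepaw <- ifelse(xor((runs$run %% 2L) == 1L, !start_right),
                         "right", "left")
  # ROIs are quantified in the left hemisphere: right-forepaw stimulation
  # makes them contralateral to the stimulus
  runs$laterality <- ifelse(runs$forepaw == "right", "contra", "ipsi")
  runs$run_id <- seq_len(nrow(runs))
  base <- karger_substrate(config$substrate$fractions,
                           config$substrate$diffusivities,
                           config$substrate$t_ex)
  mk_phantom <- function(lat) {
    reg_list <- lapply(seq_len(nrow(rg)), function(i) {
      gmd <- if ("gain_md" %in% names(rg)) rg$gain_md[i] else 1
      gmk <- if ("gain_mk" %in% names(rg)) rg$gain_mk[i] else 1
      md <- rg[[paste0("md_", lat)]][i] / gmd
      mk <- rg[[paste0("mk_", lat)]][i] / gmk
      list(label = rg$label[i], rest = base,
           stimulus = perturb_substrate(base, md, mk, config$delta_ref),
           snr = rg$snr[i])
    })
    names(reg_list) <- rg$name
    phantom_spec(config$grid, labels, reg_list, s0 = config$s0)
  }
  schemes <- lapply(config$deltas, function(d)
    acquisition_scheme(d, delta_small = config$scheme$delta_small,
                       te = config$scheme$te, tr = config$scheme$tr,
                       bvalues = config$scheme$bvalues,
                       n_b0 = config$scheme$n_b0,
                       n_reps = config$scheme$n_reps))
  dwi_design <- do.call(block_design, config$dwi_design)
  bold_design <- do.call(block_design, config$bold_design)
  structure(list(
    config = config, seed = seed, labels = labels,
    roi_names = setNames(rg$label, rg$name),
    runs = runs, schemes = schemes, deltas = config$deltas,
    dwi_design = dwi_design, bold_design = bold_design,
    dwi_schedule = schedule_block(dwi_design, schemes[[1]]),
    bold_schedule = schedule_block(bold_design, config$bold_design$tr),
    phantoms = list(contra = mk_phantom("contra"), ipsi = mk_phantom("ipsi"))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d rats, %d runs, %d diffusion times, grid %s\n",
              x$config$n_rats, nrow(x$runs), length(x$deltas),
              paste(x$config$grid, collapse = "x")))
  invisible(x)
}

#' Generate one diffusion series of a study on demand
#'
#' @param study a \code{synthetic_study}.
#' @param run_id row of the run manifest.
#' @param delta diffusion time (one of the study's).
#' @return voxels x 84 signal matrix (see \code{\link{synthesize_dwi}}).
#' @export
study_dwi_series <- function(study, run_id, delta) {
  di <- match(delta, study$deltas)
  if (is.na(di)) stop("delta ", delta, " is not in the study")
  rr <- study$runs[study$runs$run_id == run_id, ]
  seed <- derive_seed(study$seed, rr$rat, rr$run, di, "rest")
  synthesize_dwi(study$phantoms[[rr$laterality]], study$schemes[[di]],
                 study$dwi_schedule, seed = seed,
                 noise = isTRUE(study$config$noise))
}

#' Generate one BOLD voxel series of a study on demand
#'
#' @param study a \code{synthetic_study}.
#' @param run_id row of the run manifest.
#' @return voxels x 336 signal matrix.
#' @export
study_bold_series <- function(study, run_id) {
  rr <- study$runs[study$runs$run_id == run_id, ]
  cfg <- study$config
  rg <- cfg$regions
  amp <- rg[[paste0("bold_", rr$laterality)]][match(study$labels, rg$label)]
  amp[is.na(amp)] <- 0
  sched <- study$bold_schedule
  box <- as.numeric(sched$condition == "stimulus")
  base <- cfg$bold$baseline
  y <- base * (1 + outer(amp / 100, box))
  y <- y + base * cfg$bold$drift_pct_per_min / 100 *
    matrix(sched$time / 60, nrow(y), ncol(y), byrow = TRUE)
  if (isTRUE(cfg$noise)) {
    seed <- derive_seed(study$seed, rr$rat, rr$run, 0L, "stimulus")
    y <- y + with_seed(seed, {
      e <- 0
      if (cfg$bold$noise_pct > 0)
        e <- matrix(rnorm(length(y), 0, base * cfg$bold$noise_pct / 100),
                    nrow(y))
      common <- cfg$bold$noise_common_pct
      if (!is.null(common) && common > 0)
        e <- e + matrix(rnorm(ncol(y), 0, base * common / 100),
                        nrow(y), ncol(y), byrow = TRUE)
      e
    })
  }
  y
}

#' Estimate MD/MK maps for every (run, diffusion time, condition)
#'
#' Wraps \code{\link{average_conditions}}, \code{\link{estimate_md_mk}} and
#' \code{\link{mask_unphysical}} over the study, generating each series on
#' demand and keeping only the parametric maps.
#'
#' @param study a \code{synthetic_study}.
#' @param run_ids subset of runs (default all).
#' @param deltas subset of diffusion times (default all).
#' @return list \code{maps} (parametric maps) and \code{index} (data.frame
#'   with run_id, rat, laterality, delta, condition per map).
#' @export
estimate_study <- function(study, run_ids = study$runs$run_id,
                           deltas = study$deltas) {
  est <- study$config$estimator
  maps <- list(); idx <- list()
  for (rid in run_ids) {
    rr <- study$runs[study$runs$run_id == rid, ]
    for (d in deltas) {
      di <- match(d, study$deltas)
      series <- study_dwi_series(study, rid, d)
      sets <- average_conditions(series, study$dwi_schedule,
                                 study$schemes[[di]])
      for (cond in c("rest", "stimulus")) {
        map <- mask_unphysical(estimate_md_mk(
          sets[[cond]], study$schemes[[di]],
          mk_convention = est$mk_convention,
          signal_floor = est$signal_floor))
        maps[[length(maps) + 1L]] <- map
        idx[[length(idx) + 1L]] <- data.frame(
          run_id = rid, rat = rr$rat, laterality = rr$laterality,
          delta = d, condition = cond)
      }
    }
  }
  list(maps = maps, index = do.call(rbind, idx))
}

#' ROI table from estimated maps
#'
#' @param study a \code{synthetic_study}.
#' @param est result of \code{\link{estimate_study}}.
#' @return data.frame of \code{\link{roi_aggregate}} rows for all maps.
#' @export
study_roi_table <- function(study, est) {
  rows <- lapply(seq_along(est$maps), function(i) {
    ix <- est$index[i, ]
    roi_aggregate(est$maps[[i]], study$labels, study$roi_names,
                  run = ix$run_id, subject = ix$rat,
                  laterality = ix$laterality)
  })
  do.call(rbind, rows)
}

#' Full ROI-level analysis of a synthetic study
#'
#' Produces, per laterality group: the rest-vs-stimulus change report
#' (mixed-effects condition tests, FDR within metric), the S1FL
#' time-dependence model comparison on the pooled MD/MK curves, and -- when
#' the study includes BOLD -- per-ROI condition-averaged BOLD amplitudes
#' with a condition test and FDR across ROIs.
#'
#' @param study a \code{synthetic_study}.
#' @param est result of \code{\link{estimate_study}}.
#' @param timedep_roi ROI used for time-dependence curves.
#' @param include_bold logical; default from the study config.
#' @return list \code{roi_table}, \code{changes} (per laterality),
#'   \code{timedep} (per laterality), \code{bold} (data.frame or NULL).
#' @export
analyze_study <- function(study, est, timedep_roi = "s1fl",
                          include_bold = isTRUE(study$config$include_bold)) {
  roi_table <- study_roi_table(study, est)
  lats <- intersect(c("contra", "ipsi"), unique(roi_table$laterality))
  changes <- list(); timedep <- list()
  for (lat in lats) {
    sub <- roi_table[roi_table$laterality == lat, ]
    changes[[lat]] <- change_report(sub, alpha = study$config$stats$alpha)
    curves <- list()
    for (metric in c("MD", "MK")) for (cond in c("rest", "stimulus")) {
      ss <- sub[sub$roi == timedep_roi & sub$metric == metric &
                  sub$condition == cond, ]
      if (nrow(ss) == 0) next
      ds <- sort(unique(ss$delta_big))
      mn <- vapply(ds, function(d) mean(ss$mean[ss$delta_big == d]),
                   numeric(1))
      se <- vapply(ds, function(d) {
        x <- ss$mean[ss$delta_big == d]; sd(x) / sqrt(length(x))
      }, numeric(1))
      curves[[length(curves) + 1L]] <-
        timedep_curve(ds, mn, se, metric = metric, condition = cond,
                      laterality = lat)
    }
    timedep[[lat]] <- compare_models(curves,
                                     weighted = study$config$fitting$weighted)
  }
  bold <- NULL
  if (include_bold) {
    rows <- list()
    for (rid in study$runs$run_id) {
      rr <- study$runs[study$runs$run_id == rid, ]
      series <- study_bold_series(study, rid)
      box <- as.numeric(study$bold_schedule$condition == "stimulus")
      for (nm in names(study$roi_names)) {
        vox <- study$labels == study$roi_names[[nm]]
        ts <- highpass_dct(colMeans(series[vox, , drop = FALSE]),
                           study$bold_design$tr, protect = box)
        avg <- bold_condition_average(ts, study$bold_design)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = nm, run = rid, subject = rr$rat,
          laterality = rr$laterality,
          condition = c("rest", "stimulus"),
          mean = c(avg$rest_mean, avg$stim_mean))
      }
    }
    rows <- do.call(rbind, rows)
    bold <- list()
    for (lat in lats) {
      sub <- rows[rows$laterality == lat, ]
      out <- list()
      for (nm in unique(sub$roi)) {
        ss <- sub[sub$roi == nm, ]
        r <- mean(ss$mean[ss$condition == "rest"])
        s <- mean(ss$mean[ss$condition == "stimulus"])
        tst <- tryCatch(condition_mixed_test(ss),
                        error = function(e) list(p = NA_real_, fallback = NA))
        out[[length(out) + 1L]] <- data.frame(
          roi = nm, laterality = lat, rest_mean = r, stim_mean = s,
          change_pct = percent_change(r, s), p = tst$p)
      }
      out <- do.call(rbind, out)
      out$q <- fdr_adjust(out$p)
      out$stars <- .stars(out$q)
      bold[[lat]] <- out
    }
  }
  list(roi_table = roi_table, changes = changes, timedep = timedep,
       bold = bold)
}

#' Write study fixtures to disk
#'
#' Writes the label volume (NIfTI), per-diffusion-time gradient-table
#' triples, schedule TSVs, and a JSON manifest; with
#' \code{materialize = TRUE} also every DWI/BOLD series as 4D NIfTI (only
#' sensible for small configurations).
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory.
#' @param materialize write the volume series too.
#' @export
write_study <- function(study, dir, materialize = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(array(as.numeric(study$labels), study$config$grid),
                     file.path(dir, "labels.nii"))
  for (i in seq_along(study$deltas))
    write_gradient_table(study$schemes[[i]],
                         file.path(dir, sprintf("grad_delta%02d", i)))
  write_schedule(study$dwi_schedule, file.path(dir, "schedule_dwi.tsv"))
  write_schedule(study$bold_schedule, file.path(dir, "schedule_bold.tsv"))
  if (materialize) {
    for (rid in study$runs$run_id) {
      for (d in study$deltas) {
        s <- study_dwi_series(study, rid, d)
        RNifti::writeNifti(array(s, c(study$config$grid, ncol(s))),
                           file.path(dir, sprintf("run%02d_delta%g_dwi.nii",
                                                  rid, d)))
      }
      b <- study_bold_series(study, rid)
      RNifti::writeNifti(array(b, c(study$config$grid, ncol(b))),
                         file.path(dir, sprintf("run%02d_bold.nii", rid)))
    }
  }
  manifest <- list(
    seed = study$seed,
    n_rats = study$config$n_rats,
    n_runs = nrow(study$runs),
    deltas = study$deltas,
    runs = study$runs,
    regions = study$config$regions,
    grid = study$config$grid)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_study_config()
  base[names(cfg)] <- cfg
  if (is.list(base$regions) && !is.data.frame(base$regions))
    base$regions <- as.data.frame(base$regions)
  base
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
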