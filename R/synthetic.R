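#' Two-compartment exchange substrate
#'
#' Ground-truth microstructure for the simulator: compartment water
#' fractions, compartment diffusivities and an exchange time. Mean
#' diffusivity is the fraction-weighted mean of the diffusivities
#' (time-independent in this substrate); the zero-time kurtosis is
#' \code{K0 = 3 Var_f(D) / MD^2} with the fraction-weighted variance, and
#' kurtosis decays with diffusion time through the exchange time (see
#' \code{\link{karger_ground_truth}}).
#'
#' @param fractions compartment fractions, summing to 1.
#' @param diffusivities compartment diffusivities, um^2/ms.
#' @param t_ex exchange time, ms.
#' @export
karger_substrate <- function(fractions, diffusivities, t_ex) {
  stopifnot(length(fractions) == length(diffusivities), t_ex > 0,
            all(diffusivities >= 0))
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("compartment fractions must sum to 1 (within 1e-12)")
  structure(list(fractions = fractions, diffusivities = diffusivities,
                 t_ex = t_ex),
            class = "karger_substrate")
}

# exchange decay factor h(x) with x = Delta / t_ex:
# h(x) = (2/x) [1 - (1/x)(1 - exp(-x))];  h(0+) = 1, monotone decreasing
karger_decay <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 12
  xs <- x[!small]
  out[!small] <- (2 / xs) * (1 - (-expm1(-xs)) / xs)
  out
}

#' Ground-truth MD and MK of a substrate at one diffusion time
#'
#' \code{MD = sum(f_i D_i)} (independent of diffusion time);
#' \code{K0 = 3 Var_f(D) / MD^2};
#' \code{MK(Delta) = K0 (2 t_ex / Delta) [1 - (t_ex/Delta)(1 - e^(-Delta/t_ex))]},
#' the two-compartment exchange (Karger) kurtosis decay.
#'
#' @param substrate a \code{\link{karger_substrate}}.
#' @param delta_big diffusion time, ms.
#' @return list with \code{md}, \code{mk}, \code{k0}.
#' @export
karger_ground_truth <- function(substrate, delta_big) {
  stopifnot(inherits(substrate, "karger_substrate"), all(delta_big > 0))
  f <- substrate$fractions; D <- substrate$diffusivities
  md <- sum(f * D)
  varf <- sum(f * (D - md)^2)
  if (md == 0) {
    if (varf > 0) stop("undefined kurtosis: MD = 0 with nonzero variance")
    return(list(md = 0, mk = rep(0, length(delta_big)), k0 = 0))
  }
  k0 <- 3 * varf / md^2
  mk <- k0 * karger_decay(delta_big / substrate$t_ex)
  list(md = md, mk = mk, k0 = k0)
}

#' Perturb a substrate to hit target MD / MK percent changes
#'
#' Produces a stimulus-condition substrate whose MD differs by
#' \code{md_pct} percent (diffusivities scaled jointly, which leaves K0
#' unchanged) and whose MK at the reference diffusion time differs by
#' \code{mk_pct} percent. The MK change is realized by adjusting the
#' exchange time (monotone in MK); if the target exceeds the K0 ceiling the
#' compartment diffusivity spread is rescaled instead (changing K0 at
#' constant MD).
#'
#' @param substrate baseline \code{\link{karger_substrate}}.
#' @param md_pct,mk_pct percent changes (e.g. -1.1 for a 1.1 percent drop).
#' @param delta_ref reference diffusion time for the MK target, ms.
#' @export
perturb_substrate <- function(substrate, md_pct, mk_pct, delta_ref = 20) {
  f <- substrate$fractions
  D <- substrate$diffusivities * (1 + md_pct / 100)
  t_ex <- substrate$t_ex
  gt <- karger_ground_truth(karger_substrate(f, D, t_ex), delta_ref)
  if (abs(mk_pct) > 1e-12 && gt$k0 > 0) {
    target <- gt$mk * (1 + mk_pct / 100)
    if (target <= 0) stop("MK percent change drives MK nonpositive")
    if (target < gt$k0 * 0.9999) {
      t_ex <- uniroot(function(t) gt$k0 * karger_decay(delta_ref / t) - target,
                      lower = 0.05, upper = 1e5, tol = 1e-12)$root
    } else {
      # exchange ceiling reached: widen the diffusivity spread at fixed MD
      k0_new <- target / karger_decay(delta_ref / t_ex)
      md <- sum(f * D)
      D <- md + (D - md) * sqrt(k0_new / gt$k0)
    }
  }
  karger_substrate(f, D, t_ex)
}

#' Phantom specification
#'
#' A labeled voxel grid with a rest and a stimulus substrate (and a b0 SNR)
#' per region.
#'
#' @param dims integer grid dimensions.
#' @param labels integer array/vector of region labels over the grid
#'   (0 = background).
#' @param regions named list; each element
#'   \code{list(label =, rest =, stimulus =, snr =)} with substrates from
#'   \code{\link{karger_substrate}}. Optional elements \code{tensor} (3x3
#'   diffusion tensor) and \code{wtensor} (3x3x3x3 kurtosis tensor) switch a
#'   region to the anisotropic directional cumulant form.
#' @param s0 b0 signal level, arbitrary units.
#' @export
phantom_spec <- function(dims, labels, regions, s0 = 100) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == prod(dims))
  for (rg in regions) {
    stopifnot(inherits(rg$rest, "karger_substrate"),
              inherits(rg$stimulus, "karger_substrate"))
    if (rg$snr <= 0) stop("configuration error: SNR must be positive")
  }
  labs <- vapply(regions, `[[`, integer(1), "label")
  present <- setdiff(unique(labels), 0L)
  if (!all(present %in% labs))
    stop("labels ", paste(setdiff(present, labs), collapse = ", "),
         " have no region substrate")
  structure(list(dims = dims, labels = labels, regions = regions, s0 = s0),
            class = "phantom_spec")
}

# per-voxel ground truth fields for one condition at one diffusion time:
# md, mk (isotropic voxels), snr; anisotropic regions return the directional
# log-signal pieces instead via dtens/wtens region references
.phantom_fields <- function(phantom, condition, delta_big) {
  nv <- length(phantom$labels)
  md <- mk <- rep(NA_real_, nv)
  snr <- rep(Inf, nv)
  for (rg in phantom$regions) {
    vox <- phantom$labels == rg$label
    sub <- if (condition == "rest") rg$rest else rg$stimulus
    gt <- karger_ground_truth(sub, delta_big)
    md[vox] <- gt$md; mk[vox] <- gt$mk; snr[vox] <- rg$snr
  }
  list(md = md, mk = mk, snr = snr)
}

#' Synthesize a diffusion-weighted volume series
#'
#' Per voxel and volume, the noise-free signal follows the two-term cumulant
#' form \code{S(b) = S0 exp(-b MD + (1/6) b^2 MD^2 MK)} with the
#' condition-appropriate substrate evaluated at the scheme's diffusion time
#' (isotropic voxels; regions carrying \code{tensor}/\code{wtensor} use the
#' directional form \code{-b D(n) + (1/6) b^2 MD^2 W(n)}). Rician noise is
#' applied as magnitude of two independent Gaussian channels with
#' \code{sigma = S0 / SNR}.
#'
#' @param phantom a \code{\link{phantom_spec}}.
#' @param scheme an \code{\link{acquisition_scheme}}.
#' @param schedule a \code{volume_schedule} with measurement ids.
#' @param seed integer seed (ignored when \code{noise = FALSE}).
#' @param noise logical; disable for noiseless ground-truth series.
#' @return voxels x volumes signal matrix with attribute \code{dims}.
#' @export
synthesize_dwi <- function(phantom, scheme, schedule, seed = 1L, noise = TRUE) {
  stopifnot(inherits(phantom, "phantom_spec"))
  meas <- scheme$measurements
  nv <- length(phantom$labels)
  series <- matrix(NA_real_, nv, nrow(schedule))
  fields <- list(rest = .phantom_fields(phantom, "rest", scheme$delta_big),
                 stimulus = .phantom_fields(phantom, "stimulus", scheme$delta_big))
  aniso <- Filter(function(rg) !is.null(rg$tensor), phantom$regions)
  for (v in seq_len(nrow(schedule))) {
    m <- meas[meas$id == schedule$measurement_id[v], ]
    fl <- fields[[schedule$condition[v]]]
    lnS <- -m$b * fl$md + (m$b^2 * fl$md^2 * fl$mk) / 6
    for (rg in aniso) {
      vox <- phantom$labels == rg$label
      if (m$b > 0) {
        n <- matrix(c(m$gx, m$gy, m$gz), 1)
        dn <- .apparent_d(rg$tensor, n)
        wn <- .apparent_w(rg$wtensor, n)
        mdt <- sum(diag(rg$tensor)) / 3
        lnS[vox] <- -m$b * dn + (m$b^2 * mdt^2 * wn) / 6
      } else lnS[vox] <- 0
    }
    series[, v] <- phantom$s0 * exp(lnS)
  }
  if (noise) {
    sigma <- phantom$s0 / fields$rest$snr
    if (any(!is.finite(sigma) & phantom$labels != 0))
      stop("configuration error: SNR must be finite and positive")
    series <- with_seed(seed, {
      n1 <- matrix(rnorm(length(series)), nrow(series))
      n2 <- matrix(rnorm(length(series)), nrow(series))
      sqrt((series + sigma * n1)^2 + (sigma * n2)^2)
    })
  }
  attr(series, "dims") <- phantom$dims
  series
}

#' BOLD series specification
#'
#' @param design a \code{\link{block_design}}.
#' @param baseline baseline signal level.
#' @param amplitude_pct boxcar response amplitude during stimulation, percent
#'   of baseline.
#' @param drift_pct_per_min linear drift slope, percent of baseline per min.
#' @param noise_pct Gaussian noise standard deviation, percent of baseline.
#'   For multi-voxel generation this is the voxel-independent (thermal)
#'   component; \code{noise_common_pct} is a spatially common
#'   (physiological) component shared by all voxels of a volume, which sets
#'   the noise floor of ROI-mean time courses.
#' @param noise_common_pct spatially common noise SD, percent of baseline.
#' @param seed integer seed.
#' @export
bold_series_spec <- function(design, baseline = 100, amplitude_pct = 1.2,
                             drift_pct_per_min = 0, noise_pct = 0,
                             noise_common_pct = 0, seed = 1L) {
  stopifnot(inherits(design, "block_design"),
            is.finite(amplitude_pct), is.finite(noise_pct),
            is.finite(noise_common_pct))
  structure(list(design = design, baseline = baseline,
                 amplitude_pct = amplitude_pct,
                 drift_pct_per_min = drift_pct_per_min,
                 noise_pct = noise_pct, noise_common_pct = noise_common_pct,
                 seed = seed),
            class = "bold_series_spec")
}

#' Synthesize a BOLD time series
#'
#' Baseline plus boxcar response during stimulus intervals, linear drift and
#' Gaussian noise; seeded and reproducible.
#'
#' @param spec a \code{\link{bold_series_spec}}.
#' @return numeric vector, one value per scheduled volume.
#' @export
synthesize_bold <- function(spec) {
  stopifnot(inherits(spec, "bold_series_spec"))
  sched <- schedule_block(spec$design, spec$design$tr)
  base <- spec$baseline
  y <- rep(base, nrow(sched))
  y[sched$condition == "stimulus"] <-
    base * (1 + spec$amplitude_pct / 100)
  y <- y + base * spec$drift_pct_per_min / 100 * sched$time / 60
  tot <- sqrt(spec$noise_pct^2 + spec$noise_common_pct^2)
  if (tot > 0)
    y <- y + with_seed(spec$seed, rnorm(length(y), 0, base * tot / 100))
  y
}
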