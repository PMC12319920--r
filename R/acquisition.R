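#' Diffusion acquisition scheme
#'
#' Describes one pulsed-gradient spin-echo acquisition: diffusion time
#' \code{delta_big} (ms), gradient pulse duration \code{delta_small} (ms),
#' echo/repetition times, the shell b-values and the unit gradient directions.
#' The default protocol acquires, per repetition, 3 unweighted (b = 0) images
#' plus 9 directions at each of two b-values (1 and 2 ms/um^2), i.e. 21
#' measurements, with 2 repetitions per condition.
#'
#' @param delta_big diffusion time Delta in ms (time between gradient pulses).
#' @param delta_small gradient pulse duration delta in ms.
#' @param te echo time in ms.
#' @param tr repetition time in s.
#' @param bvalues nonzero shell b-values in ms/um^2.
#' @param directions matrix of unit gradient directions, one row per direction.
#' @param n_b0 number of b = 0 measurements per repetition.
#' @param n_reps repetitions per condition.
#' @return An object of class \code{acquisition_scheme} with a per-repetition
#'   measurement table (\code{$measurements}): columns \code{id}, \code{b},
#'   \code{dir} (0 for b0), \code{gx}, \code{gy}, \code{gz}. b0 entries come
#'   first, then direction-major / b-minor ordering.
#' @export
acquisition_scheme <- function(delta_big, delta_small = 4, te = 48, tr = 2,
                               bvalues = c(1, 2),
                               directions = default_directions(),
                               n_b0 = 3, n_reps = 2) {
  stopifnot(is.numeric(delta_big), length(delta_big) == 1L, delta_big > 0)
  if (delta_big < delta_small)
    stop("invalid geometry: diffusion time delta_big (", delta_big,
         " ms) must be >= gradient pulse duration delta_small (",
         delta_small, " ms)")
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("all gradient directions must have unit norm (tolerance 1e-9)")
  if (any(bvalues <= 0)) stop("shell b-values must be positive; b0 count is n_b0")
  nd <- nrow(directions)
  meas <- data.frame(
    id  = seq_len(n_b0 + nd * length(bvalues)),
    b   = c(rep(0, n_b0), rep(bvalues, times = nd)),
    dir = c(rep(0L, n_b0), rep(seq_len(nd), each = length(bvalues)))
  )
  g <- rbind(matrix(0, n_b0, 3), directions[meas$dir[-seq_len(n_b0)], , drop = FALSE])
  meas$gx <- g[, 1]; meas$gy <- g[, 2]; meas$gz <- g[, 3]
  structure(list(delta_big = delta_big, delta_small = delta_small,
                 te = te, tr = tr, bvalues = bvalues,
                 directions = directions, n_b0 = n_b0, n_reps = n_reps,
                 measurements = meas),
            class = "acquisition_scheme")
}

#' Default acquisition scheme for one diffusion time
#'
#' The protocol defaults: delta = 4 ms, TE = 48 ms, TR = 2 s, shells at
#' b = 1 and 2 ms/um^2, 9 directions, 3 b0, 2 repetitions per condition
#' (42 raw volumes per condition, 84 per acquisition under the default
#' 3-epoch block design).
#'
#' @param delta_big diffusion time in ms.
#' @return an \code{\link{acquisition_scheme}}.
#' @export
build_default_scheme <- function(delta_big) {
  acquisition_scheme(delta_big = delta_big)
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: Delta = %g ms, delta = %g ms, TE = %g ms, TR = %g s\n",
              x$delta_big, x$delta_small, x$te, x$tr))
  cat(sprintf("  %d measurements/repetition (%d b0 + %d directions x %d b-values), %d repetitions/condition\n",
              nrow(x$measurements), x$n_b0, nrow(x$directions),
              length(x$bvalues), x$n_reps))
  invisible(x)
}

#' Block paradigm design
#'
#' Alternating rest / stimulus intervals. Interval lengths must be integer
#' multiples of the volume spacing \code{tr}.
#'
#' @param n_epochs number of rest+stimulus cycles.
#' @param rest_s rest interval length, s.
#' @param stim_s stimulus interval length, s.
#' @param tr volume spacing, s.
#' @export
block_design <- function(n_epochs, rest_s = 28, stim_s = 28, tr) {
  stopifnot(n_epochs >= 1, rest_s > 0, stim_s > 0, tr > 0)
  if (abs(rest_s / tr - round(rest_s / tr)) > 1e-9 ||
      abs(stim_s / tr - round(stim_s / tr)) > 1e-9)
    stop("configuration error: interval lengths (", rest_s, ", ", stim_s,
         " s) must be integer multiples of tr = ", tr, " s")
  structure(list(n_epochs = n_epochs, rest_s = rest_s, stim_s = stim_s, tr = tr),
            class = "block_design")
}

#' Schedule volumes of a block-design acquisition
#'
#' Produces the per-volume condition labels realizing a block design, and --
#' when an acquisition scheme is supplied -- the measurement id each volume
#' realizes. Within each condition the measurement list (scheme order,
#' repeated \code{n_reps} times) is laid out over that condition's volumes in
#' acquisition order, so repetitions are split across epochs. A volume
#' belongs to the interval containing its start time (half-open bins
#' \code{[t, t + tr)}).
#'
#' @param design a \code{\link{block_design}}.
#' @param scheme_or_tr an \code{\link{acquisition_scheme}} (diffusion; its TR
#'   must match the design) or a bare TR in s (e.g. BOLD).
#' @return a \code{volume_schedule}: data.frame with columns \code{volume},
#'   \code{time} (s, volume start), \code{epoch}, \code{condition}
#'   ("rest"/"stimulus"), \code{measurement_id} (NA without a scheme).
#' @export
schedule_block <- function(design, scheme_or_tr) {
  stopifnot(inherits(design, "block_design"))
  scheme <- NULL
  if (inherits(scheme_or_tr, "acquisition_scheme")) {
    scheme <- scheme_or_tr
    if (abs(scheme$tr - design$tr) > 1e-9)
      stop("configuration error: scheme TR (", scheme$tr,
           ") does not match design TR (", design$tr, ")")
  }
  cyc <- design$rest_s + design$stim_s
  n_vol <- as.integer(round(design$n_epochs * cyc / design$tr))
  t0 <- (seq_len(n_vol) - 1L) * design$tr
  in_cycle <- t0 %% cyc
  condition <- ifelse(in_cycle < design$rest_s, "rest", "stimulus")
  epoch <- floor(t0 / cyc) + 1L
  sched <- data.frame(volume = seq_len(n_vol), time = t0,
                      epoch = as.integer(epoch), condition = condition,
                      measurement_id = NA_integer_)
  if (!is.null(scheme)) {
    n_meas <- nrow(scheme$measurements)
    per_cond <- n_meas * scheme$n_reps
    if (2L * per_cond != n_vol)
      stop("configuration error: scheme provides ", per_cond,
           " volumes/condition but the design schedules ", n_vol, " volumes")
    for (cond in c("rest", "stimulus")) {
      idx <- which(sched$condition == cond)
      sched$measurement_id[idx] <- rep(scheme$measurements$id, scheme$n_reps)
    }
  }
  class(sched) <- c("volume_schedule", "data.frame")
  sched
}

#' Average volumes into per-condition signal sets
#'
#' Voxel-wise arithmetic mean of the repeated measurements of each unique
#' diffusion weighting, per condition; all b0 volumes of a condition are
#' pooled into one mean b0 image. Under the default scheme this yields 19
#' images per condition (1 b0 + 18 diffusion-weighted).
#'
#' @param series numeric matrix, voxels x volumes (or a 4D array; the last
#'   dimension indexes volumes).
#' @param schedule a \code{volume_schedule} carrying measurement ids.
#' @param scheme the \code{\link{acquisition_scheme}} realized.
#' @return list with elements \code{rest} and \code{stimulus}, each a
#'   \code{condition_signal_set}: \code{$b0} (voxel vector), \code{$dwi}
#'   (voxels x n_weightings matrix), \code{$table} (b, dir per column),
#'   \code{$provenance} (volumes averaged per image), \code{$condition}.
#' @export
average_conditions <- function(series, schedule, scheme) {
  dims <- NULL
  if (is.array(series) && length(dim(series)) > 2L) {
    dims <- dim(series)
    series <- matrix(series, prod(dims[-length(dims)]), dims[length(dims)])
  }
  series <- as.matrix(series)
  if (ncol(series) != nrow(schedule))
    stop("series has ", ncol(series), " volumes but schedule expects ",
         nrow(schedule))
  meas <- scheme$measurements
  dw_ids <- meas$id[meas$b > 0]
  b0_ids <- meas$id[meas$b == 0]
  out <- lapply(c("rest", "stimulus"), function(cond) {
    sel <- schedule$condition == cond
    mid <- schedule$measurement_id[sel]
    sub <- series[, sel, drop = FALSE]
    need <- table(factor(mid, levels = meas$id))
    if (any(need[as.character(dw_ids)] != scheme$n_reps) ||
        sum(need[as.character(b0_ids)]) != scheme$n_b0 * scheme$n_reps)
      stop("incomplete schedule: condition '", cond,
           "' is missing repetitions of some measurements")
    b0 <- rowMeans(sub[, mid %in% b0_ids, drop = FALSE])
    dwi <- vapply(dw_ids, function(id)
      rowMeans(sub[, mid == id, drop = FALSE]), numeric(nrow(sub)))
    dwi <- matrix(dwi, nrow = nrow(sub))
    structure(list(condition = cond, b0 = b0, dwi = dwi,
                   table = meas[meas$b > 0, c("b", "dir", "gx", "gy", "gz")],
                   provenance = c(b0 = scheme$n_b0 * scheme$n_reps,
                                  dwi = scheme$n_reps),
                   dims = if (is.null(dims)) NULL else dims[-length(dims)]),
              class = "condition_signal_set")
  })
  names(out) <- c("rest", "stimulus")
  out
}

#' Number of images in a condition signal set
#' @param x a \code{condition_signal_set}.
#' @return integer: averaged diffusion-weighted images + 1 pooled b0.
#' @export
n_images <- function(x) {
  stopifnot(inherits(x, "condition_signal_set"))
  ncol(x$dwi) + 1L
}

#' Write / read a gradient table
#'
#' Plain-text pair in the usual row layout: \code{<prefix>.bval} holds one
#' whitespace-separated row of b-values (per volume of one repetition),
#' \code{<prefix>.bvec} three rows of direction components; a JSON sidecar
#' \code{<prefix>.json} records Delta, delta, TE and TR.
#'
#' @param scheme an \code{\link{acquisition_scheme}}.
#' @param prefix output path prefix.
#' @return \code{write_gradient_table}: the prefix, invisibly.
#' @export
write_gradient_table <- function(scheme, prefix) {
  m <- scheme$measurements
  writeLines(paste(sprintf("%.17g", m$b), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- rbind(m$gx, m$gy, m$gz)
  writeLines(apply(bv, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")),
             paste0(prefix, ".bvec"))
  jsonlite::write_json(list(delta_big_ms = scheme$delta_big,
                            delta_small_ms = scheme$delta_small,
                            te_ms = scheme$te, tr_s = scheme$tr,
                            n_b0 = scheme$n_b0, n_reps = scheme$n_reps),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_gradient_table
#' @return \code{read_gradient_table}: an \code{\link{acquisition_scheme}}.
#' @export
read_gradient_table <- function(prefix) {
  if (!file.exists(paste0(prefix, ".bval")))
    stop("gradient table not found: ", prefix, ".bval",
         " -- expected a .bval/.bvec/.json triple")
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- as.matrix(read.table(paste0(prefix, ".bvec")))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nz <- which(b > 0)
  dirs <- unique(t(bv[, nz, drop = FALSE]))
  acquisition_scheme(delta_big = side$delta_big_ms,
                     delta_small = side$delta_small_ms,
                     te = side$te_ms, tr = side$tr_s,
                     bvalues = sort(unique(b[nz])), directions = dirs,
                     n_b0 = sum(b == 0), n_reps = side$n_reps)
}

#' Write / read a volume schedule as TSV
#' @param schedule a \code{volume_schedule}.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  class(sched) <- c("volume_schedule", "data.frame")
  sched
}
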