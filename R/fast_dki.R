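#' Default nine-direction gradient set
#'
#' Nine unit vectors obtained by numerical optimization so that the discrete
#' direction averages reproduce the isotropic 2nd- and 4th-moment averages to
#' machine precision: \code{mean(n o n) = I/3} and \code{mean(n^o4)} equals
#' the isotropic symmetric 4-tensor. These are exactly the conditions under
#' which the plain direction average of apparent diffusivities equals
#' \code{trace(D)/3} and the tensor-weighted direction average of apparent
#' kurtoses equals the full kurtosis-tensor mean, for any tensor pair. Any
#' user-supplied set passing \code{\link{verify_direction_set}} may be used
#' instead.
#'
#' @return a 9 x 3 matrix of unit row vectors.
#' @export
default_directions <- function() {
  matrix(c(
    -0.31684705532976687, -0.80498449789512483,  0.50160532461028495,
    -0.12042182936143342,  0.05625977738855792,  0.99112734825623483,
    -0.17760254306819942, -0.83881712181206158, -0.51462916051331298,
     0.54920791202258756, -0.04896924453728839,  0.83424977222726104,
    -0.52527721341166322,  0.74113418670583475,  0.41809564260628079,
    -0.96082327116357247,  0.24557850074611515, -0.12849062830347727,
     0.35398747333488317, -0.82552728967491684,  0.43954244701049211,
     0.77662187992304066,  0.11189386214053784, -0.61995017480445680,
     0.79018247741733494,  0.58242460432705867,  0.19077010420155560),
    ncol = 3, byrow = TRUE)
}

# apparent diffusivity D(n) = n' D n for each direction (rows of n)
.apparent_d <- function(D, n) rowSums((n %*% D) * n)

# apparent W(n) = W_ijkl n_i n_j n_k n_l; W given as full 3x3x3x3 array
.apparent_w <- function(W, n) {
  apply(n, 1, function(v) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + W[i, j, k, l] * v[i] * v[j] * v[k] * v[l]
    s
  })
}

# isotropic mean of W(n) over the sphere = W_iijj / 5
.w_mean <- function(W) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + W[i, i, j, j]
  s / 5
}

# random fully symmetric 4-tensor
.random_sym4 <- function() {
  W <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in i:3) for (k in j:3) for (l in k:3) {
    v <- rnorm(1)
    p <- unique(combinat_perms(c(i, j, k, l)))
    for (r in seq_len(nrow(p))) W[p[r, 1], p[r, 2], p[r, 3], p[r, 4]] <- v
  }
  W
}

# all permutations of a length-4 index vector (24 rows, possibly repeated)
combinat_perms <- function(x) {
  idx <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 4L), ]
  t(apply(idx, 1, function(r) x[as.integer(r)]))
}

#' Verify the averaging identities of a direction set
#'
#' The fast MD/MK estimator relies on two identities of the direction set:
#' (2nd order) the plain average of apparent diffusivities over the set
#' equals \code{trace(D)/3} for every symmetric tensor D, and (4th order)
#' the average of \code{W(n)} over the set equals the isotropic
#' kurtosis-tensor mean \code{W_iijj/5} for every fully symmetric W. Both
#' are checked on random tensors.
#'
#' @param directions n x 3 matrix of unit vectors, n >= 9.
#' @param n_trials random tensors per check.
#' @param tol residual tolerance.
#' @param seed RNG seed for the random tensors.
#' @return list with \code{pass} (logical), \code{residual_2nd},
#'   \code{residual_4th} (max absolute residuals).
#' @export
verify_direction_set <- function(directions, n_trials = 12, tol = 1e-9,
                                 seed = 7L) {
  directions <- as.matrix(directions)
  if (nrow(directions) < 9L)
    stop("direction set must contain at least 9 vectors, got ",
         nrow(directions))
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
  res <- with_seed(seed, {
    r2 <- r4 <- 0
    for (t in seq_len(n_trials)) {
      A <- matrix(rnorm(9), 3); D <- (A + t(A)) / 2
      r2 <- max(r2, abs(mean(.apparent_d(D, directions)) -
                          sum(diag(D)) / 3))
      W <- .random_sym4()
      r4 <- max(r4, abs(mean(.apparent_w(W, directions)) - .w_mean(W)))
    }
    c(r2, r4)
  })
  list(pass = all(res <= tol), residual_2nd = res[1], residual_4th = res[2])
}

#' Closed-form two-shell diffusivity and kurtosis
#'
#' Exact inversion of the two-term cumulant signal model
#' \code{ln S(b) = ln S0 - b D + (1/6) b^2 D^2 K} from two shells:
#' \deqn{D = (b2^2 y1 - b1^2 y2) / (b1 b2 (b2 - b1))}
#' \deqn{K = 6 (b2 y1 - b1 y2) / (D^2 b1 b2 (b2 - b1))}
#' with \code{y_i = -ln(S(b_i)/S0)}.
#'
#' @param y1,y2 normalized log-attenuations at b1 and b2 (vectors).
#' @param b1,b2 shell b-values, \code{b2 > b1 > 0}.
#' @return list with vectors \code{d} and \code{k}; entries where the
#'   implied diffusivity is nonpositive or inputs are non-finite carry
#'   \code{flag = TRUE} (kurtosis set to NA there).
#' @export
two_shell_closed_form <- function(y1, y2, b1, b2) {
  stopifnot(b2 > b1, b1 > 0)
  den <- b1 * b2 * (b2 - b1)
  d <- (b2^2 * y1 - b1^2 * y2) / den
  k <- 6 * (b2 * y1 - b1 * y2) / (d^2 * den)
  flag <- !is.finite(d) | d <= 0 | !is.finite(k)
  k[!is.finite(k)] <- NA_real_
  list(d = d, k = k, flag = flag)
}

#' Voxel-wise fast MD / MK estimation from an averaged condition set
#'
#' Applies the two-shell closed form along each of the 9 directions and
#' averages: \code{MD = mean(D_n)}; \code{MK = mean((D_n/MD)^2 K_n)}
#' (tensor-mean convention, the default -- equals the kurtosis-tensor mean
#' for direction sets passing \code{\link{verify_direction_set}}) or the
#' plain mean of \code{K_n} with \code{mk_convention = "plain-mean"}.
#' Signals are clipped below at \code{signal_floor * S0} before logs;
#' clipped voxels are flagged into the validity mask.
#'
#' @param cond_set a \code{condition_signal_set} from
#'   \code{\link{average_conditions}}.
#' @param scheme the \code{\link{acquisition_scheme}}.
#' @param mk_convention "tensor-mean" or "plain-mean".
#' @param signal_floor lower clip for signals, as a fraction of S0.
#' @return a \code{parametric_map}: list with voxel vectors \code{md},
#'   \code{mk}, logical \code{valid}, plus \code{condition},
#'   \code{delta_big}, \code{dims}.
#' @export
estimate_md_mk <- function(cond_set, scheme,
                           mk_convention = c("tensor-mean", "plain-mean"),
                           signal_floor = 1e-6) {
  mk_convention <- match.arg(mk_convention)
  stopifnot(inherits(cond_set, "condition_signal_set"))
  tab <- cond_set$table
  bs <- sort(unique(tab$b))
  if (length(bs) != 2L)
    stop("fast estimation needs exactly two nonzero shells, got ", length(bs))
  b1 <- bs[1]; b2 <- bs[2]
  dirs <- sort(unique(tab$dir))
  s0 <- cond_set$b0
  nv <- length(s0)
  floor_v <- signal_floor * s0
  clipped <- rep(FALSE, nv)
  att <- function(col) {
    s <- cond_set$dwi[, col]
    low <- s < floor_v
    clipped <<- clipped | low | s0 <= 0
    s <- pmax(s, floor_v)
    -log(s / s0)
  }
  Dn <- Kn <- matrix(NA_real_, nv, length(dirs))
  bad <- rep(FALSE, nv)
  for (j in seq_along(dirs)) {
    c1 <- which(tab$dir == dirs[j] & tab$b == b1)
    c2 <- which(tab$dir == dirs[j] & tab$b == b2)
    if (length(c1) != 1L || length(c2) != 1L)
      stop("condition set is missing a shell for direction ", dirs[j])
    est <- two_shell_closed_form(att(c1), att(c2), b1, b2)
    Dn[, j] <- est$d; Kn[, j] <- est$k
    bad <- bad | est$flag
  }
  md <- rowMeans(Dn)
  mk <- if (mk_convention == "tensor-mean")
    rowMeans((Dn / md)^2 * Kn) else rowMeans(Kn)
  valid <- !bad & !clipped & is.finite(md) & is.finite(mk)
  structure(list(md = md, mk = mk, valid = valid,
                 condition = cond_set$condition,
                 delta_big = scheme$delta_big,
                 mk_convention = mk_convention,
                 dims = cond_set$dims),
            class = "parametric_map")
}

#' Exclude unphysical voxels from a parametric map
#'
#' Voxels with nonpositive MD, negative MK, or non-finite estimates (noise
#' or partial-volume artifacts) are removed from the validity mask; they are
#' excluded from all downstream ROI statistics.
#'
#' @param map a \code{parametric_map}.
#' @return the map with \code{valid} updated.
#' @export
mask_unphysical <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  ok <- is.finite(map$md) & is.finite(map$mk) & map$md > 0 & map$mk >= 0
  map$valid <- map$valid & ok
  map
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("Parametric map (%s, Delta = %g ms): %d voxels, %.1f%% valid\n",
              x$condition, x$delta_big, length(x$md),
              100 * mean(x$valid)))
  cat(sprintf("  MD median %.4f um^2/ms, MK median %.4f (valid voxels)\n",
              median(x$md[x$valid]), median(x$mk[x$valid])))
  invisible(x)
}

#' Write a parametric map as NIfTI volumes with a JSON sidecar
#'
#' @param map a \code{parametric_map} whose \code{dims} are set.
#' @param prefix output prefix; writes \code{<prefix>_md.nii},
#'   \code{<prefix>_mk.nii}, \code{<prefix>_mask.nii},
#'   \code{<prefix>.json}.
#' @export
write_parametric_map <- function(map, prefix) {
  stopifnot(inherits(map, "parametric_map"), !is.null(map$dims))
  wr <- function(v, suffix) RNifti::writeNifti(
    array(v, map$dims), paste0(prefix, "_", suffix, ".nii"))
  wr(map$md, "md"); wr(map$mk, "mk"); wr(as.numeric(map$valid), "mask")
  jsonlite::write_json(list(condition = map$condition,
                            delta_big_ms = map$delta_big,
                            mk_convention = map$mk_convention),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}
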