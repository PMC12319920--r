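# Independent oracles used across the suite. These deliberately do not call
# the package's estimation path.

# high-precision evaluation of the exchange kurtosis decay via the series
# expansion of exp(-x): K0 * (2/x) * [1 - (1/x) * (1 - e^-x)]
oracle_karger_mk <- function(k0, t_ex, delta) {
  x <- delta / t_ex
  # 1 - e^-x summed term by term to machine saturation
  s <- 0; term <- 1
  for (k in 1:60) {
    term <- term * (-x) / k
    s <- s - term
  }
  k0 * (2 / x) * (1 - s / x)
}

# quasi-uniform directions on the sphere (golden spiral)
oracle_sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# n' D n for rows of n
oracle_dn <- function(D, n) rowSums((n %*% D) * n)

# W(n) = W_ijkl n_i n_j n_k n_l
oracle_wn <- function(W, n) {
  apply(n, 1, function(v) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + W[i, j, k, l] * v[i] * v[j] * v[k] * v[l]
    s
  })
}

# kurtosis tensor of a two-tensor mixture:
# W_ijkl = (3/MD^2) * sym( sum_f f D_ij D_kl  -  Dbar_ij Dbar_kl )
oracle_mixture_tensors <- function(f, D1, D2) {
  Db <- f * D1 + (1 - f) * D2
  M <- f * outer(D1, D1) + (1 - f) * outer(D2, D2) - outer(Db, Db)
  md <- sum(diag(Db)) / 3
  W <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    W[i, j, k, l] <- (M[i, j, k, l] + M[i, k, j, l] + M[i, l, j, k]) / 3
  }
  list(D = Db, W = 3 * W / md^2, md = md)
}

# isotropic kurtosis-tensor mean: W_iijj / 5
oracle_wbar <- function(W) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + W[i, i, j, j]
  s / 5
}

# brute-force DKI fit: regress ln(S/S0) on the 6 diffusion-tensor and 15
# kurtosis-tensor monomials over many directions/shells, return MD and the
# kurtosis-tensor mean
oracle_dki_fit <- function(signals, s0, bvals, dirs) {
  idx6 <- rbind(c(1,1), c(2,2), c(3,3), c(1,2), c(1,3), c(2,3))
  mult6 <- c(1, 1, 1, 2, 2, 2)
  idx15 <- NULL
  for (i in 1:3) for (j in i:3) for (k in j:3) for (l in k:3)
    idx15 <- rbind(idx15, c(i, j, k, l))
  mult15 <- apply(idx15, 1, function(r) {
    perms <- unique(t(apply(
      expand.grid(1:4, 1:4, 1:4, 1:4)[apply(
        expand.grid(1:4, 1:4, 1:4, 1:4), 1,
        function(z) length(unique(z)) == 4), ], 1,
      function(p) r[as.integer(p)])))
    nrow(perms)
  })
  rows <- length(bvals)
  X <- matrix(0, rows, 6 + 15)
  for (r in seq_len(rows)) {
    n <- dirs[r, ]; b <- bvals[r]
    X[r, 1:6] <- -b * mult6 *
      vapply(seq_len(6), function(q) n[idx6[q,1]] * n[idx6[q,2]], 0)
    X[r, 7:21] <- (b^2 / 6) * mult15 *
      vapply(seq_len(15), function(q)
        prod(n[idx15[q, ]]), 0)
  }
  y <- log(signals / s0)
  beta <- qr.solve(X, y)
  Dfit <- matrix(0, 3, 3)
  for (q in 1:6) {
    Dfit[idx6[q,1], idx6[q,2]] <- beta[q]
    Dfit[idx6[q,2], idx6[q,1]] <- beta[q]
  }
  md <- sum(diag(Dfit)) / 3
  # beta[7:21] estimates V = MD^2 W (unique components)
  V <- array(0, c(3,3,3,3))
  for (q in 1:15) {
    p <- idx15[q, ]
    perms <- unique(t(apply(
      expand.grid(1:4, 1:4, 1:4, 1:4)[apply(
        expand.grid(1:4, 1:4, 1:4, 1:4), 1,
        function(z) length(unique(z)) == 4), ], 1,
      function(z) p[as.integer(z)])))
    for (r in seq_len(nrow(perms)))
      V[perms[r,1], perms[r,2], perms[r,3], perms[r,4]] <- beta[6 + q]
  }
  list(md = md, wbar = oracle_wbar(V) / md^2)
}

# tiny default-structure study configuration for fast pipeline tests
tiny_config <- function(grid = c(10, 10, 3), n_rats = 2L, runs_per_rat = 2L) {
  cfg <- default_study_config(grid = grid)
  cfg$n_rats <- n_rats; cfg$runs_per_rat <- runs_per_rat
  cfg$short_rats <- 0L
  cfg
}
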