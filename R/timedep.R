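#' Time-dependence model registry
#'
#' Five candidate models for the diffusion-time dependence of MD and MK in
#' gray matter:
#' \itemize{
#'   \item \code{disorder1d_md}, \code{disorder1d_mk}: short-range 1D
#'     structural disorder, \code{v(Delta) = c_inf + 2 A Delta^(-1/2)}
#'     (parameters \code{A}, \code{c_inf}).
#'   \item \code{disorder2d3d_md}, \code{disorder2d3d_mk}: 2D-3D structural
#'     disorder, \code{v(Delta) = c_inf + A ln(Delta/t_c) / Delta}
#'     (parameters \code{A}, \code{t_c}, \code{c_inf}).
#'   \item \code{karger_mk}: two-compartment exchange kurtosis decay,
#'     \code{MK(Delta) = K0 (2 t_ex/Delta)[1 - (t_ex/Delta)(1 - e^(-Delta/t_ex))]}
#'     (parameters \code{K0}, \code{t_ex}).
#' }
#' \code{c_inf} is the long-time asymptote (reported as \code{D_inf} for MD
#' and \code{K_inf} for MK).
#'
#' @format list keyed by model id with elements \code{params}, \code{k},
#'   \code{metric}.
#' @export
timedep_models <- list(
  disorder1d_md   = list(params = c("A", "c_inf"),        k = 2L, metric = "MD"),
  disorder2d3d_md = list(params = c("A", "t_c", "c_inf"), k = 3L, metric = "MD"),
  disorder1d_mk   = list(params = c("A", "c_inf"),        k = 2L, metric = "MK"),
  disorder2d3d_mk = list(params = c("A", "t_c", "c_inf"), k = 3L, metric = "MK"),
  karger_mk       = list(params = c("K0", "t_ex"),        k = 2L, metric = "MK")
)

#' Evaluate a time-dependence model
#'
#' @param model model id, one of \code{names(timedep_models)}.
#' @param params named vector of parameters for the model.
#' @param delta_big diffusion times, ms.
#' @return model values at \code{delta_big}.
#' @export
eval_model <- function(model, params, delta_big) {
  stopifnot(model %in% names(timedep_models), all(delta_big > 0))
  p <- as.list(params)
  switch(sub("_m[dk]$", "", model),
    disorder1d = p$c_inf + 2 * p$A * delta_big^(-1 / 2),
    disorder2d3d = {
      if (p$t_c <= 0) stop("domain error: t_c must be positive")
      p$c_inf + p$A * log(delta_big / p$t_c) / delta_big
    },
    karger = {
      if (p$t_ex <= 0) stop("domain error: t_ex must be positive")
      p$K0 * karger_decay(delta_big / p$t_ex)
    })
}

#' Corrected Akaike information criterion from a least-squares fit
#'
#' Gaussian-likelihood form: \code{AIC = n ln(rss/n) + 2k};
#' \code{AICc = AIC + 2k(k+1)/(n - k - 1)}. Undefined (NA) when
#' \code{n <= k + 1}.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of points.
#' @param k number of fitted parameters.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) return(NA_real_)
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Construct a time-dependence curve
#'
#' @param delta_big strictly increasing diffusion times, ms.
#' @param value metric values (MD in um^2/ms or MK, unitless).
#' @param se optional standard errors.
#' @param metric "MD" or "MK".
#' @param condition,laterality optional annotations.
#' @export
timedep_curve <- function(delta_big, value, se = NULL,
                          metric = c("MD", "MK"),
                          condition = NA_character_,
                          laterality = NA_character_) {
  metric <- match.arg(metric)
  stopifnot(length(delta_big) == length(value),
            all(diff(delta_big) > 0))
  structure(list(delta_big = delta_big, value = value, se = se,
                 metric = metric, condition = condition,
                 laterality = laterality),
            class = "timedep_curve")
}

# multi-start initial values per model (list of named vectors)
.timedep_starts <- function(model, curve) {
  d <- curve$delta_big; v <- curve$value
  if (model %in% c("disorder1d_md", "disorder1d_mk")) {
    A0 <- (v[1] - v[2]) / (2 * (d[1]^-0.5 - d[2]^-0.5))
    list(c(A = A0, c_inf = min(v)),
         c(A = max(abs(A0), 1e-3), c_inf = v[length(v)]))
  } else if (model %in% c("disorder2d3d_md", "disorder2d3d_mk")) {
    # the model is linear in (c_inf, A, -A ln t_c): seed from that solve
    X <- cbind(1, log(d) / d, 1 / d)
    beta <- tryCatch(qr.solve(X, v), error = function(e) c(min(v), 0.01, 0))
    A0 <- beta[2]
    tc0 <- if (abs(A0) > 1e-12) exp(-beta[3] / A0) else 1
    tc0 <- min(max(tc0, 1e-2), 999)
    lapply(c(tc0, 1, 10), function(tc)
      c(A = if (abs(A0) > 1e-12) A0 else 0.01, t_c = tc, c_inf = min(v)))
  } else {
    lapply(c(10, 25, 50, 100, 200), function(tex)
      c(K0 = max(v), t_ex = tex))
  }
}

.timedep_bounds <- function(model) {
  if (model == "karger_mk")
    list(lower = c(K0 = 1e-8, t_ex = 1), upper = c(K0 = 10, t_ex = 1e3))
  else if (grepl("2d3d", model))
    list(lower = c(A = -Inf, t_c = 1e-3, c_inf = -Inf),
         upper = c(A = Inf, t_c = 1e3, c_inf = Inf))
  else
    list(lower = c(A = -Inf, c_inf = -Inf), upper = c(A = Inf, c_inf = Inf))
}

#' Fit a time-dependence model to a curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the mean curve, with a
#' small multi-start grid; the best converged start by RSS wins. Parameter
#' standard errors come from the Jacobian-based covariance scaled by
#' \code{rss/(n - k)}. Unweighted by default; \code{weighted = TRUE} uses
#' \code{1/se^2} weights.
#'
#' @param curve a \code{\link{timedep_curve}}.
#' @param model model id.
#' @param weighted logical; weight by inverse squared standard errors.
#' @return a \code{timedep_fit}: list with \code{model}, \code{params},
#'   \code{se}, \code{cov}, \code{rss}, \code{n}, \code{k}, \code{aicc},
#'   \code{converged}, plus curve annotations.
#' @export
fit_timedep <- function(curve, model, weighted = FALSE) {
  stopifnot(inherits(curve, "timedep_curve"), model %in% names(timedep_models))
  info <- timedep_models[[model]]
  n <- length(curve$value); k <- info$k
  if (n < k + 1)
    stop("curve has ", n, " points; model '", model, "' needs at least ",
         k + 1)
  w <- if (weighted && !is.null(curve$se)) 1 / curve$se^2 else rep(1, n)
  dat <- data.frame(d = curve$delta_big, v = curve$value, w = w)
  bounds <- .timedep_bounds(model)
  form <- switch(model,
    disorder1d_md = , disorder1d_mk = v ~ c_inf + 2 * A * d^(-0.5),
    disorder2d3d_md = , disorder2d3d_mk = v ~ c_inf + A * log(d / t_c) / d,
    karger_mk = v ~ K0 * karger_decay(d / t_ex))
  best <- NULL
  for (start in .timedep_starts(model, curve)) {
    start <- pmin(pmax(start, bounds$lower + 1e-10), bounds$upper - 1e-10)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(start),
                        weights = w,
                        lower = bounds$lower[names(start)],
                        upper = bounds$upper[names(start)],
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, se = NULL,
                          cov = NULL, rss = NA_real_, n = n, k = k,
                          aicc = NA_real_, converged = FALSE,
                          metric = curve$metric, condition = curve$condition,
                          laterality = curve$laterality),
                     class = "timedep_fit"))
  }
  fit <- best$fit
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, length(est), length(est)))
  structure(list(model = model, params = est,
                 se = sqrt(pmax(diag(vc), 0)), cov = vc,
                 rss = best$rss, n = n, k = k,
                 aicc = aicc(best$rss, n, k), converged = TRUE,
                 metric = curve$metric, condition = curve$condition,
                 laterality = curve$laterality),
            class = "timedep_fit")
}

#' @export
print.timedep_fit <- function(x, ...) {
  cat(sprintf("Time-dependence fit: %s (%s%s)\n", x$model, x$metric,
              if (!is.na(x$condition)) paste0(", ", x$condition) else ""))
  if (!x$converged) { cat("  did not converge\n"); return(invisible(x)) }
  for (p in names(x$params))
    cat(sprintf("  %s = %.4g +/- %.3g\n", p, x$params[p], x$se[p]))
  cat(sprintf("  RSS = %.4g, n = %d, k = %d, AICc = %.4g\n",
              x$rss, x$n, x$k, x$aicc))
  invisible(x)
}

#' Fit and compare all applicable time-dependence models
#'
#' MD curves are fit with the 1D and 2D-3D disorder forms; MK curves
#' additionally with the exchange model. For each curve the winner is the
#' lowest finite AICc; ties (within \code{tie_tol}) break toward fewer
#' parameters. Non-converged fits or fits with undefined AICc are excluded
#' from the comparison.
#'
#' @param curves list of \code{\link{timedep_curve}} objects.
#' @param weighted passed to \code{\link{fit_timedep}}.
#' @param tie_tol AICc difference treated as a tie.
#' @return a \code{timedep_comparison}: list with \code{fits} (nested list
#'   per curve), \code{table} (one row per curve x model) and per-curve
#'   \code{winner}.
#' @export
compare_models <- function(curves, weighted = FALSE, tie_tol = 1e-9) {
  if (inherits(curves, "timedep_curve")) curves <- list(curves)
  rows <- list(); fits <- list(); winners <- character(length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    mods <- names(Filter(function(m) m$metric == cv$metric, timedep_models))
    fl <- lapply(mods, function(m) fit_timedep(cv, m, weighted = weighted))
    names(fl) <- mods
    # -Inf AICc (an exact fit) stays in the comparison; NA (undefined) drops
    ok <- vapply(fl, function(f) f$converged && !is.na(f$aicc), logical(1))
    win <- NA_character_
    if (any(ok)) {
      cand <- fl[ok]
      a <- vapply(cand, `[[`, numeric(1), "aicc")
      kk <- vapply(cand, `[[`, numeric(1), "k")
      best_a <- min(a)
      tied <- which(a <= best_a + tie_tol)
      win <- names(cand)[tied[which.min(kk[tied])]]
    }
    winners[i] <- win
    fits[[i]] <- fl
    for (m in mods) {
      f <- fl[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        curve = i, metric = cv$metric, condition = cv$condition,
        laterality = cv$laterality, model = m,
        params = if (f$converged)
          paste(sprintf("%s=%.4g(%.2g)", names(f$params), f$params, f$se),
                collapse = "; ") else NA_character_,
        rss = f$rss, aicc = f$aicc, winner = identical(m, win))
    }
  }
  structure(list(fits = fits, table = do.call(rbind, rows),
                 winner = winners),
            class = "timedep_comparison")
}

#' @export
print.timedep_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
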