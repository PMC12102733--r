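#' Fit the Michaelis-Menten model to velocities at one inhibitor level
#'
#' Nonlinear least squares of v = Vmax * S / (KM + S), with deterministic
#' starting values from the Hanes linearisation (S/v regressed on S, so
#' 1/slope estimates Vmax and intercept/slope estimates KM). Standard errors
#' come from the covariance matrix of the fit.
#'
#' @param S substrate concentrations (uM), at least 3 distinct positive
#'   levels.
#' @param v velocities (pmol min^-1 ug^-1).
#' @param sem optional replicate SEMs, used when `weighted = TRUE`
#'   (weights 1/sem^2).
#' @param weighted logical; default unweighted.
#' @param I inhibitor level this series was measured at (metadata only).
#' @return An object of class `mm_fit`: list with `I`, `KM`, `KM_se`,
#'   `Vmax`, `Vmax_se`, `residual_ss`, `n`, `converged`.
#' @export
fit_michaelis_menten <- function(S, v, sem = NULL, weighted = FALSE, I = NA) {
  stopifnot(is.numeric(S), is.numeric(v), length(S) == length(v))
  if (anyNA(S) || anyNA(v) || any(!is.finite(S)) || any(!is.finite(v)))
    stop("velocities and concentrations must be finite")
  keep <- S > 0
  S <- S[keep]; v <- v[keep]
  if (length(unique(S)) < 3)
    stop("need at least 3 distinct positive substrate levels")
  if (all(v == 0)) stop("all velocities are zero; nothing to fit")
  if (any(v < 0)) warning("negative velocities present; fit may be unstable")

  w <- rep(1, length(S))
  if (weighted) {
    if (is.null(sem)) stop("'weighted = TRUE' requires 'sem'")
    sem <- sem[keep]
    if (any(sem <= 0)) stop("weighted fit requires strictly positive SEMs")
    w <- 1 / sem^2
  }

  # Hanes start: S/v = KM/Vmax + S/Vmax (only usable points with v > 0)
  pos <- v > 0
  start <- if (sum(pos) >= 2) {
    h <- stats::lm(I(S[pos] / v[pos]) ~ S[pos])
    b <- unname(stats::coef(h))
    if (is.finite(b[2]) && b[2] > 0 && b[1] > 0)
      c(KM = b[1] / b[2], Vmax = 1 / b[2]) else NULL
  } else NULL
  if (is.null(start))
    start <- c(KM = stats::median(S), Vmax = max(v) * 1.2)

  sw <- sqrt(w)
  resid_fn <- function(p) sw * (v - p[2] * S / (p[1] + S))
  jac_fn <- function(p)
    -sw * cbind(KM = -p[2] * S / (p[1] + S)^2, Vmax = S / (p[1] + S))
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                       lower = c(KM = 0, Vmax = 0),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "Michaelis-Menten fit failed (start KM = %g, Vmax = %g): %s",
        start[["KM"]], start[["Vmax"]], conditionMessage(e))))
  if (!out$info %in% 1:4 || !is.finite(out$deviance))
    stop(sprintf(
      "Michaelis-Menten fit did not converge (start KM = %g, Vmax = %g; final deviance %g)",
      start[["KM"]], start[["Vmax"]], out$deviance))
  est <- out$par
  rss <- sum(resid_fn(est)^2)
  J <- jac_fn(est)
  se <- tryCatch(
    sqrt(pmax(diag(solve(crossprod(J)) * rss / max(length(S) - 2, 1)), 0)),
    error = function(e) c(KM = NA_real_, Vmax = NA_real_))
  structure(
    list(I = I,
         KM = est[["KM"]], KM_se = se[["KM"]],
         Vmax = est[["Vmax"]], Vmax_se = se[["Vmax"]],
         residual_ss = rss,
         n = length(S), converged = out$info %in% 1:4),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit (I = %s uM): KM = %.4g +/- %.2g uM, Vmax = %.4g +/- %.2g\n",
              format(x$I), x$KM, x$KM_se, x$Vmax, x$Vmax_se))
  invisible(x)
}

#' Per-inhibitor-level Michaelis-Menten fits
#'
#' Fits the uninhibited model separately at every inhibitor concentration in
#' the rate table, yielding apparent KM and Vmax as functions of inhibitor --
#' the classical summary table of a graphical inhibition analysis. A falling
#' Vmax with a roughly constant (or falling) KM is the uncompetitive
#' signature.
#'
#' @param table a `rate_table`.
#' @param weighted logical, see [fit_michaelis_menten()].
#' @return A list of `mm_fit` objects ordered by inhibitor concentration,
#'   of class `mm_fit_series`. `as.data.frame()` renders the summary table.
#' @export
fit_per_inhibitor_series <- function(table, weighted = FALSE) {
  stopifnot(is.data.frame(table))
  levels_I <- sort(unique(table$I_uM))
  fits <- lapply(levels_I, function(i) {
    g <- table[table$I_uM == i, ]
    fit_michaelis_menten(g$S_uM, g$v_pmol_min_ug, sem = g$sem,
                         weighted = weighted, I = i)
  })
  structure(fits, class = "mm_fit_series")
}

#' @export
as.data.frame.mm_fit_series <- function(x, ...) {
  do.call(rbind, lapply(x, function(f)
    data.frame(I_uM = f$I, KM_app = f$KM, KM_se = f$KM_se,
               Vmax_app = f$Vmax, Vmax_se = f$Vmax_se,
               residual_ss = f$residual_ss, n = f$n)))
}

#' @export
print.mm_fit_series <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

aicc <- function(rss, n, npar) {
  k <- npar + 1  # + residual variance
  rss <- max(rss, .Machine$double.xmin)
  n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

# The inhibition constants are fitted on the inverse (affinity) scale
# bi = 1/Ki, bip = 1/Ki', bc = 1/K (uM^-1, lower-bounded at 0): a
# structurally weak constant then sits at the 0 boundary instead of
# diverging to infinity, which keeps the Jacobian well conditioned.
# Each mechanism fixes which affinities are free:
#   none: neither; competitive: bi; uncompetitive: bip;
#   noncompetitive: one shared bc = bi = bip; mixed: both.
global_model_pars <- function(mechanism) {
  switch(mechanism,
         none = c("KM", "Vmax"),
         competitive = c("KM", "Vmax", "bi"),
         uncompetitive = c("KM", "Vmax", "bip"),
         noncompetitive = c("KM", "Vmax", "bc"),
         mixed = c("KM", "Vmax", "bi", "bip"))
}

# map the free-parameter vector of a mechanism onto the full
# (KM, Vmax, bi, bip) vector of the general model
expand_theta <- function(p, mechanism) {
  switch(mechanism,
         none = c(p[1], p[2], 0, 0),
         competitive = c(p[1], p[2], p[3], 0),
         uncompetitive = c(p[1], p[2], 0, p[3]),
         noncompetitive = c(p[1], p[2], p[3], p[3]),
         mixed = p)
}

global_model_v <- function(theta, S, I) {
  theta[2] * S / (theta[1] * (1 + I * theta[3]) + S * (1 + I * theta[4]))
}

# analytic gradient of the general model wrt (KM, Vmax, bi, bip), mapped to
# the mechanism's free parameters by the chain rule
global_model_grad <- function(p, mechanism, S, I) {
  theta <- expand_theta(p, mechanism)
  D <- theta[1] * (1 + I * theta[3]) + S * (1 + I * theta[4])
  G <- cbind(KM = -theta[2] * S * (1 + I * theta[3]) / D^2,
             Vmax = S / D,
             bi = -theta[2] * S * theta[1] * I / D^2,
             bip = -theta[2] * S^2 * I / D^2)
  switch(mechanism,
         none = G[, 1:2, drop = FALSE],
         competitive = G[, c("KM", "Vmax", "bi"), drop = FALSE],
         uncompetitive = G[, c("KM", "Vmax", "bip"), drop = FALSE],
         noncompetitive = cbind(G[, 1:2, drop = FALSE],
                                bc = G[, "bi"] + G[, "bip"]),
         mixed = G)
}

# deterministic starting value for an inhibition constant from the trend of
# a per-I apparent quantity q(I) = q0 * (1 + I/K): through-origin regression
# of q/q0 - 1 on I
start_constant <- function(I, ratio_minus_1, fallback) {
  use <- I > 0 & is.finite(ratio_minus_1)
  if (!any(use)) return(fallback)
  b <- sum(I[use] * ratio_minus_1[use]) / sum(I[use]^2)
  if (!is.finite(b) || b <= 0) return(fallback)
  # clamp so that data with no trend (constant structurally absent) still
  # yield a usable, non-degenerate starting point
  min(max(1 / b, fallback / 100), fallback * 100)
}

#' Global fit of the general inhibitor model under a fixed mechanism
#'
#' Least-squares fit of v = Vmax * S / (KM (1 + I/Ki) + S (1 + I/Ki'))
#' across all (S, I) cells simultaneously, with only the inhibition
#' constants allowed by the mechanism as free parameters (an infinite
#' constant is removed from the model structurally, never fitted against a
#' large bound). Free constants are estimated on the inverse (affinity)
#' scale, so a constant the data cannot support tends to zero affinity and
#' is reported as infinite with an `unidentifiable` flag rather than
#' derailing the optimisation. A small-sample-corrected information
#' criterion (AICc) is
#' reported for cross-mechanism comparison; the mechanism verdict of the
#' pipeline nevertheless rests on the graphical discrimination, not on AICc.
#'
#' @param table a `rate_table` containing I = 0 and at least one more
#'   inhibitor level.
#' @param mechanism one of [mechanism_labels()].
#' @param weighted logical; 1/sem^2 weights.
#' @return An object of class `global_fit`: list with `mechanism`, `params`
#'   (a [kinetic_params()]), `se` (named SEs of the free parameters),
#'   `residual_ss`, `aic_c`, `n`, `converged`, `unidentifiable` (names of
#'   constants with relative SE > 1e3, if any).
#' @export
fit_global_inhibition <- function(table, mechanism, weighted = FALSE) {
  stopifnot(is.data.frame(table))
  mechanism <- match.arg(mechanism, mechanism_labels())
  dat <- data.frame(S = table$S_uM, I = table$I_uM,
                    v = table$v_pmol_min_ug, sem = table$sem)
  dat <- dat[dat$S > 0, ]
  levels_I <- sort(unique(dat$I))
  if (mechanism != "none") {
    if (length(levels_I) < 2 || !(0 %in% levels_I))
      stop("need at least 2 inhibitor levels including I = 0")
  }

  per_i <- fit_per_inhibitor_series(
    structure(data.frame(S_uM = dat$S, I_uM = dat$I, v_pmol_min_ug = dat$v,
                         sem = dat$sem), class = c("rate_table", "data.frame")),
    weighted = FALSE)
  app <- as.data.frame(per_i)
  KM0 <- app$KM_app[app$I_uM == min(levels_I)][1]
  Vmax0 <- app$Vmax_app[app$I_uM == min(levels_I)][1]
  fallback <- 2 * max(dat$I, 1)
  kip0 <- start_constant(app$I_uM, Vmax0 / app$Vmax_app - 1, fallback)
  ki0 <- start_constant(app$I_uM,
                        (app$KM_app / app$Vmax_app) / (KM0 / Vmax0) - 1,
                        fallback)
  start_all <- c(KM = KM0, Vmax = Vmax0,
                 bi = 1 / ki0, bip = 1 / kip0, bc = 1 / kip0)

  pars <- global_model_pars(mechanism)
  w <- rep(1, nrow(dat))
  if (weighted) {
    if (any(dat$sem <= 0)) stop("weighted fit requires strictly positive SEMs")
    w <- 1 / dat$sem^2
  }
  sw <- sqrt(w)
  resid_fn <- function(p)
    sw * (dat$v - global_model_v(expand_theta(p, mechanism), dat$S, dat$I))
  jac_fn <- function(p) -sw * global_model_grad(p, mechanism, dat$S, dat$I)
  lower <- stats::setNames(c(1e-9, 1e-9, rep(0, length(pars) - 2)), pars)
  out <- tryCatch(
    minpack.lm::nls.lm(par = start_all[pars], fn = resid_fn, jac = jac_fn,
                       lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("global %s fit failed: %s", mechanism,
                   conditionMessage(e))))
  if (!out$info %in% 1:4 || !is.finite(out$deviance))
    stop(sprintf(
      "global %s fit did not converge (start %s; final deviance %g)",
      mechanism, paste(sprintf("%s = %.4g", pars, start_all[pars]),
                       collapse = ", "), out$deviance))
  est <- stats::setNames(out$par, pars)
  rss <- sum(resid_fn(out$par)^2)
  # SEs from the Jacobian at the solution
  J <- jac_fn(out$par)
  dof <- nrow(dat) - length(pars)
  se <- tryCatch({
    covm <- solve(crossprod(J)) * rss / max(dof, 1)
    stats::setNames(sqrt(pmax(diag(covm), 0)), pars)
  }, error = function(e) stats::setNames(rep(NA_real_, length(pars)), pars))

  inv <- function(nm) if (nm %in% names(est) && est[[nm]] > 0)
    1 / est[[nm]] else Inf
  ki_est <- switch(mechanism, competitive = inv("bi"), mixed = inv("bi"),
                   noncompetitive = inv("bc"), Inf)
  kip_est <- switch(mechanism, uncompetitive = inv("bip"),
                    mixed = inv("bip"), noncompetitive = inv("bc"), Inf)
  params <- kinetic_params(KM = est[["KM"]], Vmax = est[["Vmax"]],
                           Ki = ki_est, Ki_prime = kip_est)
  # delta-method SEs on the constant scale: se(1/b) = se(b)/b^2
  se_out <- c(KM = unname(se[["KM"]]), Vmax = unname(se[["Vmax"]]))
  for (nm in intersect(names(est), c("bi", "bip", "bc"))) {
    knm <- c(bi = "Ki", bip = "Ki_prime", bc = "K")[[nm]]
    se_out[[knm]] <- if (est[[nm]] > 0) se[[nm]] / est[[nm]]^2 else NA_real_
  }
  rel_se <- se / abs(est)
  constants <- intersect(names(est), c("bi", "bip", "bc"))
  # flagged when the SE swamps the estimate or the implied constant lies
  # orders of magnitude beyond the probed inhibitor range
  i_max <- max(dat$I)
  unident <- constants[!is.finite(rel_se[constants]) |
                         rel_se[constants] > 1e3 |
                         est[constants] < 1 / (1e3 * i_max)]
  structure(
    list(mechanism = mechanism, params = params, se = se_out,
         residual_ss = rss,
         aic_c = aicc(rss, nrow(dat), length(pars)),
         n = nrow(dat), converged = out$info %in% 1:4,
         unidentifiable = unident),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global %s fit: RSS = %.4g, AICc = %.4g\n",
              x$mechanism, x$residual_ss, x$aic_c))
  print(x$params)
  invisible(x)
}

#' Fit every inhibition mechanism globally and tabulate the comparison
#'
#' @param table a `rate_table`.
#' @param mechanisms labels to fit (default: all five).
#' @param weighted logical.
#' @return A list with `fits` (named list of `global_fit`) and `comparison`
#'   (data frame of mechanism, residual_ss, aic_c, converged).
#' @export
compare_mechanisms <- function(table, mechanisms = mechanism_labels(),
                               weighted = FALSE) {
  fits <- lapply(mechanisms, function(m)
    tryCatch(fit_global_inhibition(table, m, weighted = weighted),
             error = function(e) NULL))
  names(fits) <- mechanisms
  ok <- !vapply(fits, is.null, logical(1))
  comparison <- do.call(rbind, lapply(fits[ok], function(f)
    data.frame(mechanism = f$mechanism, residual_ss = f$residual_ss,
               aic_c = f$aic_c, converged = f$converged)))
  rownames(comparison) <- NULL
  list(fits = fits[ok], comparison = comparison)
}
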