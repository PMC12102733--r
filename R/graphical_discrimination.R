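#' Secondary-plot lines (Dixon and substrate-over-velocity)
#'
#' For each substrate level S, a straight line of a transformed velocity
#' against inhibitor concentration is fitted by ordinary least squares to the
#' replicate-mean points of the rate table:
#'
#' * Dixon: y = 1/v (min ug pmol^-1) vs I. Under the general inhibitor
#'   model, 1/v = KM (1 + I/Ki) / (Vmax S) + (1 + I/Ki') / Vmax, so the
#'   lines are parallel exactly when Ki is infinite (uncompetitive) and
#'   concurrent at I = -Ki otherwise.
#' * S/v: y = S/v with S in nM, so y carries min ug units. Here
#'   S/v = KM (1 + I/Ki) / Vmax + S (1 + I/Ki') / Vmax: parallel when Ki' is
#'   infinite (competitive), otherwise concurrent at I = -Ki' with
#'   y = KM (1 - Ki'/Ki) / Vmax -- for an uncompetitive inhibitor simply
#'   y = KM/Vmax.
#'
#' Each line is also expressed in the implicit form a x + b y + c = 0
#' normalised to b = -1 (a = slope, c = intercept), which is the form the
#' intersection estimator consumes.
#'
#' @param table a `rate_table`; substrate levels with any non-positive mean
#'   velocity are dropped with a warning.
#' @param weighting `"none"` for ordinary least squares; `"cv"` to weight
#'   points by 1/y^2, which equalises their influence when velocities carry
#'   a roughly constant coefficient of variation (the reciprocal transform
#'   otherwise makes low-velocity points dominate the residuals); `"sem"`
#'   to weight by the inverse squared delta-method SEM of the transformed
#'   quantity.
#' @return An object of class `secondary_lines`: a list of per-S lines, each
#'   with fields `S`, `kind`, `slope`, `intercept`, `slope_se`, `a`, `b`,
#'   `c`, and `points` (data frame I, y, weight).
#' @export
dixon_lines <- function(table, weighting = c("none", "cv", "sem")) {
  secondary_lines(table, kind = "dixon", weighting = weighting)
}

#' @rdname dixon_lines
#' @export
cornish_bowden_lines <- function(table, weighting = c("none", "cv", "sem")) {
  secondary_lines(table, kind = "s_over_v", weighting = weighting)
}

secondary_lines <- function(table, kind = c("dixon", "s_over_v"),
                            weighting = c("none", "cv", "sem")) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(table))
  tab <- as.data.frame(table)[table$S_uM > 0, ]
  S_levels <- sort(unique(tab$S_uM))
  usable <- vapply(S_levels, function(s)
    all(tab$v_pmol_min_ug[tab$S_uM == s] > 0), logical(1))
  if (any(!usable))
    warning("dropping substrate level(s) with non-positive velocity: ",
            paste(S_levels[!usable], collapse = ", "))
  S_levels <- S_levels[usable]
  if (length(S_levels) < 2)
    stop("need at least 2 usable substrate levels for secondary plots")

  lines <- lapply(S_levels, function(s) {
    g <- tab[tab$S_uM == s, ]
    g <- g[order(g$I_uM), ]
    if (kind == "dixon") {
      y <- 1 / g$v_pmol_min_ug
      sem_y <- g$sem / g$v_pmol_min_ug^2
    } else {
      s_nM <- s * 1000
      y <- s_nM / g$v_pmol_min_ug
      sem_y <- s_nM * g$sem / g$v_pmol_min_ug^2
    }
    w <- switch(weighting,
                none = rep(1, length(y)),
                cv = 1 / y^2,
                sem = {
                  if (any(sem_y <= 0))
                    stop("SEM weighting requires strictly positive SEMs")
                  1 / sem_y^2
                })
    fit <- stats::lm(y ~ I, data = data.frame(I = g$I_uM, y = y), weights = w)
    # summary() warns on interpolating fits; noise-free tables are routine
    # here, so the perfect-fit warning carries no information
    cf <- suppressWarnings(summary(fit))$coefficients
    list(S = s, kind = kind,
         slope = cf["I", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
         slope_se = cf["I", "Std. Error"],
         a = cf["I", "Estimate"], b = -1, c = cf["(Intercept)", "Estimate"],
         points = data.frame(I = g$I_uM, y = y, weight = w))
  })
  structure(lines, kind = kind, class = "secondary_lines")
}

#' @export
print.secondary_lines <- function(x, ...) {
  cat(attr(x, "kind"), "secondary plot,", length(x), "lines\n")
  print(data.frame(S_uM = vapply(x, `[[`, numeric(1), "S"),
                   slope = vapply(x, `[[`, numeric(1), "slope"),
                   intercept = vapply(x, `[[`, numeric(1), "intercept")))
  invisible(x)
}

line_slopes <- function(lines) vapply(lines, `[[`, numeric(1), "slope")

relative_slope_spread <- function(slopes) {
  m <- mean(abs(slopes))
  if (m == 0) return(0)
  (max(slopes) - min(slopes)) / m
}

#' Closest-neighbour intersection of a pencil of lines
#'
#' Finds the point (x*, y*) minimising the sum of squared perpendicular
#' distances to a set of lines given in implicit form a_i x + b_i y + c_i = 0:
#' \deqn{\sum_i \frac{(a_i x + b_i y + c_i)^2}{a_i^2 + b_i^2}.}
#' The minimiser solves a 2x2 linear system in closed form. For two
#' non-parallel lines it is their exact intersection (zero residual). When
#' all lines are mutually parallel (relative slope spread below
#' `parallel_tol`, or a numerically singular system) the result is flagged
#' as having no finite intersection rather than raising an error.
#'
#' @param lines a `secondary_lines` object (or list of lines with fields
#'   `a`, `b`, `c`).
#' @param parallel_tol relative slope spread below which the pencil is
#'   treated as exactly parallel.
#' @return An object of class `intersection_estimate`: list with `x_star`,
#'   `y_star`, `residual`, `n_lines`, and the logical `finite`.
#' @export
closest_neighbor_intersection <- function(lines, parallel_tol = 1e-8) {
  if (length(lines) < 2) stop("need at least 2 lines")
  a <- vapply(lines, `[[`, numeric(1), "a")
  b <- vapply(lines, `[[`, numeric(1), "b")
  cc <- vapply(lines, `[[`, numeric(1), "c")
  no_int <- structure(list(x_star = NA_real_, y_star = NA_real_,
                           residual = NA_real_, n_lines = length(lines),
                           finite = FALSE),
                      class = "intersection_estimate")
  if (relative_slope_spread(-a / b) < parallel_tol) return(no_int)
  w <- 1 / (a^2 + b^2)
  M <- rbind(c(sum(w * a^2), sum(w * a * b)),
             c(sum(w * a * b), sum(w * b^2)))
  rhs <- -c(sum(w * a * cc), sum(w * b * cc))
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(no_int)
  res <- sum(w * (a * sol[1] + b * sol[2] + cc)^2)
  structure(list(x_star = sol[1], y_star = sol[2], residual = res,
                 n_lines = length(lines), finite = TRUE),
            class = "intersection_estimate")
}

#' @export
print.intersection_estimate <- function(x, ...) {
  if (x$finite)
    cat(sprintf("Intersection of %d lines at (%.4g, %.4g), residual %.3g\n",
                x$n_lines, x$x_star, x$y_star, x$residual))
  else
    cat(sprintf("No finite intersection (%d mutually parallel lines)\n",
                x$n_lines))
  invisible(x)
}

#' Test a pencil of secondary-plot lines for a shared slope
#'
#' Extra-sum-of-squares F-test comparing a shared-slope model (separate
#' intercepts, one slope) against a free-slopes model (separate intercepts
#' and slopes) over all lines' points. The pencil is called parallel when
#' the test fails to reject at level `alpha` and, as a guard against
#' vacuously non-significant but structurally different slopes, the relative
#' slope spread stays below `spread_guard`. When both models fit the points
#' essentially exactly (noise-free data) the F statistic is undefined and
#' the verdict falls back to the slope spread alone.
#'
#' @param lines a `secondary_lines` object with point data attached.
#' @param alpha significance level (default 0.05).
#' @param spread_guard maximum relative slope spread, (max - min) /
#'   mean |slope|, for a parallel verdict.
#' @return List with `parallel`, `f_statistic`, `p_value`, `df`, `spread`.
#' @export
parallelism_test <- function(lines, alpha = 0.05, spread_guard = 1) {
  if (length(lines) < 2) stop("need at least 2 lines")
  pts <- do.call(rbind, lapply(lines, function(l)
    data.frame(line = sprintf("S%g", l$S), I = l$points$I, y = l$points$y,
               w = l$points$weight)))
  if (nrow(pts) < 2 * length(lines) + 1)
    stop("not enough points to fit the free-slope model")
  pts$line <- factor(pts$line)
  shared <- stats::lm(y ~ line + I, data = pts, weights = pts$w)
  free <- stats::lm(y ~ line + line:I, data = pts, weights = pts$w)
  rss_s <- sum(stats::weighted.residuals(shared)^2)
  rss_f <- sum(stats::weighted.residuals(free)^2)
  df1 <- length(lines) - 1
  df2 <- stats::df.residual(free)
  spread <- relative_slope_spread(line_slopes(lines))
  scale0 <- sum(pts$w * pts$y^2)
  if (rss_f <= 1e-20 * scale0 && rss_s <= 1e-20 * scale0) {
    # both models interpolate: noise-free pencil, judge by slopes alone
    fstat <- NA_real_
    p <- NA_real_
    parallel <- spread < 1e-8
  } else {
    fstat <- ((rss_s - rss_f) / df1) / (rss_f / df2)
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    parallel <- is.finite(p) && p > alpha && spread < spread_guard
  }
  list(parallel = parallel, f_statistic = fstat, p_value = p,
       df = c(df1, df2), spread = spread)
}

# equality test for the Dixon and S/v convergence abscissae: nested
# extra-sum-of-squares F-test of the noncompetitive rate law (Ki = Ki')
# inside the mixed one, on the velocity scale where the replicate-mean
# errors are independent across (S, I) cells; on noise-free tables (both
# residuals essentially zero) the abscissae are compared directly
abscissae_equal <- function(table, x_dx, x_sv, alpha) {
  fits <- tryCatch(list(nc = fit_global_inhibition(table, "noncompetitive"),
                        mx = fit_global_inhibition(table, "mixed")),
                   error = function(e) NULL)
  if (is.null(fits))
    return(abs(x_dx - x_sv) <= 1e-6 * mean(abs(c(x_dx, x_sv))))
  scale0 <- sum(table$v_pmol_min_ug^2)
  if (fits$mx$residual_ss <= 1e-20 * scale0 &&
      fits$nc$residual_ss <= 1e-20 * scale0)
    return(abs(x_dx - x_sv) <= 1e-6 * mean(abs(c(x_dx, x_sv))))
  df2 <- fits$mx$n - 4
  f <- (fits$nc$residual_ss - fits$mx$residual_ss) /
    (fits$mx$residual_ss / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  is.finite(p) && p > alpha
}

#' Classify the inhibition mechanism from the two secondary plots
#'
#' Implements the graphical discrimination rules:
#'
#' * Dixon lines parallel and S/v lines intersecting at x < 0:
#'   uncompetitive, with Ki' = -x*.
#' * S/v lines parallel and Dixon lines intersecting at x < 0: competitive,
#'   with Ki = -x*.
#' * Both pencils intersecting at x < 0: the two plots' convergence
#'   abscissae are tested for equality -- equal abscissae mean a single
#'   inhibition constant, i.e. noncompetitive inhibition, and unequal ones
#'   mean mixed inhibition. Because the two pencils are deterministic
#'   transforms of the same velocities, the equality test is carried out on
#'   the velocity scale as the extra-sum-of-squares F-test of the
#'   noncompetitive rate law (Ki = Ki') nested in the mixed one. Failing to
#'   reject at `alpha` yields noncompetitive (Ki = Ki' from the mean
#'   abscissa); rejecting yields mixed (Ki from the Dixon abscissa, Ki'
#'   from the S/v abscissa).
#' * Anything else (positive intersection abscissae, parallel/parallel,
#'   failed estimates): indeterminate.
#'
#' @param table a `rate_table`.
#' @param alpha significance level for the parallelism tests and the
#'   noncompetitive-vs-mixed equality test.
#' @param spread_guard passed to [parallelism_test()].
#' @param weighting point weighting for the secondary-line fits and the
#'   parallelism tests, see [dixon_lines()]. The default `"cv"` assumes a
#'   constant coefficient of variation on the velocities, which keeps the
#'   parallelism F-test close to its nominal level; `"none"` reproduces
#'   plain OLS lines.
#' @param zero_I_fit optional `mm_fit` at I = 0 used for the KM/Vmax
#'   consistency check; fitted from the table when absent.
#' @return An object of class `mechanism_call`: verdict, ki, ki_prime, the
#'   two parallelism tests, the two intersection estimates, and
#'   `consistency_pct` (percent difference between the S/v intersection
#'   ordinate and KM/Vmax at I = 0; `NA` when not applicable).
#' @export
classify_mechanism <- function(table, alpha = 0.05, spread_guard = 1,
                               weighting = "cv", zero_I_fit = NULL) {
  dx <- dixon_lines(table, weighting = weighting)
  sv <- cornish_bowden_lines(table, weighting = weighting)
  # with too few points for the free-slope model (e.g. only two inhibitor
  # levels) fall back to judging parallelism by exact slope agreement
  spread_only <- function(lines) {
    warning("too few points for the parallelism F-test; ",
            "judging by slope spread only")
    spread <- relative_slope_spread(line_slopes(lines))
    list(parallel = spread < 1e-8, f_statistic = NA_real_,
         p_value = NA_real_, df = c(NA_real_, NA_real_), spread = spread)
  }
  t_dx <- tryCatch(
    parallelism_test(dx, alpha = alpha, spread_guard = spread_guard),
    error = function(e) spread_only(dx))
  t_sv <- tryCatch(
    parallelism_test(sv, alpha = alpha, spread_guard = spread_guard),
    error = function(e) spread_only(sv))
  i_dx <- closest_neighbor_intersection(dx)
  i_sv <- closest_neighbor_intersection(sv)

  verdict <- "indeterminate"
  ki <- NA_real_; ki_prime <- NA_real_
  if (t_dx$parallel && !t_sv$parallel && i_sv$finite && i_sv$x_star < 0) {
    verdict <- "uncompetitive"
    ki <- Inf
    ki_prime <- -i_sv$x_star
  } else if (t_sv$parallel && !t_dx$parallel && i_dx$finite &&
             i_dx$x_star < 0) {
    verdict <- "competitive"
    ki <- -i_dx$x_star
    ki_prime <- Inf
  } else if (!t_dx$parallel && !t_sv$parallel &&
             i_dx$finite && i_sv$finite &&
             i_dx$x_star < 0 && i_sv$x_star < 0) {
    if (abscissae_equal(table, i_dx$x_star, i_sv$x_star, alpha)) {
      verdict <- "noncompetitive"
      ki <- ki_prime <- -mean(c(i_dx$x_star, i_sv$x_star))
    } else {
      verdict <- "mixed"
      ki <- -i_dx$x_star
      ki_prime <- -i_sv$x_star
    }
  }

  consistency <- NA_real_
  if (i_sv$finite && i_sv$x_star < 0) {
    if (is.null(zero_I_fit)) {
      g0 <- table[table$I_uM == min(table$I_uM), ]
      zero_I_fit <- tryCatch(
        fit_michaelis_menten(g0$S_uM, g0$v_pmol_min_ug, I = g0$I_uM[1]),
        error = function(e) NULL)
    }
    if (!is.null(zero_I_fit))
      consistency <- consistency_check(i_sv, zero_I_fit)
  }

  structure(
    list(verdict = verdict, ki = ki, ki_prime = ki_prime,
         dixon_parallel = t_dx$parallel, dixon_test = t_dx,
         sv_parallel = t_sv$parallel, sv_test = t_sv,
         intersection_dixon = i_dx, intersection_sv = i_sv,
         dixon_lines = dx, sv_lines = sv,
         consistency_pct = consistency),
    class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Mechanism verdict:", x$verdict, "\n")
  cat(sprintf("  Dixon lines parallel: %s (p = %s, spread = %.3g)\n",
              x$dixon_parallel, format(x$dixon_test$p_value, digits = 3),
              x$dixon_test$spread))
  cat(sprintf("  S/v lines parallel:   %s (p = %s, spread = %.3g)\n",
              x$sv_parallel, format(x$sv_test$p_value, digits = 3),
              x$sv_test$spread))
  if (is.finite(x$ki)) cat(sprintf("  Ki  = %.4g uM\n", x$ki))
  if (is.finite(x$ki_prime)) cat(sprintf("  Ki' = %.4g uM\n", x$ki_prime))
  if (is.finite(x$consistency_pct))
    cat(sprintf("  KM/Vmax consistency: %.2f%% difference\n",
                x$consistency_pct))
  invisible(x)
}

#' Consistency check of the S/v intersection against KM/Vmax
#'
#' For inhibitors that do not bind free enzyme, the ordinate of the common
#' S/v intersection equals KM/Vmax. This check compares the estimated
#' intersection ordinate y* with the ratio r = KM/Vmax (KM in nM so the
#' units are min ug) from the zero-inhibitor Michaelis-Menten fit and
#' returns the percent difference 100 |y* - r| / mean(y*, r).
#'
#' @param estimate an `intersection_estimate` (or a bare ordinate value).
#' @param zero_I_fit an `mm_fit` at I = 0, or a list with `KM` (uM) and
#'   `Vmax`.
#' @return Percent difference (scalar).
#' @export
consistency_check <- function(estimate, zero_I_fit) {
  y_star <- if (inherits(estimate, "intersection_estimate")) {
    if (!estimate$finite) stop("no finite intersection to check")
    estimate$y_star
  } else estimate
  r <- zero_I_fit$KM * 1000 / zero_I_fit$Vmax
  if (!is.finite(r) || r <= 0)
    stop("zero-inhibitor KM/Vmax ratio must be positive")
  100 * abs(y_star - r) / mean(c(y_star, r))
}
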