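#' Inhibition mechanism labels
#'
#' The general (mixed) inhibitor rate law
#' \deqn{v = \frac{V_{max} S}{K_M (1 + I/K_i) + S (1 + I/K_i')}}
#' contains two inhibition constants: \eqn{K_i}, the dissociation constant of
#' the inhibitor from free enzyme (EI complex), and \eqn{K_i'}, its
#' dissociation constant from the enzyme-substrate complex (ESI). The
#' classical mechanisms correspond to finiteness patterns of the pair:
#'
#' * `"none"`: both infinite (no inhibition);
#' * `"competitive"`: finite \eqn{K_i}, infinite \eqn{K_i'};
#' * `"uncompetitive"`: infinite \eqn{K_i}, finite \eqn{K_i'};
#' * `"noncompetitive"`: both finite and equal;
#' * `"mixed"`: both finite and unequal.
#'
#' @return Character vector of the recognised mechanism labels.
#' @export
mechanism_labels <- function() {
  c("none", "competitive", "noncompetitive", "mixed", "uncompetitive")
}

#' Infer the mechanism label from the two inhibition constants
#'
#' @param Ki inhibition constant of the EI complex (uM); may be `Inf`.
#' @param Ki_prime inhibition constant of the ESI complex (uM); may be `Inf`.
#' @return One of [mechanism_labels()].
#' @export
mechanism_from_constants <- function(Ki, Ki_prime) {
  fi <- is.finite(Ki)
  fp <- is.finite(Ki_prime)
  if (!fi && !fp) return("none")
  if (fi && !fp) return("competitive")
  if (!fi && fp) return("uncompetitive")
  if (isTRUE(all.equal(Ki, Ki_prime))) "noncompetitive" else "mixed"
}

#' Kinetic parameter set for the general inhibitor model
#'
#' Bundles the Michaelis constant, maximal specific activity and the two
#' inhibition constants, together with the mechanism label they imply.
#' Infinite constants are represented explicitly as `Inf` (never as a large
#' sentinel number) so that the corresponding `I/K` term is exactly zero.
#'
#' @param KM Michaelis constant (uM), positive.
#' @param Vmax maximal velocity as specific activity (pmol min^-1 ug^-1),
#'   positive.
#' @param Ki inhibition constant of the EI complex (uM); `Inf` when the
#'   inhibitor does not bind free enzyme.
#' @param Ki_prime inhibition constant of the ESI complex (uM); `Inf` when
#'   the inhibitor does not bind the enzyme-substrate complex.
#' @param mechanism optional label; when supplied it must agree with the
#'   finiteness pattern of `(Ki, Ki_prime)`.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(KM = 93.9, Vmax = 33.02, Ki_prime = 44.3)  # uncompetitive
#' @export
kinetic_params <- function(KM, Vmax, Ki = Inf, Ki_prime = Inf,
                           mechanism = NULL) {
  for (nm in c("KM", "Vmax", "Ki", "Ki_prime")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("'%s' must be a single non-missing number", nm))
  }
  if (!(KM > 0) || !is.finite(KM)) stop("'KM' must be positive and finite")
  if (!(Vmax > 0) || !is.finite(Vmax)) stop("'Vmax' must be positive and finite")
  if (!(Ki > 0)) stop("'Ki' must be positive (possibly Inf)")
  if (!(Ki_prime > 0)) stop("'Ki_prime' must be positive (possibly Inf)")
  implied <- mechanism_from_constants(Ki, Ki_prime)
  if (is.null(mechanism)) {
    mechanism <- implied
  } else {
    mechanism <- match.arg(mechanism, mechanism_labels())
    if (mechanism != implied)
      stop(sprintf(
        "mechanism '%s' inconsistent with (Ki = %g, Ki' = %g), which imply '%s'",
        mechanism, Ki, Ki_prime, implied))
  }
  structure(
    list(KM = KM, Vmax = Vmax, Ki = Ki, Ki_prime = Ki_prime,
         mechanism = mechanism),
    class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$mechanism, ")\n", sep = "")
  cat(sprintf("  KM   = %g uM\n  Vmax = %g pmol min^-1 ug^-1\n", x$KM, x$Vmax))
  cat(sprintf("  Ki   = %g uM\n  Ki'  = %g uM\n", x$Ki, x$Ki_prime))
  invisible(x)
}

check_nonneg <- function(x, nm) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", nm))
}

#' Michaelis-Menten velocity
#'
#' Uninhibited rate law \eqn{v = V_{max} S / (K_M + S)}.
#'
#' @param S substrate concentration (uM), vectorised.
#' @param KM Michaelis constant (uM).
#' @param Vmax maximal specific activity (pmol min^-1 ug^-1).
#' @return Velocity in pmol min^-1 ug^-1.
#' @examples
#' mm_velocity(93.9, KM = 93.9, Vmax = 33.02)  # half-maximal: 16.51
#' @export
mm_velocity <- function(S, KM, Vmax) {
  check_nonneg(S, "S")
  if (!is.numeric(KM) || length(KM) != 1L || !is.finite(KM) || KM <= 0)
    stop("'KM' must be a single positive finite number")
  if (!is.numeric(Vmax) || length(Vmax) != 1L || !is.finite(Vmax) || Vmax <= 0)
    stop("'Vmax' must be a single positive finite number")
  Vmax * S / (KM + S)
}

#' Velocity under the general inhibitor model
#'
#' Rate law \eqn{v = V_{max} S / (K_M (1 + I/K_i) + S (1 + I/K_i'))}.
#' An infinite inhibition constant makes its `I/K` term exactly zero, so the
#' expression specialises to the competitive, uncompetitive, noncompetitive
#' or uninhibited law according to `params$mechanism`. At `I = 0` it equals
#' [mm_velocity()].
#'
#' @param S substrate concentration (uM), vectorised (recycled against `I`).
#' @param I inhibitor concentration (uM), vectorised.
#' @param params a [kinetic_params()] object.
#' @return Velocity in pmol min^-1 ug^-1.
#' @export
inhibited_velocity <- function(S, I, params) {
  stopifnot(inherits(params, "kinetic_params"))
  check_nonneg(S, "S")
  check_nonneg(I, "I")
  # I/Inf is exactly 0 in IEEE arithmetic, so infinite constants drop out
  params$Vmax * S /
    (params$KM * (1 + I / params$Ki) + S * (1 + I / params$Ki_prime))
}

#' Apparent Michaelis-Menten parameters at a fixed inhibitor concentration
#'
#' At fixed `I` the general inhibitor model is itself Michaelis-Menten in `S`
#' with
#' \deqn{K_M^{app} = K_M \frac{1 + I/K_i}{1 + I/K_i'}, \qquad
#'       V_{max}^{app} = \frac{V_{max}}{1 + I/K_i'}.}
#' For an uncompetitive inhibitor both parameters shrink by the same factor,
#' so the ratio \eqn{K_M^{app}/V_{max}^{app}} is invariant in `I` -- the
#' structural fact behind the Cornish-Bowden plot's common intersection.
#'
#' @param params a [kinetic_params()] object.
#' @param I inhibitor concentration (uM), vectorised.
#' @return A data frame with columns `I`, `KM_app`, `Vmax_app`.
#' @export
apparent_parameters <- function(params, I) {
  stopifnot(inherits(params, "kinetic_params"))
  check_nonneg(I, "I")
  fac_i <- 1 + I / params$Ki
  fac_p <- 1 + I / params$Ki_prime
  data.frame(I = I,
             KM_app = params$KM * fac_i / fac_p,
             Vmax_app = params$Vmax / fac_p)
}
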