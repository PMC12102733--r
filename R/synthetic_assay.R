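#' Fluorogenic microplate assay design
#'
#' Describes a kinetic plate-reader experiment: which substrate and inhibitor
#' concentrations are dispensed, how many replicates, how much enzyme, how
#' often the plate is read, and the statistical imperfections of the
#' measurement (detector noise, pipetting error). The defaults emulate an
#' endopeptidase assay run with 20 ng of enzyme in 100 uL per well, substrate
#' from 0 to 200 uM, inhibitor from 0 to 25 uM, triplicates, and fluorescence
#' read every 45 s for 1400 s.
#'
#' @param S_grid substrate concentrations (uM), excluding the blank; blanks
#'   at S = 0 are always generated.
#' @param I_grid inhibitor concentrations (uM); should include 0.
#' @param replicates number of replicate wells per (S, I) cell.
#' @param enzyme_mass enzyme per well (ug).
#' @param well_volume reaction volume (uL).
#' @param read_interval time between reads (s).
#' @param duration total read time (s); reads at `seq(0, duration, read_interval)`.
#' @param gain detector gain (AU per pmol of released fluorophore).
#' @param baseline fluorescence offset (AU).
#' @param noise_sd additive Gaussian read noise (AU).
#' @param pipetting_cv coefficient of variation of the lognormal error on the
#'   actually dispensed substrate and inhibitor concentrations (the metadata
#'   keeps the nominal values, as on a real plate).
#' @param depletion logical; if `TRUE`, substrate consumption is integrated
#'   so progress curves bend as substrate runs out; if `FALSE`, product
#'   accumulates at the constant initial rate.
#' @param seed RNG seed used by [simulate_plate()].
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(S_grid = c(12.5, 25, 50, 100, 150, 200),
                         I_grid = c(0, 6.25, 12, 20, 25),
                         replicates = 3,
                         enzyme_mass = 0.02,
                         well_volume = 100,
                         read_interval = 45,
                         duration = 1400,
                         gain = 300,
                         baseline = 50,
                         noise_sd = 5,
                         pipetting_cv = 0.02,
                         depletion = FALSE,
                         seed = 1L) {
  check_nonneg(S_grid, "S_grid")
  check_nonneg(I_grid, "I_grid")
  stopifnot(replicates >= 1, read_interval > 0, duration >= read_interval,
            gain > 0, noise_sd >= 0, pipetting_cv >= 0,
            enzyme_mass >= 0, well_volume > 0)
  if (any(duplicated(S_grid))) stop("duplicated substrate levels in 'S_grid'")
  if (any(duplicated(I_grid))) stop("duplicated inhibitor levels in 'I_grid'")
  structure(
    list(S_grid = sort(S_grid[S_grid > 0]), I_grid = sort(I_grid),
         replicates = as.integer(replicates),
         enzyme_mass = enzyme_mass, well_volume = well_volume,
         read_interval = read_interval, duration = duration,
         gain = gain, baseline = baseline, noise_sd = noise_sd,
         pipetting_cv = pipetting_cv, depletion = isTRUE(depletion),
         seed = seed),
    class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design:",
      length(x$S_grid), "substrate levels x",
      length(x$I_grid), "inhibitor levels x",
      x$replicates, "replicates (+ blanks)\n")
  cat(sprintf("  enzyme %g ug in %g uL; reads every %g s for %g s\n",
              x$enzyme_mass, x$well_volume, x$read_interval, x$duration))
  cat(sprintf("  gain %g AU/pmol, baseline %g AU, noise sd %g AU, pipetting CV %g\n",
              x$gain, x$baseline, x$noise_sd, x$pipetting_cv))
  cat("  substrate depletion:", if (x$depletion) "integrated" else "off", "\n")
  invisible(x)
}

read_times <- function(design) seq(0, design$duration, by = design$read_interval)

#' Product formed over time in a single well (noise-free)
#'
#' With depletion off the product accumulates linearly at the initial rate.
#' With depletion on, substrate consumption dS/dt = -v(S) * mass/volume
#' (uM min^-1) is integrated with a fixed-step classical Runge-Kutta scheme
#' on a 1 s internal grid and sampled at the requested times; the released
#' product is bounded by the substrate initially present.
#'
#' @param design an [assay_design()].
#' @param truth a [kinetic_params()] ground truth.
#' @param S,I actual substrate and inhibitor concentrations in the well (uM).
#' @param times times (s) at which to evaluate.
#' @return Product in pmol at each time.
#' @keywords internal
product_curve <- function(design, truth, S, I, times) {
  if (design$enzyme_mass == 0 || S == 0)
    return(rep(0, length(times)))
  if (!design$depletion) {
    v <- inhibited_velocity(S, I, truth)          # pmol min^-1 ug^-1
    return(v * design$enzyme_mass * times / 60)   # pmol
  }
  grid <- sort(unique(c(seq(0, max(times), by = 1), times)))
  deriv <- function(t, y, parms) {
    s <- max(y[1], 0)
    list(-inhibited_velocity(s, I, truth) * design$enzyme_mass /
           design$well_volume / 60)               # uM s^-1
  }
  sol <- deSolve::ode(y = c(S = S), times = grid, func = deriv, parms = NULL,
                      method = "rk4")
  s_t <- sol[match(times, sol[, "time"]), "S"]
  if (anyNA(s_t) || any(!is.finite(s_t)))
    stop("progress-curve integration produced non-finite substrate values")
  (S - s_t) * design$well_volume                  # pmol
}

#' Simulate one progress curve
#'
#' Forward model of a single well: fluorescence(t) = gain * P(t) + baseline +
#' Gaussian read noise, with the product P(t) from [product_curve()]. Noise is
#' drawn from the current RNG state.
#'
#' @inheritParams product_curve
#' @param S_nominal,I_nominal concentrations recorded in the metadata
#'   (default: the actual ones). [simulate_plate()] passes pipetting-perturbed
#'   actual values with nominal labels.
#' @param well_id well label.
#' @param replicate replicate index.
#' @return A data frame (one row per read) with columns `well_id`, `S_uM`,
#'   `I_uM`, `replicate`, `time_s`, `fluorescence_au`.
#' @export
simulate_progress_curve <- function(design, truth, S, I,
                                    S_nominal = S, I_nominal = I,
                                    well_id = "w1", replicate = 1L) {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "kinetic_params"))
  check_nonneg(S, "S"); check_nonneg(I, "I")
  times <- read_times(design)
  P <- product_curve(design, truth, S, I, times)
  if (any(!is.finite(P)))
    stop(sprintf("non-finite product trace in well '%s'", well_id))
  noise <- if (design$noise_sd > 0)
    stats::rnorm(length(times), 0, design$noise_sd) else 0
  data.frame(well_id = well_id, S_uM = S_nominal, I_uM = I_nominal,
             replicate = as.integer(replicate), time_s = times,
             fluorescence_au = design$gain * P + design$baseline + noise)
}

pipetting_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Simulate a full kinetic plate
#'
#' Generates one progress curve per (S, I, replicate) cell plus substrate-free
#' blanks at every (I, replicate). Dispensed concentrations are perturbed by
#' the design's pipetting error but recorded at their nominal values,
#' mimicking real plate metadata. Wells are generated in a fixed canonical
#' order (inhibitor, then substrate with blanks first, then replicate) from a
#' single RNG stream seeded by `design$seed`, so a plate is fully reproducible.
#'
#' @param design an [assay_design()].
#' @param truth a [kinetic_params()] ground truth.
#' @return A long-format data frame of class `plate_data` (one row per read),
#'   with the design and truth attached as attributes.
#' @export
simulate_plate <- function(design, truth) {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "kinetic_params"))
  if (!is.null(design$seed)) set.seed(design$seed)
  cells <- expand.grid(replicate = seq_len(design$replicates),
                       S = c(0, design$S_grid), I = design$I_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$I, cells$S, cells$replicate), ]
  fS <- pipetting_factor(nrow(cells), design$pipetting_cv)
  fI <- pipetting_factor(nrow(cells), design$pipetting_cv)
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    S <- cells$S[k]; I <- cells$I[k]; r <- cells$replicate[k]
    id <- sprintf("S%g_I%g_r%d", S, I, r)
    rows[[k]] <- simulate_progress_curve(
      design, truth, S = S * fS[k], I = I * fI[k],
      S_nominal = S, I_nominal = I, well_id = id, replicate = r)
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  class(plate) <- c("plate_data", "data.frame")
  attr(plate, "design") <- design
  attr(plate, "truth") <- truth
  plate
}

plate_columns <- c("well_id", "S_uM", "I_uM", "replicate", "time_s",
                   "fluorescence_au")

canonical_plate_order <- function(plate) {
  plate[order(plate$I_uM, plate$S_uM, plate$replicate, plate$well_id,
              plate$time_s), , drop = FALSE]
}

#' Write / read a plate as long-format CSV
#'
#' One row per read, header `well_id,S_uM,I_uM,replicate,time_s,
#' fluorescence_au`, numeric fields with 10 significant digits. The reader
#' validates the header, coerces types, canonicalises row order (so a
#' shuffled file parses to the same object) and checks that each well's
#' times are strictly increasing.
#'
#' @param plate a `plate_data` data frame (any data frame with the plate
#'   columns is accepted).
#' @param path file path.
#' @return `write_plate_csv` returns `path` invisibly; `read_plate_csv`
#'   returns a `plate_data` data frame.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(is.data.frame(plate))
  missing_cols <- setdiff(plate_columns, names(plate))
  if (length(missing_cols))
    stop("plate is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- plate[, plate_columns]
  for (nm in c("S_uM", "I_uM", "time_s", "fluorescence_au"))
    out[[nm]] <- sprintf("%.10g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- tryCatch(
    names(utils::read.csv(path, nrows = 1, check.names = FALSE)),
    error = function(e) stop("malformed plate CSV '", path, "': ",
                             conditionMessage(e)))
  missing_cols <- setdiff(plate_columns, header)
  if (length(missing_cols))
    stop("plate CSV '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "))
  plate <- tryCatch(
    utils::read.csv(path, colClasses = c(
      well_id = "character", S_uM = "numeric", I_uM = "numeric",
      replicate = "integer", time_s = "numeric", fluorescence_au = "numeric")),
    error = function(e) stop("malformed plate CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(plate) == 0) stop("plate CSV '", path, "' contains no reads")
  if (anyNA(plate[, plate_columns]))
    stop("plate CSV '", path, "' contains missing values")
  if (any(!is.finite(plate$fluorescence_au)))
    stop("plate CSV '", path, "' contains non-finite fluorescence")
  plate <- canonical_plate_order(plate)
  rownames(plate) <- NULL
  for (w in unique(plate$well_id)) {
    t <- plate$time_s[plate$well_id == w]
    if (any(diff(t) <= 0))
      stop(sprintf("well '%s': times are not strictly increasing", w))
  }
  class(plate) <- c("plate_data", "data.frame")
  plate
}
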