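#' Initial-rate estimation from a progress curve
#'
#' Ordinary least-squares line through the fluorescence reads falling in a
#' time window. The default window spans the whole trace, which matches
#' fitting a straight line to the full progress curve; narrower windows (or
#' the conversion-limited window of [build_rate_table()]) avoid the downward
#' bias that substrate depletion induces in full-trace slopes.
#'
#' @param curve a single well's reads: data frame with columns `time_s` and
#'   `fluorescence_au`.
#' @param window numeric length-2, time range (s) of reads to use.
#' @param r2_threshold reads below this R-squared raise a curvature flag.
#' @return A list with `slope` (AU s^-1), `slope_se`, `intercept`,
#'   `r_squared`, `n`, and the logical `curvature_flag`. For a flat trace
#'   (zero residual variance around a zero-slope line) R-squared is
#'   reported as 1.
#' @export
fit_initial_rate <- function(curve, window = c(0, Inf), r2_threshold = 0.98) {
  stopifnot(is.data.frame(curve),
            all(c("time_s", "fluorescence_au") %in% names(curve)))
  keep <- curve$time_s >= window[1] & curve$time_s <= window[2]
  t <- curve$time_s[keep]
  y <- curve$fluorescence_au[keep]
  if (length(t) < 3) stop("need at least 3 reads in the window")
  sxx <- sum((t - mean(t))^2)
  if (sxx == 0) stop("zero time variance in the window")
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  res <- y - intercept - slope * t
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  se <- sqrt(rss / (length(t) - 2) / sxx)
  list(slope = slope, slope_se = se, intercept = intercept,
       r_squared = r2, n = length(t),
       curvature_flag = r2 < r2_threshold)
}

#' Convert a fluorescence slope to specific activity
#'
#' @param slope fluorescence rate (AU s^-1).
#' @param gain detector gain (AU per pmol).
#' @param enzyme_mass enzyme per well (ug).
#' @return Specific activity v = slope * 60 / (gain * enzyme_mass), in
#'   pmol min^-1 ug^-1.
#' @export
to_specific_activity <- function(slope, gain, enzyme_mass) {
  if (!is.numeric(gain) || gain <= 0) stop("'gain' must be positive")
  if (!is.numeric(enzyme_mass) || enzyme_mass <= 0)
    stop("'enzyme_mass' must be positive")
  slope * 60 / (gain * enzyme_mass)
}

#' Build the initial-velocity table from a plate
#'
#' For every well a straight line is fitted to the progress curve; the mean
#' blank slope (substrate-free wells at the same inhibitor level) is
#' subtracted from each signal well's slope; slopes are converted to specific
#' activity and replicates aggregated as mean +/- SEM.
#'
#' @param plate a `plate_data` data frame ([simulate_plate()] or
#'   [read_plate_csv()]).
#' @param gain,enzyme_mass calibration used for the unit conversion; default
#'   from the plate's attached design, if any.
#' @param window regression window (s) passed to [fit_initial_rate()];
#'   alternatively `max_conversion` selects, per well, only reads before the
#'   fluorescence has covered that fraction of the well's full range
#'   (`NULL` disables).
#' @param max_conversion optional fraction in (0, 1].
#' @param r2_threshold curvature-warning threshold on the worst replicate.
#' @param provenance free-text recorded on the table.
#' @return A `rate_table`: data frame with columns `S_uM`, `I_uM`,
#'   `v_pmol_min_ug`, `sem`, `n`, `r_squared_min`, sorted by (I, S).
#' @export
build_rate_table <- function(plate, gain = NULL, enzyme_mass = NULL,
                             window = c(0, Inf), max_conversion = NULL,
                             r2_threshold = 0.98, provenance = "") {
  stopifnot(is.data.frame(plate))
  design <- attr(plate, "design")
  if (is.null(gain)) gain <- design$gain
  if (is.null(enzyme_mass)) enzyme_mass <- design$enzyme_mass
  if (is.null(gain) || is.null(enzyme_mass))
    stop("supply 'gain' and 'enzyme_mass' (plate carries no design)")

  wells <- unique(plate[, c("well_id", "S_uM", "I_uM", "replicate")])
  if (nrow(wells) == 0) stop("empty plate")
  wells$slope <- NA_real_
  wells$r2 <- NA_real_
  for (k in seq_len(nrow(wells))) {
    curve <- plate[plate$well_id == wells$well_id[k] &
                     plate$replicate == wells$replicate[k], ]
    win <- window
    if (!is.null(max_conversion)) {
      stopifnot(max_conversion > 0, max_conversion <= 1)
      f <- curve$fluorescence_au
      span <- max(f) - min(f)
      if (span > 0) {
        ok <- which(f - f[1] <= max_conversion * span)
        # keep an initial contiguous run of at least 3 reads
        last <- max(3L, if (length(ok)) max(ok) else 0L)
        win <- c(curve$time_s[1], curve$time_s[min(last, nrow(curve))])
      }
    }
    fit <- fit_initial_rate(curve, window = win, r2_threshold = r2_threshold)
    wells$slope[k] <- fit$slope
    wells$r2[k] <- fit$r_squared
  }

  blanks <- wells[wells$S_uM == 0, ]
  signal <- wells[wells$S_uM > 0, ]
  if (nrow(signal) == 0) {
    warning("plate contains only blanks; returning an empty rate table")
    out <- data.frame(S_uM = numeric(0), I_uM = numeric(0),
                      v_pmol_min_ug = numeric(0), sem = numeric(0),
                      n = integer(0), r_squared_min = numeric(0))
    class(out) <- c("rate_table", "data.frame")
    return(out)
  }
  if (nrow(blanks) == 0)
    warning("no substrate-free blanks found; skipping blank correction")

  blank_mean <- function(I) {
    b <- blanks$slope[blanks$I_uM == I]
    if (length(b) == 0) 0 else mean(b)
  }
  signal$slope_corr <- signal$slope -
    vapply(signal$I_uM, blank_mean, numeric(1))
  signal$v <- to_specific_activity(signal$slope_corr, gain, enzyme_mass)

  key <- interaction(signal$I_uM, signal$S_uM, drop = TRUE)
  agg <- lapply(split(signal, key), function(g) {
    n <- nrow(g)
    data.frame(S_uM = g$S_uM[1], I_uM = g$I_uM[1],
               v_pmol_min_ug = mean(g$v),
               sem = if (n > 1) stats::sd(g$v) / sqrt(n) else 0,
               n = n, r_squared_min = min(g$r2))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$I_uM, out$S_uM), ]
  rownames(out) <- NULL
  reps <- unique(out$n)
  if (length(reps) > 1)
    attr(out, "replicate_note") <-
      paste("inconsistent replicate counts:", paste(reps, collapse = ", "))
  class(out) <- c("rate_table", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' Rate-table CSV input/output
#'
#' Header `S_uM,I_uM,v_pmol_min_ug,sem,n`; this file format is also the
#' entry point for users bringing pre-computed velocities instead of raw
#' progress curves.
#'
#' @param table a `rate_table` (or any data frame with those columns).
#' @param path file path.
#' @export
write_rate_csv <- function(table, path) {
  cols <- c("S_uM", "I_uM", "v_pmol_min_ug", "sem", "n")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("rate table missing columns: ", paste(missing_cols, collapse = ", "))
  out <- as.data.frame(table)[, cols]
  for (nm in c("S_uM", "I_uM", "v_pmol_min_ug", "sem"))
    out[[nm]] <- sprintf("%.10g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_csv
#' @export
read_rate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(utils::read.csv(path),
                  error = function(e) stop("malformed rate CSV '", path, "': ",
                                           conditionMessage(e)))
  cols <- c("S_uM", "I_uM", "v_pmol_min_ug", "sem", "n")
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols))
    stop("rate CSV '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("rate CSV '", path, "' is empty")
  if (anyNA(tab[cols])) stop("rate CSV '", path, "' contains missing values")
  dup <- duplicated(tab[, c("S_uM", "I_uM")])
  if (any(dup))
    stop("rate CSV '", path, "' has duplicate (S, I) entries")
  tab <- tab[order(tab$I_uM, tab$S_uM), ]
  rownames(tab) <- NULL
  if (!"r_squared_min" %in% names(tab)) tab$r_squared_min <- NA_real_
  class(tab) <- c("rate_table", "data.frame")
  attr(tab, "provenance") <- path
  tab
}
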