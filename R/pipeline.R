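#' Simulate an assay and write it to disk
#'
#' Convenience wrapper around [simulate_plate()] that writes the plate CSV
#' together with a JSON record of the ground-truth parameters and the full
#' design, so a simulated dataset is self-describing.
#'
#' @param out_dir output directory (created if needed).
#' @param truth a [kinetic_params()].
#' @param design an [assay_design()].
#' @return Invisibly, a list with `plate` (the simulated data) and the two
#'   file paths.
#' @export
cmd_simulate <- function(out_dir, truth, design = assay_design()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate <- simulate_plate(design, truth)
  plate_path <- file.path(out_dir, "plate.csv")
  write_plate_csv(plate, plate_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(truth = unclass(truth), design = unclass(design)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(plate = plate, plate_path = plate_path,
                 truth_path = truth_path))
}

#' Analyse a rate table: fits, secondary plots, mechanism verdict
#'
#' The core analysis chain applied to an initial-velocity table: per-
#' inhibitor-level Michaelis-Menten fits (apparent KM and Vmax), optional
#' global fits of all five inhibition-model variants with AICc, and the
#' graphical mechanism discrimination with its inhibition-constant estimate
#' and KM/Vmax consistency check.
#'
#' @param table a `rate_table`.
#' @param alpha,spread_guard,weighting passed to [classify_mechanism()].
#' @param weighted logical; weight the model fits by 1/SEM^2.
#' @param fit_global logical; also fit the five global models.
#' @return A list with `rates`, `per_inhibitor` (data frame), `mechanism`
#'   (a `mechanism_call`), and optionally `global` (from
#'   [compare_mechanisms()]).
#' @export
analyze_rate_table <- function(table, alpha = 0.05, spread_guard = 1,
                               weighting = "cv", weighted = FALSE,
                               fit_global = TRUE) {
  per_i <- fit_per_inhibitor_series(table, weighted = weighted)
  zero_fit <- per_i[[1]]
  call <- classify_mechanism(table, alpha = alpha,
                             spread_guard = spread_guard,
                             weighting = weighting, zero_I_fit = zero_fit)
  out <- list(rates = table, per_inhibitor = as.data.frame(per_i),
              mechanism = call)
  if (fit_global) out$global <- compare_mechanisms(table, weighted = weighted)
  out
}

#' End-to-end analysis of a plate or rate CSV
#'
#' Reads either raw progress curves (long-format plate CSV) or a pre-computed
#' rate table, runs [analyze_rate_table()], and optionally writes a JSON
#' report, the apparent-parameter summary table, the extracted rates and the
#' diagnostic figures. Every tunable used in the computation is echoed into
#' the report for provenance.
#'
#' @param input path to a CSV file, or a `plate_data` / `rate_table` object.
#' @param input_kind `"auto"` (sniff the header), `"plate"` or `"rates"`.
#' @param out_dir optional output directory for `report.json`,
#'   `apparent_parameters.csv`, `rates.csv` (and figures with
#'   `plots = TRUE`).
#' @param gain,enzyme_mass calibration for plate input when the plate does
#'   not carry a design (defaults: the standard design's values).
#' @param window,max_conversion rate-extraction options, see
#'   [build_rate_table()].
#' @param alpha,spread_guard,weighting,weighted,fit_global analysis options,
#'   see [analyze_rate_table()].
#' @param plots logical; write Dixon, S/v and Michaelis-Menten figures
#'   (requires ggplot2).
#' @param strict logical; raise an error on an indeterminate verdict.
#' @return The analysis list from [analyze_rate_table()], plus `report`
#'   (the serialisable report) and `config`.
#' @export
cmd_analyze <- function(input, input_kind = c("auto", "plate", "rates"),
                        out_dir = NULL, gain = NULL, enzyme_mass = NULL,
                        window = c(0, Inf), max_conversion = NULL,
                        alpha = 0.05, spread_guard = 1, weighting = "cv",
                        weighted = FALSE, fit_global = TRUE,
                        plots = FALSE, strict = FALSE) {
  input_kind <- match.arg(input_kind)
  provenance <- "in-memory object"
  if (is.character(input)) {
    provenance <- input
    if (!file.exists(input)) stop("input file not found: ", input)
    if (input_kind == "auto") {
      header <- names(utils::read.csv(input, nrows = 1))
      input_kind <- if ("fluorescence_au" %in% header) "plate" else "rates"
    }
    input <- if (input_kind == "plate") read_plate_csv(input)
             else read_rate_csv(input)
  } else if (input_kind == "auto") {
    input_kind <- if (inherits(input, "rate_table")) "rates" else "plate"
  }

  default_design <- assay_design()
  if (input_kind == "plate") {
    if (is.null(attr(input, "design"))) {
      if (is.null(gain)) gain <- default_design$gain
      if (is.null(enzyme_mass)) enzyme_mass <- default_design$enzyme_mass
    }
    table <- build_rate_table(input, gain = gain, enzyme_mass = enzyme_mass,
                              window = window,
                              max_conversion = max_conversion,
                              provenance = provenance)
  } else {
    table <- input
  }

  res <- analyze_rate_table(table, alpha = alpha,
                            spread_guard = spread_guard,
                            weighting = weighting, weighted = weighted,
                            fit_global = fit_global)
  if (strict && res$mechanism$verdict == "indeterminate")
    stop("mechanism verdict is indeterminate (strict mode)")

  config <- list(input = provenance, input_kind = input_kind,
                 gain = gain, enzyme_mass = enzyme_mass,
                 window = window, max_conversion = max_conversion,
                 alpha = alpha, spread_guard = spread_guard,
                 weighting = weighting, weighted = weighted,
                 fit_global = fit_global)
  res$config <- config
  res$report <- build_report(res, config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    utils::write.csv(res$per_inhibitor,
                     file.path(out_dir, "apparent_parameters.csv"),
                     row.names = FALSE)
    write_rate_csv(table, file.path(out_dir, "rates.csv"))
    if (plots) write_figures(res, out_dir)
  }
  res
}

line_summary <- function(lines) {
  lapply(unclass(lines), function(l)
    list(S_uM = l$S, slope = l$slope, intercept = l$intercept,
         slope_se = l$slope_se, a = l$a, b = l$b, c = l$c))
}

intersection_summary <- function(est) {
  list(x_star = est$x_star, y_star = est$y_star, residual = est$residual,
       n_lines = est$n_lines, finite = est$finite)
}

build_report <- function(res, config) {
  m <- res$mechanism
  rep <- list(
    schema_version = "1.0",
    config = config,
    per_inhibitor = res$per_inhibitor,
    mechanism = list(
      verdict = m$verdict, ki_uM = m$ki, ki_prime_uM = m$ki_prime,
      consistency_pct = m$consistency_pct,
      dixon = list(parallel = m$dixon_parallel,
                   f_statistic = m$dixon_test$f_statistic,
                   p_value = m$dixon_test$p_value,
                   spread = m$dixon_test$spread,
                   lines = line_summary(m$dixon_lines),
                   intersection = intersection_summary(m$intersection_dixon)),
      s_over_v = list(parallel = m$sv_parallel,
                      f_statistic = m$sv_test$f_statistic,
                      p_value = m$sv_test$p_value,
                      spread = m$sv_test$spread,
                      lines = line_summary(m$sv_lines),
                      intersection = intersection_summary(m$intersection_sv))))
  if (!is.null(res$global)) {
    rep$global_fits <- lapply(res$global$fits, function(f)
      list(mechanism = f$mechanism, KM = f$params$KM, Vmax = f$params$Vmax,
           Ki = f$params$Ki, Ki_prime = f$params$Ki_prime,
           residual_ss = f$residual_ss, aic_c = f$aic_c,
           converged = f$converged,
           unidentifiable = as.list(f$unidentifiable)))
    rep$global_comparison <- res$global$comparison
  }
  rep
}

default_benchmark_truths <- function(KM = 93.9, Vmax = 33.02,
                                     Ki = 44.3, Ki_prime = 44.3) {
  list(
    competitive = kinetic_params(KM, Vmax, Ki = Ki),
    noncompetitive = kinetic_params(KM, Vmax, Ki = Ki, Ki_prime = Ki),
    mixed = kinetic_params(KM, Vmax, Ki = 30, Ki_prime = 60),
    uncompetitive = kinetic_params(KM, Vmax, Ki_prime = Ki_prime))
}

#' Benchmark the mechanism classifier over seeded simulations
#'
#' Simulates plates under each requested ground-truth mechanism across many
#' seeds, runs the full extraction-classification pipeline on each, and
#' tabulates the verdicts and the inhibition-constant recovery errors.
#'
#' @param mechanisms subset of names of `truths`.
#' @param n_seeds simulations per mechanism.
#' @param seed base seed; run r of mechanism m uses `seed + index`.
#' @param noise_cv pipetting coefficient of variation of the simulated
#'   plates.
#' @param design base [assay_design()] (its seed and pipetting CV are
#'   overridden per run).
#' @param truths named list of [kinetic_params()] ground truths.
#' @param alpha,spread_guard classifier options.
#' @return A list with `runs` (one row per simulation: mechanism, seed,
#'   verdict, ki, ki_prime, true constants) and `summary` (per mechanism:
#'   number correct, accuracy, and median/90th-percentile relative error of
#'   the recovered inhibition constant).
#' @export
cmd_benchmark <- function(mechanisms = names(default_benchmark_truths()),
                          n_seeds = 25, seed = 1,
                          noise_cv = 0.02, design = assay_design(),
                          truths = default_benchmark_truths(),
                          alpha = 0.05, spread_guard = 1) {
  stopifnot(all(mechanisms %in% names(truths)))
  runs <- list()
  idx <- 0L
  for (m in mechanisms) {
    truth <- truths[[m]]
    for (r in seq_len(n_seeds)) {
      idx <- idx + 1L
      d <- design
      d$pipetting_cv <- noise_cv
      d$seed <- (seed + idx) %% .Machine$integer.max
      plate <- simulate_plate(d, truth)
      table <- build_rate_table(plate)
      call <- tryCatch(
        classify_mechanism(table, alpha = alpha,
                           spread_guard = spread_guard),
        error = function(e) NULL)
      runs[[idx]] <- data.frame(
        mechanism = m, seed = d$seed,
        verdict = if (is.null(call)) "error" else call$verdict,
        ki = if (is.null(call)) NA_real_ else call$ki,
        ki_prime = if (is.null(call)) NA_real_ else call$ki_prime,
        true_ki = truth$Ki, true_ki_prime = truth$Ki_prime)
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(mechanisms, function(m) {
    g <- runs[runs$mechanism == m, ]
    correct <- g$verdict == m
    # relative error of the constant the mechanism actually has
    err <- if (is.finite(g$true_ki_prime[1]))
      abs(g$ki_prime - g$true_ki_prime) / g$true_ki_prime
    else abs(g$ki - g$true_ki) / g$true_ki
    err <- err[correct & is.finite(err)]
    data.frame(mechanism = m, n = nrow(g), n_correct = sum(correct),
               accuracy = mean(correct),
               median_rel_err = if (length(err)) stats::median(err) else NA_real_,
               q90_rel_err = if (length(err))
                 unname(stats::quantile(err, 0.9)) else NA_real_)
  }))
  list(runs = runs, summary = summary)
}
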