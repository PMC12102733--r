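#' Diagnostic figures for an inhibition analysis
#'
#' Michaelis-Menten overlay (velocity vs substrate at each inhibitor level
#' with the per-level fits), Dixon plot (1/v vs I) and substrate-over-
#' velocity plot (S/v vs I, with the closest-neighbour intersection marked).
#' These require ggplot2, which is only suggested: each function errors with
#' a clear message when it is unavailable.
#'
#' @param res an analysis result from [analyze_rate_table()] or
#'   [cmd_analyze()].
#' @return A ggplot object.
#' @export
plot_michaelis_menten <- function(res) {
  need_ggplot2()
  tab <- as.data.frame(res$rates)
  app <- res$per_inhibitor
  grid <- do.call(rbind, lapply(seq_len(nrow(app)), function(k) {
    S <- seq(0, max(tab$S_uM), length.out = 100)
    data.frame(S_uM = S, I_uM = app$I_uM[k],
               v = mm_velocity(S, app$KM_app[k], app$Vmax_app[k]))
  }))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$S_uM, y = .data$v_pmol_min_ug,
                                    colour = factor(.data$I_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$v_pmol_min_ug - .data$sem,
                                        ymax = .data$v_pmol_min_ug + .data$sem),
                           width = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$v)) +
    ggplot2::labs(x = "[S] (uM)", y = "v (pmol min^-1 ug^-1)",
                  colour = "[I] (uM)") +
    ggplot2::theme_minimal()
}

secondary_plot_data <- function(lines) {
  pts <- do.call(rbind, lapply(unclass(lines), function(l)
    cbind(l$points, S_uM = l$S)))
  fits <- do.call(rbind, lapply(unclass(lines), function(l)
    data.frame(S_uM = l$S, slope = l$slope, intercept = l$intercept)))
  list(points = pts, fits = fits)
}

#' @rdname plot_michaelis_menten
#' @export
plot_dixon <- function(res) {
  need_ggplot2()
  d <- secondary_plot_data(res$mechanism$dixon_lines)
  ggplot2::ggplot(d$points, ggplot2::aes(x = .data$I, y = .data$y,
                                         colour = factor(.data$S_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = d$fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = factor(.data$S_uM))) +
    ggplot2::labs(x = "[I] (uM)", y = "1/v (min ug pmol^-1)",
                  colour = "[S] (uM)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_michaelis_menten
#' @export
plot_cornish_bowden <- function(res) {
  need_ggplot2()
  d <- secondary_plot_data(res$mechanism$sv_lines)
  est <- res$mechanism$intersection_sv
  p <- ggplot2::ggplot(d$points, ggplot2::aes(x = .data$I, y = .data$y,
                                              colour = factor(.data$S_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = d$fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = factor(.data$S_uM))) +
    ggplot2::labs(x = "[I] (uM)", y = "S/v (min ug)", colour = "[S] (uM)") +
    ggplot2::theme_minimal()
  if (isTRUE(est$finite))
    p <- p +
      ggplot2::geom_vline(xintercept = est$x_star, linetype = "dashed",
                          colour = "red") +
      ggplot2::geom_hline(yintercept = est$y_star, linetype = "dashed",
                          colour = "red")
  p
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("figures require the 'ggplot2' package")
}

write_figures <- function(res, out_dir) {
  need_ggplot2()
  ggplot2::ggsave(file.path(out_dir, "michaelis_menten.pdf"),
                  plot_michaelis_menten(res), width = 6, height = 4)
  ggplot2::ggsave(file.path(out_dir, "dixon.pdf"), plot_dixon(res),
                  width = 6, height = 4)
  ggplot2::ggsave(file.path(out_dir, "cornish_bowden.pdf"),
                  plot_cornish_bowden(res), width = 6, height = 4)
  invisible(out_dir)
}
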