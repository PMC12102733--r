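# shared fixtures: ground truths and designs used across the suite

truth_uncompetitive <- function(Ki_prime = 44.3)
  kinetic_params(KM = 93.9, Vmax = 33.02, Ki_prime = Ki_prime)

truth_competitive <- function(Ki = 44.3)
  kinetic_params(KM = 93.9, Vmax = 33.02, Ki = Ki)

truth_noncompetitive <- function(K = 44.3)
  kinetic_params(KM = 93.9, Vmax = 33.02, Ki = K, Ki_prime = K)

truth_mixed <- function(Ki = 30, Ki_prime = 60)
  kinetic_params(KM = 93.9, Vmax = 33.02, Ki = Ki, Ki_prime = Ki_prime)

noiseless_design <- function(...)
  assay_design(noise_sd = 0, pipetting_cv = 0, ...)

# exact rate table straight from the rate law, bypassing the simulator
exact_rate_table <- function(truth,
                             S = c(12.5, 25, 50, 100, 150, 200),
                             I = c(0, 6.25, 12, 20, 25)) {
  grid <- expand.grid(S_uM = S, I_uM = I)
  grid <- grid[order(grid$I_uM, grid$S_uM), ]
  tab <- data.frame(S_uM = grid$S_uM, I_uM = grid$I_uM,
                    v_pmol_min_ug = inhibited_velocity(grid$S_uM, grid$I_uM,
                                                       truth),
                    sem = 0, n = 3, r_squared_min = 1)
  rownames(tab) <- NULL
  class(tab) <- c("rate_table", "data.frame")
  tab
}

# bare line in implicit form for intersection tests
make_line <- function(slope, intercept)
  list(S = NA, kind = "synthetic", slope = slope, intercept = intercept,
       slope_se = 0, a = slope, b = -1, c = intercept,
       points = data.frame(I = numeric(0), y = numeric(0),
                           weight = numeric(0)))

# brute-force grid minimiser of the summed squared perpendicular distances,
# independent of the closed-form solver; two-stage refinement down to the
# requested resolution
grid_search_intersection <- function(lines, centre, half_width = 50,
                                     resolution = 1e-3) {
  a <- vapply(lines, `[[`, numeric(1), "a")
  b <- vapply(lines, `[[`, numeric(1), "b")
  cc <- vapply(lines, `[[`, numeric(1), "c")
  obj <- function(x, y) {
    tot <- 0
    for (i in seq_along(a))
      tot <- tot + (a[i] * x + b[i] * y + cc[i])^2 / (a[i]^2 + b[i]^2)
    tot
  }
  x0 <- centre[1]; y0 <- centre[2]; h <- half_width
  repeat {
    step <- max(h / 50, resolution)
    xs <- seq(x0 - h, x0 + h, by = step)
    ys <- seq(y0 - h, y0 + h, by = step)
    vals <- outer(xs, ys, Vectorize(obj))
    k <- arrayInd(which.min(vals), dim(vals))
    x0 <- xs[k[1]]; y0 <- ys[k[2]]
    if (step <= resolution) break
    h <- step * 2
  }
  c(x = x0, y = y0)
}
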