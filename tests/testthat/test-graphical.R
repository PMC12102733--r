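test_that("Dixon lines under uncompetitive truth share the analytic slope", {
  tab <- exact_rate_table(truth_uncompetitive())
  dx <- dixon_lines(tab)
  slopes <- vapply(dx, `[[`, numeric(1), "slope")
  expect_equal(slopes, rep(1 / (33.02 * 44.3), length(slopes)),
               tolerance = 1e-9)
  # intercepts differ with S: (KM/S + 1)/Vmax
  ints <- vapply(dx, `[[`, numeric(1), "intercept")
  S <- vapply(dx, `[[`, numeric(1), "S")
  expect_equal(ints, (93.9 / S + 1) / 33.02, tolerance = 1e-9)
})

test_that("Dixon lines under competitive truth converge at minus Ki", {
  tab <- exact_rate_table(truth_competitive(Ki = 30))
  est <- closest_neighbor_intersection(dixon_lines(tab))
  expect_true(est$finite)
  expect_equal(est$x_star, -30, tolerance = 1e-8)
  expect_equal(est$y_star, 1 / 33.02, tolerance = 1e-8)
  expect_lt(est$residual, 1e-16)
})

test_that("S/v lines carry the analytic coefficients in min ug units", {
  tab <- exact_rate_table(truth_uncompetitive())
  sv <- cornish_bowden_lines(tab)
  for (l in sv) {
    s_nM <- l$S * 1000
    expect_equal(l$slope, s_nM / (33.02 * 44.3), tolerance = 1e-9)
    expect_equal(l$intercept, (93.9 * 1000 + s_nM) / 33.02,
                 tolerance = 1e-9)
    # value at I = 0 is the intercept
    expect_equal(l$points$y[l$points$I == 0], l$intercept,
                 tolerance = 1e-9)
  }
})

test_that("scaling all velocities scales the secondary lines inversely", {
  tab <- exact_rate_table(truth_uncompetitive())
  tab2 <- tab
  tab2$v_pmol_min_ug <- tab$v_pmol_min_ug * 2
  for (fn in list(dixon_lines, cornish_bowden_lines)) {
    l1 <- fn(tab)
    l2 <- fn(tab2)
    expect_equal(vapply(l2, `[[`, numeric(1), "slope"),
                 vapply(l1, `[[`, numeric(1), "slope") / 2,
                 tolerance = 1e-10)
    expect_equal(vapply(l2, `[[`, numeric(1), "intercept"),
                 vapply(l1, `[[`, numeric(1), "intercept") / 2,
                 tolerance = 1e-10)
  }
})

test_that("substrate levels with non-positive velocity are excluded", {
  tab <- exact_rate_table(truth_uncompetitive())
  tab$v_pmol_min_ug[tab$S_uM == 50 & tab$I_uM == 25] <- 0
  expect_warning(dx <- dixon_lines(tab), "50")
  expect_false(50 %in% vapply(dx, `[[`, numeric(1), "S"))
  # with a single usable level left, the pencil cannot be built
  tab2 <- exact_rate_table(truth_uncompetitive(), S = c(50, 100))
  tab2$v_pmol_min_ug[tab2$S_uM == 50] <- -1
  expect_error(suppressWarnings(dixon_lines(tab2)), "at least 2")
})

test_that("the perpendicular-distance minimiser is exact for crossing pairs", {
  est <- closest_neighbor_intersection(list(make_line(1, 0),
                                            make_line(-1, 0)))
  expect_equal(c(est$x_star, est$y_star), c(0, 0), tolerance = 1e-12)
  expect_equal(est$residual, 0, tolerance = 1e-20)

  l1 <- make_line(2.5, -3)
  l2 <- make_line(-0.7, 11)
  est2 <- closest_neighbor_intersection(list(l1, l2))
  x_exact <- (11 - (-3)) / (2.5 - (-0.7))
  expect_equal(est2$x_star, x_exact, tolerance = 1e-12)
  expect_equal(est2$y_star, 2.5 * x_exact - 3, tolerance = 1e-12)
  expect_lt(est2$residual, 1e-24)
})

test_that("the minimiser of a non-concurrent triangle matches a grid search", {
  lines <- list(make_line(0, 0),            # y = 0
                make_line(1, 1),            # y = x + 1
                make_line(-1, 2))           # y = -x + 2
  est <- closest_neighbor_intersection(lines)
  ref <- grid_search_intersection(lines, centre = c(0, 0), half_width = 5)
  expect_equal(est$x_star, ref[["x"]], tolerance = 2e-3)
  expect_equal(est$y_star, ref[["y"]], tolerance = 2e-3)
  # the closed form must not exceed the best grid objective
  obj <- function(x, y) sum(vapply(lines, function(l)
    (l$a * x + l$b * y + l$c)^2 / (l$a^2 + l$b^2), numeric(1)))
  expect_lte(obj(est$x_star, est$y_star), obj(ref[["x"]], ref[["y"]]) + 1e-9)
})

test_that("mutually parallel pencils yield no finite intersection", {
  est <- closest_neighbor_intersection(list(make_line(2, 0),
                                            make_line(2, 5),
                                            make_line(2, -4)))
  expect_false(est$finite)
  expect_true(is.na(est$x_star))
  expect_error(closest_neighbor_intersection(list(make_line(1, 0))),
               "at least 2")
})

make_fitted_line <- function(S, I, y, w = rep(1, length(y))) {
  fit <- stats::lm(y ~ I, weights = w)
  b <- unname(coef(fit))
  list(S = S, kind = "synthetic", slope = b[2], intercept = b[1],
       slope_se = suppressWarnings(summary(fit))$coefficients[
         "I", "Std. Error"],
       a = b[2], b = -1, c = b[1],
       points = data.frame(I = I, y = y, weight = w))
}

test_that("the parallelism test separates shared from distinct slopes", {
  I <- c(0, 6.25, 12, 20, 25)
  exact <- lapply(1:3, function(k)
    make_fitted_line(k, I, 2 * I + k))
  expect_true(parallelism_test(exact)$parallel)

  distinct <- lapply(1:3, function(k) {
    set.seed(k)
    make_fitted_line(k, I, k * I + rnorm(5, 0, 1e-4))
  })
  res <- parallelism_test(distinct)
  expect_false(res$parallel)
  expect_lt(res$p_value, 1e-6)
})

test_that("borderline parallelism verdicts agree with a permutation oracle", {
  I <- c(0, 6.25, 12, 20, 25)
  slopes <- c(1, 1.005, 0.995)             # within 1%
  agree <- vapply(1:20, function(s) {
    set.seed(s)
    lines <- lapply(1:3, function(k)
      make_fitted_line(k, I, slopes[k] * I + 10 * k +
                         rnorm(5, 0, 0.05 * 12)))   # ~5% of the y scale
    res <- parallelism_test(lines, spread_guard = Inf)
    pts <- do.call(rbind, lapply(lines, function(l)
      data.frame(line = factor(l$S), I = l$points$I, y = l$points$y)))
    f_stat <- function(yy) {
      shared <- stats::lm(yy ~ line + I, data = pts)
      free <- stats::lm(yy ~ line + line:I, data = pts)
      rss_s <- sum(resid(shared)^2); rss_f <- sum(resid(free)^2)
      ((rss_s - rss_f) / 2) / (rss_f / df.residual(free))
    }
    shared <- stats::lm(y ~ line + I, data = pts)
    f_obs <- f_stat(pts$y)
    perm <- vapply(1:199, function(p)
      f_stat(fitted(shared) + sample(resid(shared))), numeric(1))
    p_perm <- (1 + sum(perm >= f_obs)) / 200
    (p_perm > 0.05) == res$parallel
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("noiseless truths of every mechanism are classified correctly", {
  cases <- list(
    uncompetitive = truth_uncompetitive(),
    competitive = truth_competitive(Ki = 30),
    noncompetitive = truth_noncompetitive(K = 50),
    mixed = truth_mixed())
  for (mech in names(cases)) {
    call <- classify_mechanism(exact_rate_table(cases[[mech]]))
    expect_identical(call$verdict, mech)
    if (is.finite(cases[[mech]]$Ki))
      expect_equal(call$ki, cases[[mech]]$Ki, tolerance = 1e-6)
    if (is.finite(cases[[mech]]$Ki_prime))
      expect_equal(call$ki_prime, cases[[mech]]$Ki_prime, tolerance = 1e-6)
  }
  # uncompetitive pattern: parallel Dixon pencil, converging S/v pencil
  call <- classify_mechanism(exact_rate_table(truth_uncompetitive()))
  expect_true(call$dixon_parallel)
  expect_false(call$sv_parallel)
  expect_equal(call$intersection_sv$x_star, -44.3, tolerance = 1e-8)
})

test_that("all noiseless S/v lines pass through the common point", {
  # finite Ki' of any mechanism: common point (-Ki', KM_nM (1 - Ki'/Ki)/Vmax)
  for (truth in list(truth_uncompetitive(), truth_noncompetitive(K = 50),
                     truth_mixed())) {
    kp <- truth$Ki_prime
    y_expect <- 93.9 * 1000 * (1 - kp / truth$Ki) / 33.02
    sv <- cornish_bowden_lines(exact_rate_table(truth))
    for (l in sv)
      expect_equal(l$slope * (-kp) + l$intercept, y_expect,
                   tolerance = 1e-8)
  }
})

test_that("the verdict is invariant to row order and uniform velocity scaling", {
  tab <- exact_rate_table(truth_uncompetitive())
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  class(shuffled) <- class(tab)
  c1 <- classify_mechanism(tab)
  c2 <- classify_mechanism(shuffled)
  expect_identical(c2$verdict, c1$verdict)
  expect_equal(c2$ki_prime, c1$ki_prime, tolerance = 1e-10)

  scaled <- tab
  scaled$v_pmol_min_ug <- tab$v_pmol_min_ug * 3.7   # detector-gain rescale
  c3 <- classify_mechanism(scaled)
  expect_identical(c3$verdict, c1$verdict)
  expect_equal(c3$ki_prime, c1$ki_prime, tolerance = 1e-6)
})

test_that("the consistency check reproduces its closed forms", {
  fit0 <- list(KM = 93.9, Vmax = 33.02)
  r <- 93.9 * 1000 / 33.02
  expect_equal(consistency_check(r, fit0), 0)
  expect_equal(consistency_check(2 * r, fit0), 200 / 3, tolerance = 1e-9)
  expected <- 100 * abs(3116.68 - 2843.73) / ((3116.68 + 2843.73) / 2)
  expect_equal(consistency_check(3116.68, fit0), expected, tolerance = 1e-4)
  expect_error(consistency_check(2800, list(KM = -1, Vmax = 33.02)),
               "positive")
})
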