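test_that("noiseless Michaelis-Menten data are recovered exactly", {
  S <- c(12.5, 25, 50, 100, 150, 200)
  v <- mm_velocity(S, 93.9, 33.02)
  fit <- fit_michaelis_menten(S, v, I = 0)
  expect_equal(fit$KM, 93.9, tolerance = 1e-8)
  expect_equal(fit$Vmax, 33.02, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$residual_ss, 1e-16)
})

test_that("Michaelis-Menten fit preconditions are enforced", {
  expect_error(fit_michaelis_menten(c(10, 20), c(1, 2)), "at least 3")
  expect_error(fit_michaelis_menten(c(10, 20, 30), c(0, 0, 0)), "zero")
  expect_error(fit_michaelis_menten(c(10, 20, 30), c(1, NA, 2)), "finite")
  expect_error(fit_michaelis_menten(c(10, 20, 30), c(1, 2, 3),
                                    weighted = TRUE),
               "sem")
})

test_that("saturated (vanishing KM) data fit without crashing", {
  S <- c(10, 20, 50, 100, 200)
  v <- rep(33.02, 5)                      # v = Vmax regardless of S
  fit <- fit_michaelis_menten(S, v)
  expect_lt(fit$KM, 1e-3)
  expect_equal(fit$Vmax, 33.02, tolerance = 1e-4)
  # brute-force profile over a KM grid confirms the boundary minimum
  prof <- vapply(c(0.01, 0.1, 1, 10, 100), function(km) {
    vm <- sum(v * S / (km + S)) / sum((S / (km + S))^2)
    sum((v - vm * S / (km + S))^2)
  }, numeric(1))
  expect_true(all(fit$residual_ss <= prof + 1e-12))
})

test_that("per-inhibitor fits reproduce the apparent-parameter curves", {
  truth <- truth_uncompetitive()
  tab <- exact_rate_table(truth)
  series <- fit_per_inhibitor_series(tab)
  app <- as.data.frame(series)
  expected <- apparent_parameters(truth, app$I_uM)
  expect_equal(app$KM_app, expected$KM_app, tolerance = 1e-6)
  expect_equal(app$Vmax_app, expected$Vmax_app, tolerance = 1e-6)
  # the uncompetitive Table-1 signature: Vmax falls with I, KM/Vmax fixed
  expect_true(all(diff(app$Vmax_app) < 0))
  expect_equal(app$KM_app / app$Vmax_app, rep(93.9 / 33.02, 5),
               tolerance = 1e-6)
})

test_that("a single inhibitor level yields a single fit", {
  tab <- exact_rate_table(truth_uncompetitive(), I = 0)
  series <- fit_per_inhibitor_series(tab)
  expect_length(series, 1)
})

test_that("each global model recovers its own noiseless truth", {
  cases <- list(
    competitive = truth_competitive(),
    noncompetitive = truth_noncompetitive(),
    mixed = truth_mixed(),
    uncompetitive = truth_uncompetitive())
  for (mech in names(cases)) {
    tab <- exact_rate_table(cases[[mech]])
    fit <- fit_global_inhibition(tab, mech)
    expect_lt(fit$residual_ss, 1e-12)
    expect_equal(fit$params$KM, 93.9, tolerance = 1e-4)
    expect_equal(fit$params$Vmax, 33.02, tolerance = 1e-4)
    if (is.finite(cases[[mech]]$Ki))
      expect_equal(fit$params$Ki, cases[[mech]]$Ki, tolerance = 1e-4)
    else
      expect_identical(fit$params$Ki, Inf)
    if (is.finite(cases[[mech]]$Ki_prime))
      expect_equal(fit$params$Ki_prime, cases[[mech]]$Ki_prime,
                   tolerance = 1e-4)
    else
      expect_identical(fit$params$Ki_prime, Inf)
  }
})

test_that("models that cannot represent the truth fit strictly worse", {
  tab <- exact_rate_table(truth_uncompetitive())
  rss <- vapply(mechanism_labels(), function(m)
    fit_global_inhibition(tab, m)$residual_ss, numeric(1))
  # competitive, noncompetitive and the uninhibited model are misspecified
  expect_gt(rss[["competitive"]], rss[["uncompetitive"]] + 1)
  expect_gt(rss[["noncompetitive"]], rss[["uncompetitive"]] + 1)
  expect_gt(rss[["none"]], rss[["uncompetitive"]] + 1)
  # the mixed model nests the uncompetitive one, so it matches, with the
  # free-enzyme constant flagged unidentifiable
  expect_lt(rss[["mixed"]], 1e-12)
  expect_true("bi" %in% fit_global_inhibition(tab, "mixed")$unidentifiable)
})

test_that("global fit preconditions are enforced", {
  tab <- exact_rate_table(truth_uncompetitive(), I = 0)
  expect_error(fit_global_inhibition(tab, "uncompetitive"),
               "inhibitor levels")
})

test_that("per-level and global fits agree on noiseless apparent parameters", {
  truth <- truth_mixed()
  tab <- exact_rate_table(truth)
  gfit <- fit_global_inhibition(tab, "mixed")
  app_global <- apparent_parameters(gfit$params, c(0, 6.25, 12, 20, 25))
  app_per_i <- as.data.frame(fit_per_inhibitor_series(tab))
  expect_equal(app_per_i$KM_app, app_global$KM_app, tolerance = 1e-4)
  expect_equal(app_per_i$Vmax_app, app_global$Vmax_app, tolerance = 1e-4)
})

test_that("apparent Vmax is recovered within a few percent under assay noise", {
  truth <- truth_uncompetitive()
  errs <- sapply(1:50, function(s) {
    tab <- build_rate_table(simulate_plate(assay_design(seed = 400 + s),
                                           truth))
    app <- as.data.frame(fit_per_inhibitor_series(tab))
    expected <- apparent_parameters(truth, app$I_uM)
    median(abs(app$Vmax_app - expected$Vmax_app) / expected$Vmax_app)
  })
  expect_lt(median(errs), 0.05)
})

test_that("nominal 95% intervals for Ki-prime cover the truth in most runs", {
  truth <- truth_uncompetitive()
  cover <- vapply(1:200, function(s) {
    tab <- build_rate_table(simulate_plate(assay_design(seed = 20000 + s),
                                           truth))
    fit <- fit_global_inhibition(tab, "uncompetitive")
    se <- fit$se[["Ki_prime"]]
    is.finite(se) && abs(fit$params$Ki_prime - 44.3) <= 1.96 * se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("mechanism comparison table is complete and AICc-ordered sanely", {
  tab <- exact_rate_table(truth_noncompetitive())
  cm <- compare_mechanisms(tab)
  expect_setequal(cm$comparison$mechanism, mechanism_labels())
  best <- cm$comparison$mechanism[which.min(cm$comparison$aic_c)]
  expect_identical(best, "noncompetitive")
})
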