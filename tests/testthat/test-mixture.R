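test_that("EM recovers parameters on a separable noise-free fixture", {
  d <- sim_mixture(500, s0 = 1e-4, s1 = 1e-4, seed = 2)
  fit <- pav_mixture(d$x, d$y, seed = 1)
  co <- coef(fit)
  expect_lt(abs(co[["b1"]] - 1), 1e-6)
  expect_lt(abs(co[["b0"]]), 1e-6)
  expect_lt(abs(co[["a1"]]), 1e-4)
  tau1 <- fit$tau[, "present"]
  expect_true(all(pmin(tau1, 1 - tau1) < 1e-6))
  expect_true(all((tau1 > 0.5) == (d$z == 1)))
})

test_that("EM parameter recovery at n = 5000 from the generator settings", {
  d <- simulate_mixture(5000, seed = 1)
  fit <- pav_mixture(d$x, d$y, seed = 1)
  co <- coef(fit)
  # slopes, noise sd and mixing: sampling sd at n = 5000 is far inside the
  # tolerance, so truth is the oracle
  expect_lt(abs(co[["b0"]] - 0), 0.05)
  expect_lt(abs(co[["b1"]] - 1), 0.05)
  expect_lt(abs(sqrt(co[["sigma2_0"]]) - 0.8), 0.05)
  expect_lt(abs(sqrt(co[["sigma2_1"]]) - 0.8), 0.05)
  expect_lt(abs(co[["pi"]] - 0.5), 0.03)
  expect_true(fit$converged)
  # intercepts: their MLE sampling sd here is ~0.05 (x lies in [10, 40], far
  # from the origin), so the sharp recovery statement is agreement with the
  # supervised oracle — weighted least squares on the true labels; the
  # truth-level +/-0.05 check is made on the replicate ensemble in the
  # acceptance suite
  for (k in 0:1) {
    ols <- lm(d$y[d$z == k] ~ d$x[d$z == k])
    expect_lt(abs(co[[paste0("a", k)]] - coef(ols)[[1]]), 2e-3)
    expect_lt(abs(co[[paste0("b", k)]] - coef(ols)[[2]]), 2e-3)
  }
})

test_that("log-likelihood is non-decreasing at every EM iteration on every
           fixture", {
  for (s in 1:5) {
    d <- sim_mixture(400, pi1 = c(0.3, 0.5, 0.7, 0.5, 0.4)[s], seed = s)
    fit <- pav_mixture(d$x, d$y, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
})

test_that("posterior matches the closed-form density ratio and never NaNs", {
  d <- sim_mixture(200, seed = 3)
  fit <- pav_mixture(d$x, d$y, seed = 1)
  co <- fit$coefficients
  tau <- posterior(fit)
  expect_equal(rowSums(tau), rep(1, 200), tolerance = 1e-12)
  # closed form at a handful of points
  for (i in c(1, 50, 117)) {
    d1 <- fit$pi * dnorm(d$y[i], co[2, 1] + co[2, 2] * d$x[i],
                         sqrt(fit$sigma2[2]))
    d0 <- (1 - fit$pi) * dnorm(d$y[i], co[1, 1] + co[1, 2] * d$x[i],
                               sqrt(fit$sigma2[1]))
    expect_equal(unname(tau[i, 2]), d1 / (d0 + d1), tolerance = 1e-10)
  }
  # extreme outlier: log-space computation keeps tau finite
  tau_out <- posterior(fit, x = 25, y = 1e6)
  expect_false(any(is.nan(tau_out)))
  expect_equal(sum(tau_out), 1)
  # hand case: sigma equal, equidistant lines, pi = 0.5 -> tau = 0.5
  hand <- structure(list(
    coefficients = matrix(c(0, 0, 0, 1), 2, 2,
                          dimnames = list(c("absent", "present"),
                                          c("intercept", "slope"))),
    sigma2 = c(absent = 1, present = 1), pi = 0.5),
    class = "pav_mixture")
  expect_equal(unname(posterior(hand, x = 10, y = 5)[, 2]), 0.5,
               tolerance = 1e-12)
})

test_that("label-swap invariance: initialization labels do not change calls", {
  d <- sim_mixture(800, seed = 4)
  init_a <- list(a0 = 0, b0 = 0, sigma0 = 0.8, a1 = 0, b1 = 1, sigma1 = 0.8,
                 pi = 0.5)
  init_b <- list(a0 = 0, b0 = 1, sigma0 = 0.8, a1 = 0, b1 = 0, sigma1 = 0.8,
                 pi = 0.5)  # components named the other way round
  f1 <- pav_mixture(d$x, d$y, init = init_a, n_starts = 1)
  f2 <- pav_mixture(d$x, d$y, init = init_b, n_starts = 1)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_identical(bfdr_classify(f1)$call, bfdr_classify(f2)$call)
})

test_that("degenerate inputs fail loudly", {
  # all points from one cluster
  d <- sim_mixture(300, pi1 = 1, seed = 5)
  expect_error(pav_mixture(d$x, d$y, seed = 1), "degenerate")
  expect_error(pav_mixture(1:5, 1:5), "at least 10")
  expect_error(pav_mixture(c(1:9, NA), 1:10), "finite")
})

test_that("simulate() draws from the fitted model with correct moments", {
  d <- sim_mixture(2000, seed = 6)
  fit <- pav_mixture(d$x, d$y, seed = 1)
  sims <- simulate(fit, nsim = 3, seed = 9)
  z <- attr(sims, "z")
  expect_identical(dim(z), c(2000L, 3L))
  # mixing proportion of the draws near the fitted pi
  expect_lt(abs(mean(z) - fit$pi), 3 * sqrt(0.25 / 6000))
  # residual sd within the present cluster near sigma1
  r <- sims[z[, 1] == 1, 1] - (fit$coefficients[2, 1] +
                                 fit$coefficients[2, 2] * d$x[z[, 1] == 1])
  expect_lt(abs(sd(r) - sqrt(fit$sigma2[2])), 0.06)
})

test_that("BFDR prefix rule follows the hand-computed example and edge
           cases", {
  # q = 0.001, 0.002, 0.05, 0.40 -> only the first two classified
  tau1 <- c(0.999, 0.998, 0.95, 0.60)
  cl <- bfdr_classify(tau1, alpha = 0.01)
  expect_identical(cl$call, c("present", "present", "unclassified",
                              "unclassified"))
  expect_equal(attr(cl, "bfdr"), mean(c(0.001, 0.002)), tolerance = 1e-12)
  # all tau = 1: everything classified
  expect_true(all(bfdr_classify(rep(1, 5))$classified))
  # all q = 0.5: nothing classified
  cl2 <- bfdr_classify(rep(0.5, 5))
  expect_true(all(!cl2$classified))
  expect_true(is.na(attr(cl2, "bfdr")))
  expect_error(bfdr_classify(tau1, alpha = 0), "alpha")
  expect_error(bfdr_classify(tau1, alpha = 1.5), "alpha")
  expect_error(bfdr_classify(c(0.5, 1.2)), "0, 1")
})

test_that("BFDR calibration: mean realized FDR over seeded replicates stays
           at or below the nominal level", {
  fdr <- vapply(1:8, function(r) {
    d <- sim_mixture(2000, seed = 100 + r)
    fit <- pav_mixture(d$x, d$y, seed = r)
    cl <- bfdr_classify(fit, alpha = 0.01)
    wrong <- (cl$call == "present" & d$z == 0) |
      (cl$call == "absent" & d$z == 1)
    sum(wrong) / max(1, sum(cl$classified))
  }, numeric(1))
  mc_se <- sd(fdr) / sqrt(length(fdr))
  expect_lte(mean(fdr), 0.01 + 2 * mc_se)
})

test_that("genotype_panel: donor and opposite controls, truth agreement,
           all-zero lines and empty input", {
  cfg <- sim_config(seed = 31L)
  sim <- simulate_genome_pair(cfg)
  panel <- simulate_panel(sim$truth, cfg,
                          region_ids = sprintf("r%03d", 1:300))
  dm <- simulate_depth_matrix(sim$truth, cfg, panel)
  cs <- genotype_panel(dm, alpha = 0.01, seed = 1)

  # donor control: all present; opposite reference: all absent
  expect_gte(mean(cs$calls[, "F2"] == 1, na.rm = TRUE), 0.99)
  expect_gte(mean(cs$calls[, "B73"] == 0, na.rm = TRUE), 0.99)

  # classified calls agree with the simulation truth
  for (ln in c("L01", "L07", "L15")) {
    cl <- cs$calls[, ln]
    ok <- !is.na(cl)
    expect_gte(mean(cl[ok] == panel$genotypes[ok, ln]), 1 - 2 * 0.01)
  }

  # an all-zero line is skipped with a report
  dm2 <- dm
  dm2$counts[, "L03"] <- 0
  cs2 <- genotype_panel(dm2, seed = 1)
  expect_identical(cs2$skipped, "L03")
  expect_true(all(is.na(cs2$calls[, "L03"])))

  empty <- pavpan:::new_depth_matrix(x = numeric(0),
    Y = matrix(numeric(0), 0, 0), counts = matrix(numeric(0), 0, 0))
  expect_error(genotype_panel(empty), "empty")
})

test_that("sqrt transform is applied exactly once and refuses a second
           application", {
  counts <- matrix(c(100, 400, 900, 0, 4, 16), 3, 2,
                   dimnames = list(c("r1", "r2", "r3"), c("F2", "L1")))
  dm <- as_depth_matrix(counts, donor = "F2")
  expect_equal(dm$x, c(r1 = 10, r2 = 20, r3 = 30))
  expect_error(sqrt_transform(dm), "twice")
})
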