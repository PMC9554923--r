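test_that("Wald ratio divides outcome by exposure effect with delta SE", {
  # MTHFR variant against the combined aneurysm outcome
  est <- mr_wald_ratio(list(bx = 0.158, by = 0.034, se_y = 0.024))
  expect_equal(est$beta, 0.215189873418, tolerance = 1e-10)
  expect_equal(est$se, 0.151898734177, tolerance = 1e-10)

  null <- mr_wald_ratio(list(bx = 0.1, by = 0, se_y = 0.05))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  expect_error(mr_wald_ratio(list(bx = 0, by = 0.1, se_y = 0.05)),
               "exposure effect is zero")
})

test_that("IVW equals weighted regression through the origin", {
  # exactly proportional ratios: estimate is their common value
  expect_equal(mr_ivw(toy_a())$beta, 0.5, tolerance = 1e-12)

  est_b <- mr_ivw(toy_b())
  expect_equal(est_b$beta, 0.561904761905, tolerance = 1e-12)
  # independent route: lm through the origin with 1/se_y^2 weights
  ins <- toy_b()$instruments
  fit <- lm(by ~ 0 + bx, data = ins, weights = 1 / ins$se_y^2)
  expect_equal(est_b$beta, unname(coef(fit)), tolerance = 1e-12)

  # random small sets against the same oracle
  for (case in 1:10) {
    set.seed(100 + case)
    k <- sample(2:5, 1)
    hs <- toy_set(runif(k, 0.05, 0.3), rnorm(k, 0.02, 0.02),
                  runif(k, 0.02, 0.08))
    fit <- lm(by ~ 0 + bx, data = hs$instruments,
              weights = 1 / hs$instruments$se_y^2)
    expect_equal(mr_ivw(hs)$beta, unname(coef(fit)), tolerance = 1e-12)
  }
})

test_that("single-instrument IVW degrades to the Wald ratio", {
  hs <- toy_set(0.1, 0.05, 0.05)
  expect_warning(est <- mr_ivw(hs), "Wald ratio")
  wald <- mr_wald_ratio(hs$instruments[1, ])
  expect_equal(est$beta, wald$beta)
  expect_equal(est$se, wald$se)
})

test_that("random-effects IVW shares the point estimate and never shrinks the SE", {
  for (case in 1:10) {
    set.seed(200 + case)
    k <- sample(3:8, 1)
    hs <- toy_set(runif(k, 0.05, 0.3), rnorm(k, 0.02, 0.03),
                  runif(k, 0.02, 0.08))
    fe <- mr_ivw(hs, "fixed"); re <- mr_ivw(hs, "random")
    expect_identical(fe$beta, re$beta)
    expect_gte(re$se, fe$se)
  }
})

test_that("MR-Egger matches a direct weighted-least-squares oracle", {
  eg_a <- mr_egger(toy_a())
  expect_equal(eg_a$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg_a$intercept, 0, tolerance = 1e-10)

  eg_b <- mr_egger(toy_b())
  expect_equal(eg_b$slope$beta, 0.728571428571, tolerance = 1e-10)
  expect_equal(eg_b$intercept, -0.05, tolerance = 1e-10)
  # oracle: lm with weights, SEs rescaled to the unit variance floor
  ins <- toy_b()$instruments
  fit <- summary(lm(by ~ bx, data = ins, weights = 1 / ins$se_y^2))
  infl <- max(1, fit$sigma) / fit$sigma
  expect_equal(eg_b$slope$se, fit$coefficients["bx", 2] * infl,
               tolerance = 1e-10)
  expect_equal(eg_b$intercept_se, fit$coefficients["(Intercept)", 2] * infl,
               tolerance = 1e-10)
  # t p-values on k - 2 = 1 df
  expect_equal(eg_b$slope$pvalue,
               2 * pt(-abs(eg_b$slope$beta / eg_b$slope$se), 1),
               tolerance = 1e-12)

  expect_error(mr_egger(toy_set(c(0.1, 0.2), c(0.05, 0.1), c(0.05, 0.05))),
               "at least 3")
})

test_that("Egger orientation makes the fit invariant to joint sign flips", {
  set.seed(42)
  hs <- toy_set(runif(5, 0.05, 0.3), rnorm(5, 0.03, 0.02), runif(5, 0.02, 0.08))
  flipped <- hs
  flipped$instruments$bx[c(2, 4)] <- -flipped$instruments$bx[c(2, 4)]
  flipped$instruments$by[c(2, 4)] <- -flipped$instruments$by[c(2, 4)]
  a <- mr_egger(hs); b <- mr_egger(flipped)
  expect_equal(a$slope$beta, b$slope$beta, tolerance = 1e-12)
  expect_equal(a$intercept, b$intercept, tolerance = 1e-12)
  # the same invariance holds for IVW and the weighted median
  expect_equal(mr_ivw(hs)$beta, mr_ivw(flipped)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, 100, seed = 1)$beta,
               mr_weighted_median(flipped, 100, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("Egger with its intercept forced to zero reproduces IVW", {
  ins <- toy_b()$instruments
  fit <- lm(by ~ 0 + bx, data = ins, weights = 1 / ins$se_y^2)
  expect_equal(unname(coef(fit)), mr_ivw(toy_b())$beta, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  expect_equal(mr_weighted_median(toy_a(), 100, seed = 1)$beta, 0.5,
               tolerance = 1e-12)
  # ratios (0.2, 0.5, 0.6) with weights (4, 16, 64)/84 -> 0.575
  est <- mr_weighted_median(toy_b(), 1000, seed = 1)
  expect_equal(est$beta, 0.575, tolerance = 1e-12)

  # brute-force oracle on random sets
  wm_oracle <- function(r, w) {
    o <- order(r); r <- r[o]; w <- w[o] / sum(w)
    s <- cumsum(w) - w / 2
    approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
  }
  for (case in 1:10) {
    set.seed(300 + case)
    k <- sample(3:7, 1)
    hs <- toy_set(runif(k, 0.05, 0.3), rnorm(k, 0.03, 0.03),
                  runif(k, 0.02, 0.08))
    ins <- hs$instruments
    expect_equal(mr_weighted_median(hs, 100, seed = 1)$beta,
                 wm_oracle(ins$by / ins$bx, ins$bx^2 / ins$se_y^2),
                 tolerance = 1e-12)
    # estimate lies within the ratio range
    r <- ins$by / ins$bx
    est <- mr_weighted_median(hs, 100, seed = 1)$beta
    expect_gte(est, min(r)); expect_lte(est, max(r))
  }
})

test_that("concentrating all weight on one instrument returns its ratio", {
  hs <- toy_set(c(0.2, 0.2, 0.2), c(0.02, 0.10, 0.12),
                c(1e4, 0.05, 1e4))  # gigantic SEs kill instruments 1 and 3
  expect_equal(mr_weighted_median(hs, 100, seed = 1)$beta, 0.5,
               tolerance = 1e-9)
})

test_that("mode estimators find the dominant ratio cluster", {
  expect_equal(mr_mode(toy_a(), n_boot = 100, seed = 1)$beta, 0.5,
               tolerance = 1e-9)
  # 5 ratios with an exact triple at 0.5: the MAD collapses, the kernel
  # bandwidth degenerates, and the estimator falls back to the dominant
  # cluster's value
  tied <- toy_set(rep(0.1, 5), c(0.01, 0.05, 0.05, 0.05, 0.09), rep(0.05, 5))
  expect_equal(mr_mode(tied, n_boot = 100, seed = 1)$beta, 0.5,
               tolerance = 1e-9)
  # near-tied cluster: grid-evaluation oracle with the same bandwidth rule
  hs <- toy_set(rep(0.1, 5), c(0.010, 0.049, 0.050, 0.051, 0.090),
                rep(0.05, 5))
  r <- hs$instruments$by / hs$instruments$bx
  est <- mr_mode(hs, n_boot = 100, seed = 1)
  h <- 0.9 * min(sd(r), mad(r)) * 5^(-1 / 5)
  grid_step <- (diff(range(r)) + 6 * h) / 511
  expect_lt(abs(est$beta - 0.5), grid_step + 1e-12)
  # independent grid-evaluation oracle
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(x) mean(dnorm(x, r, h)))
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 1e-12)
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  a <- mr_weighted_median(toy_b(), 300, seed = 7)
  b <- mr_weighted_median(toy_b(), 300, seed = 7)
  expect_identical(a$se, b$se)
  c1 <- mr_mode(toy_b(), weighted = TRUE, n_boot = 300, seed = 7)
  c2 <- mr_mode(toy_b(), weighted = TRUE, n_boot = 300, seed = 7)
  expect_identical(c1$se, c2$se)
  d <- mr_weighted_median(toy_b(), 300, seed = 8)
  expect_false(identical(a$se, d$se))
})

test_that("estimate objects expose coherent CI and OR fields", {
  est <- mr_ivw(toy_b())
  expect_lt(est$ci_low, est$ci_high)
  expect_equal(est$ci_low, est$beta - 1.959964 * est$se, tolerance = 1e-12)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_error(mr_weighted_median(toy_b(), n_boot = 50), "at least 100")
})
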