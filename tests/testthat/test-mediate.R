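test_that("ols_ml recovers exact linear relations and flags collinearity", {
  x <- 1:5
  X <- cbind(1, x)
  fit <- ols_ml(X, 3 * x + 1)
  expect_equal(unname(fit$coefficients), c(1, 3))
  expect_lt(fit$sigma2, 1e-20)

  Xd <- cbind(intercept = 1, a = x, a_copy = x)
  expect_error(ols_ml(Xd, rnorm(5)), "collinear.*a_copy")
})

test_that("ols_ml matches the normal-equations oracle", {
  set.seed(31)
  for (i in 1:5) {
    X <- cbind(1, matrix(rnorm(40), 20, 2))
    colnames(X) <- c("i", "x1", "x2")
    y <- rnorm(20)
    fit <- ols_ml(X, y)
    expect_equal(unname(fit$coefficients), c(ne_ols(X, y)), tolerance = 1e-8)
    expect_equal(unname(fit$se), ne_ols_se(X, y), tolerance = 1e-8)
  }
})

test_that("ML and unbiased standard errors differ by sqrt((n-p)/n) only", {
  set.seed(5)
  X <- cbind(1, rnorm(25), rnorm(25))
  y <- rnorm(25)
  ml <- ols_ml(X, y, "ml")
  ub <- ols_ml(X, y, "unbiased")
  expect_equal(ml$coefficients, ub$coefficients)
  expect_equal(ml$se / ub$se, rep(sqrt((25 - 3) / 25), 3),
               ignore_attr = TRUE)
})

test_that("effect decomposition identities hold at machine precision", {
  d <- mediation_testdata(n = 250)
  fit <- mediate(d, "c", "a", "b", n_boot = 50, seed = 4)
  eff <- fit$effects
  expect_equal(eff["total", "estimate"],
               eff["direct", "estimate"] + eff["indirect", "estimate"],
               tolerance = 1e-12)
  expect_equal(eff["indirect", "estimate"],
               eff["a_to_b", "estimate"] * eff["b_to_c", "estimate"],
               tolerance = 1e-12)
  expect_equal(eff["indirect", "beta"],
               eff["a_to_b", "beta"] * eff["b_to_c", "beta"],
               tolerance = 1e-12)
  expect_equal(eff["total", "beta"],
               eff["direct", "beta"] + eff["indirect", "beta"],
               tolerance = 1e-12)
  # total equals the coefficient of a in the auxiliary model c ~ a + covariates
  aux <- lm(c ~ a + age + duration, data = d)
  expect_equal(eff["total", "estimate"], unname(coef(aux)["a"]),
               tolerance = 1e-10)
  # z = estimate / se, two-sided normal p
  expect_equal(eff$z, eff$estimate / eff$se)
  expect_equal(eff$p, 2 * pnorm(-abs(eff$z)))
  expect_true(all(eff$ci_low <= eff$ci_high))
})

test_that("Sobel SE matches the product-of-coefficients delta formula", {
  d <- mediation_testdata(n = 250)
  fit <- mediate(d, "c", "a", "b", n_boot = 10, seed = 4)
  m1 <- fit$models$mediator_model
  m2 <- fit$models$outcome_model
  alpha <- m1$coefficients["a"]; se_a <- m1$se["a"]
  betab <- m2$coefficients["b"]; se_b <- m2$se["b"]
  expect_equal(fit$effects["indirect", "se"],
               unname(sqrt(betab^2 * se_a^2 + alpha^2 * se_b^2)))
})

test_that("mediation models match lm() fits on the centered data", {
  d <- mediation_testdata(n = 180)
  fit <- mediate(d, "c", "a", "b", n_boot = 10, seed = 2)
  dc <- d
  for (v in c("a", "b", "age", "duration")) dc[[v]] <- dc[[v]] - mean(dc[[v]])
  lm1 <- lm(b ~ a + age + duration, dc)
  lm2 <- lm(c ~ a + b + age + duration, dc)
  expect_equal(fit$effects["a_to_b", "estimate"], unname(coef(lm1)["a"]))
  expect_equal(fit$effects["direct", "estimate"], unname(coef(lm2)["a"]))
  expect_equal(fit$effects["b_to_c", "estimate"], unname(coef(lm2)["b"]))
  # ML standard errors: lm's unbiased SEs shrunk by sqrt((n-p)/n)
  n <- nrow(d)
  expect_equal(fit$effects["a_to_b", "se"],
               unname(sqrt(diag(vcov(lm1)))["a"]) * sqrt((n - 4) / n))
})

test_that("estimates, betas and bootstrap CIs are invariant to mean centering", {
  d <- mediation_testdata(n = 150)
  shifted <- d
  shifted$a <- shifted$a + 100
  shifted$b <- shifted$b - 55
  shifted$age <- shifted$age + 7
  f1 <- mediate(d, "c", "a", "b", n_boot = 200, seed = 11)
  f2 <- mediate(shifted, "c", "a", "b", n_boot = 200, seed = 11)
  expect_equal(f1$effects, f2$effects, tolerance = 1e-8)
})

test_that("a pure-noise mediator yields null a->b and indirect paths", {
  set.seed(14)
  d <- mediation_testdata(n = 2000)
  d$b <- rnorm(2000, 0, 5)  # independent of everything
  fit <- mediate(d, "c", "a", "b", n_boot = 100, seed = 3)
  expect_lt(abs(fit$effects["a_to_b", "estimate"]),
            3 * fit$effects["a_to_b", "se"])
  expect_lt(abs(fit$effects["indirect", "estimate"]), 0.01)
})

test_that("deterministic outcome model gives zero-width CIs for its paths", {
  set.seed(15)
  n <- 80
  d <- data.frame(a = rnorm(n), age = rnorm(n), duration = rnorm(n))
  d$b <- 2 * d$a + rnorm(n)
  d$c <- 1.5 * d$a - 0.5 * d$b          # exactly linear in a and b
  fit <- mediate(d, "c", "a", "b", n_boot = 100, seed = 5)
  expect_equal(fit$effects["b_to_c", "ci_low"], -0.5, tolerance = 1e-10)
  expect_equal(fit$effects["b_to_c", "ci_high"], -0.5, tolerance = 1e-10)
  expect_equal(fit$effects["direct", "ci_low"],
               fit$effects["direct", "ci_high"], tolerance = 1e-10)
})

test_that("the bootstrap is reproducible given a seed", {
  d <- mediation_testdata(n = 120)
  f1 <- mediate(d, "c", "a", "b", n_boot = 150, seed = 42)
  f2 <- mediate(d, "c", "a", "b", n_boot = 150, seed = 42)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$boot, f2$boot)
  f3 <- mediate(d, "c", "a", "b", n_boot = 150, seed = 43)
  expect_false(identical(f1$effects$ci_low, f3$effects$ci_low))
})

test_that("Sobel z and bootstrap CI agree on clearly null and non-null settings", {
  d_alt <- mediation_testdata(n = 3000, alpha = -10, beta_b = 0.05, seed = 61)
  f_alt <- mediate(d_alt, "c", "a", "b", n_boot = 400, seed = 6)
  expect_gt(abs(f_alt$effects["indirect", "z"]), 3)
  expect_true(f_alt$effects["indirect", "ci_high"] < 0 ||
              f_alt$effects["indirect", "ci_low"] > 0)

  d_null <- mediation_testdata(n = 3000, alpha = -10, beta_b = 0, seed = 62)
  f_null <- mediate(d_null, "c", "a", "b", n_boot = 400, seed = 6)
  expect_lt(abs(f_null$effects["indirect", "z"]), 2)
  expect_true(f_null$effects["indirect", "ci_low"] <= 0 &&
              f_null$effects["indirect", "ci_high"] >= 0)
})

test_that("effect bias shrinks as the sample grows", {
  errs <- sapply(c(200, 2000), function(n) {
    est <- sapply(1:5, function(s) {
      d <- mediation_testdata(n = n, alpha = -10, beta_b = 0.02, tau = -0.4,
                              seed = 100 + s)
      coef(mediate(d, "c", "a", "b", n_boot = 1, seed = s))[c("a_to_b", "direct")]
    })
    rowMeans(abs(est - c(-10, -0.4)))
  })
  expect_lt(errs["a_to_b", 2], errs["a_to_b", 1])
  expect_lt(errs["direct", 2], errs["direct", 1])
})

test_that("standardized betas are scale-equivariant", {
  d <- mediation_testdata(n = 200)
  f1 <- mediate(d, "c", "a", "b", n_boot = 10, seed = 1)
  d2 <- d; d2$c <- 2 * d2$c
  f2 <- mediate(d2, "c", "a", "b", n_boot = 10, seed = 1)
  # doubling the outcome doubles outcome-scale estimates, leaves betas alone
  expect_equal(f2$effects["direct", "estimate"],
               2 * f1$effects["direct", "estimate"])
  expect_equal(f2$effects$beta, f1$effects$beta, tolerance = 1e-12)
  # with pre-standardized variables, beta equals the estimate
  ds <- as.data.frame(scale(d[c("a", "b", "c", "age", "duration")]))
  fs <- mediate(ds, "c", "a", "b", n_boot = 10, seed = 1)
  expect_equal(fs$effects$beta, fs$effects$estimate, tolerance = 1e-12)
})

test_that("mediate validates its inputs", {
  d <- mediation_testdata(n = 50)
  expect_error(mediate(d, "c", "a", "a", n_boot = 10), "distinct")
  expect_error(mediate(d, "c", "a", "zz", n_boot = 10), "zz")
  expect_error(mediate(d[1:5, ], "c", "a", "b", n_boot = 10), "10 complete")
  dz <- d; dz$b <- 1
  expect_error(mediate(dz, "c", "a", "b", n_boot = 10), "zero variance")
  expect_error(mediate(d, "c", "a", "b", n_boot = 0), "n_boot")
  # listwise deletion records n_used
  dn <- d; dn$b[1:7] <- NA
  fit <- mediate(dn, "c", "a", "b", n_boot = 10, seed = 1)
  expect_equal(fit$n_used, 43)
})

test_that("mediation methods print, coef and confint behave", {
  d <- mediation_testdata(n = 100)
  fit <- mediate(d, "c", "a", "b", n_boot = 100, seed = 2)
  expect_named(coef(fit), c("indirect", "a_to_b", "b_to_c", "direct", "total"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(5L, 2L))
  ci90 <- confint(fit, level = 0.90)
  expect_true(all(ci90[, 1] >= ci[, 1] - 1e-12))
  expect_output(print(fit), "indirect \\+ direct")
  expect_output(print(summary(fit)), "Mediator model")
})
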