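pfs_ref <- weibull_params(0.0474, 1.5590)
os_ref <- weibull_params(0.0075, 1.3601)

test_that("Weibull survival evaluates the closed form", {
  expect_equal(weibull_survival(pfs_ref, 0), 1)
  # median located independently by bisection on S(t) = 1/2
  med <- uniroot(function(t) weibull_survival(pfs_ref, t) - 0.5,
                 c(0.1, 60), tol = 1e-10)$root
  expect_equal(med, weibull_median(pfs_ref), tolerance = 1e-7)
  expect_equal(med, 5.594, tolerance = 1e-3)
  expect_equal(weibull_survival(os_ref, 12), exp(-0.0075 * 12^1.3601))
  expect_equal(weibull_survival(os_ref, 12), 0.8024, tolerance = 1e-3)
  expect_error(weibull_survival(pfs_ref, -1), ">= 0")
  # monotone non-increasing over a grid
  s <- weibull_survival(pfs_ref, seq(0, 100, by = 0.5))
  expect_true(all(diff(s) <= 0))
})

test_that("hazard-ratio adjustment scales lambda and composes multiplicatively", {
  expect_equal(apply_hazard_ratio(pfs_ref, 1), pfs_ref)
  adj <- apply_hazard_ratio(pfs_ref, 0.37)
  expect_equal(adj$scale, 0.017538, tolerance = 1e-6)
  expect_equal(adj$shape, 1.5590)
  # composition: hr1 then hr2 equals hr1*hr2
  set.seed(1)
  for (i in 1:20) {
    h1 <- runif(1, 0.1, 2); h2 <- runif(1, 0.1, 2)
    a <- apply_hazard_ratio(apply_hazard_ratio(os_ref, h1), h2)
    b <- apply_hazard_ratio(os_ref, h1 * h2)
    expect_equal(a$scale, b$scale, tolerance = 1e-12)
  }
  # protective hazard ratio lifts the whole curve
  tt <- seq(0.5, 80, by = 0.5)
  expect_true(all(weibull_survival(apply_hazard_ratio(pfs_ref, 0.37), tt) >=
                    weibull_survival(pfs_ref, tt)))
  expect_error(apply_hazard_ratio(pfs_ref, -0.5), "positive")
})

test_that("per-cycle transition probabilities follow the survival function", {
  # constant hazard: gamma = 1 reduces to 1 - exp(-lambda * dt) at every cycle
  expo <- weibull_params(0.1, 1)
  p <- cycle_transition_probability(expo, 0:99, 1)
  expect_equal(p, rep(1 - exp(-0.1), 100))
  # increasing hazard: strictly increasing in cycle index
  p2 <- cycle_transition_probability(pfs_ref, 0:199, 7 / 30.4375)
  expect_true(all(diff(p2) > 0))
  expect_equal(p2[1], 1 - weibull_survival(pfs_ref, 7 / 30.4375))
  expect_equal(p2[1], 0.004786, tolerance = 1e-3)
  expect_true(all(p2 >= 0 & p2 < 1))
  expect_error(cycle_transition_probability(pfs_ref, -1, 1), ">= 0")
})

test_that("Weibull mean matches numerical integration of the survival curve", {
  quad <- integrate(function(t) weibull_survival(os_ref, t), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(quad, weibull_mean(os_ref), tolerance = 1e-8)
  expect_equal(weibull_mean(os_ref), 33.5, tolerance = 0.01)
})

test_that("parametric MLE recovers the generating Weibull and nests correctly", {
  truth <- weibull_params(0.0474, 1.559)
  d <- gen_censored_weibull(5000, truth, censor_frac = 0.2, seed = 7)
  fit <- fit_parametric(d, "weibull")
  expect_lt(abs(fit$params[["scale"]] - truth$scale) / truth$scale, 0.05)
  expect_lt(abs(fit$params[["shape"]] - truth$shape) / truth$shape, 0.05)
  # bias shrinks with n
  d_small <- gen_censored_weibull(500, truth, censor_frac = 0.2, seed = 7)
  fit_small <- fit_parametric(d_small, "weibull")
  expect_lt(abs(fit$params[["shape"]] - truth$shape),
            abs(fit_small$params[["shape"]] - truth$shape) + 0.02)
  # nested model: weibull log-likelihood dominates exponential
  fe <- fit_parametric(d, "exponential")
  expect_gte(fit$loglik, fe$loglik)
  # exponential data fitted as weibull gives shape near 1
  de <- gen_censored_weibull(5000, weibull_params(0.1, 1), censor_frac = 0,
                             seed = 8)
  expect_equal(fit_parametric(de, "weibull")$params[["shape"]], 1,
               tolerance = 0.05)
  # information criteria follow their definitions
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(5000))
  expect_equal(fe$aic, -2 * fe$loglik + 2)
  # degenerate data are rejected
  expect_error(fit_parametric(survival_dataset(1:5, rep(1, 5)), "weibull"),
               ">= 10")
  expect_error(fit_parametric(survival_dataset(1:20, rep(0, 20)), "weibull"),
               "event")
})

test_that("Gompertz MLE agrees with the hand-computed likelihood optimum", {
  # simulate from h(t) = a exp(b t) by inversion
  set.seed(21)
  a <- 0.05; b <- 0.08; n <- 3000
  u <- runif(n)
  tt <- log(1 - b * log(u) / a) / b
  d <- survival_dataset(tt, rep(1L, n))
  fit <- fit_parametric(d, "gompertz")
  expect_lt(abs(fit$params[["a"]] - a) / a, 0.1)
  expect_lt(abs(fit$params[["b"]] - b) / b, 0.1)
})

test_that("model selection minimises BIC with documented tie-breaking", {
  mk <- function(family, loglik, n = 100, k = 2) {
    structure(list(family = family, params = numeric(0), loglik = loglik,
                   aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n),
                   n = n, k = k), class = "fit_result")
  }
  fits <- list(mk("exponential", -50), mk("weibull", -45), mk("gompertz", -47.5))
  expect_identical(select_model(fits)$family, "weibull")
  expect_identical(select_model(fits[1])$family, "exponential")
  expect_error(select_model(list()), "empty")
  # BIC tie resolved by AIC, then family order
  t1 <- mk("lognormal", -45); t2 <- mk("weibull", -45)
  expect_identical(select_model(list(t1, t2))$family, "weibull")

  # on seeded Weibull data the Weibull family wins in >= 90% of replicates
  fams <- c("exponential", "weibull", "gompertz", "loglogistic", "lognormal")
  truth <- weibull_params(0.0474, 1.559)
  sel <- vapply(1:50, function(s) {
    d <- gen_censored_weibull(500, truth, censor_frac = 0.2, seed = 1000 + s)
    select_model(lapply(fams, fit_parametric, data = d))$family
  }, character(1))
  expect_gte(mean(sel == "weibull"), 0.9)
})

test_that("life-table conversion to weekly mortality is exact", {
  lt <- life_table(40:100, rep(0.02, 61))
  expect_equal(weekly_background_mortality(lt, 71), 1 - 0.98^(1 / WEEKS_PER_YEAR))
  expect_equal(weekly_background_mortality(lt, 71), 0.000387, tolerance = 1e-3)
  lt0 <- life_table(c(40, 60), c(0, 1))
  expect_equal(weekly_background_mortality(lt0, 41), 0)
  expect_equal(weekly_background_mortality(lt0, 60), 1)
  # clamp above table maximum, error below minimum
  expect_equal(annual_background_mortality(lt, 120), 0.02)
  expect_error(weekly_background_mortality(lt, 30), "below")
  expect_error(life_table(c(40, 40), c(0.1, 0.2)), "increasing")
})
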