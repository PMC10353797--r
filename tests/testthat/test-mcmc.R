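test_that("PG(1, z) draws have the analytic mean", {
  set.seed(41)
  for (z in c(0, 1.3, 4)) {
    x <- rpg(40000, z)
    m <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(x) - m), 3 * sd(x) / sqrt(40000))
    expect_true(all(x > 0))
  }
  expect_error(rpg(5, NA_real_), "finite")
})

test_that("inverse-gamma variance update matches its analytic conditional", {
  set.seed(42)
  # finite-mean case: IG(shape + dim/2, rate + ss/2) has mean rate'/(shape'-1)
  draws <- replicate(20000, update_variance(6, 8, prior = c(2, 1)))
  shape_post <- 2 + 4
  rate_post <- 1 + 3
  m_true <- rate_post / (shape_post - 1)
  v_true <- rate_post^2 / ((shape_post - 1)^2 * (shape_post - 2))
  expect_lt(abs(mean(draws) - m_true), 3 * sqrt(v_true / 20000))
  # concentration: sum_sq = dim * v concentrates near v for large dim
  big <- replicate(2000, update_variance(4000 * 0.37, 4000))
  expect_lt(abs(mean(big) - 0.37), 0.01)
  expect_error(update_variance(-1, 3), "non-negative")
  # with no data contribution the draw falls back to the prior itself
  # (checked at the two quantiles where the IG(0.001, 0.001) cdf is
  # numerically representable)
  prior_draws <- replicate(20000, update_variance(0, 0))
  for (p in c(0.25, 0.5)) {
    q <- 1 / qgamma(1 - p, 0.001, rate = 0.001)
    expect_lt(abs(mean(prior_draws <= q) - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("centring shifts the level into the intercept and is idempotent", {
  res <- center_block(c(1, 1, 1), 0)
  expect_equal(res$values, c(0, 0, 0))
  expect_equal(res$intercept, 1)
  set.seed(43)
  v <- rnorm(9)
  r1 <- center_block(v, 2.5)
  # eta invariance: value[k] + intercept unchanged for every k
  expect_lt(max(abs((r1$values + r1$intercept) - (v + 2.5))), 1e-10)
  r2 <- center_block(r1$values, r1$intercept)
  expect_equal(r2, r1)
  # weighted centring
  w <- c(2, 1, 1, rep(1, 6))
  rw <- center_block(v, 0, weights = w)
  expect_lt(abs(sum(rw$values * w)), 1e-10)
})

test_that("chains are reproducible given a seed", {
  cfg <- tiny_config(300, seed = 55)
  d <- simulate_dataset(cfg)
  f1 <- run_mcmc(d, "M1", fast_chain(n_iter = 200, burn_in = 50, seed = 3))
  f2 <- run_mcmc(d, "M1", fast_chain(n_iter = 200, burn_in = 50, seed = 3))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- run_mcmc(d, "M1", fast_chain(n_iter = 200, burn_in = 50, seed = 4))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
  expect_identical(dim(f1$draws$beta), c(75L, ncol(f1$design$X), 2L))
})

test_that("a short M1 chain recovers strong effects and has sane blocks", {
  cfg <- tiny_config(1500, seed = 60)
  d <- simulate_dataset(cfg)
  fit <- run_mcmc(d, "M1", fast_chain(n_iter = 900, burn_in = 300, seed = 5))
  s <- summarize_effects(fit)
  est <- s[s$category == "overweight_obese" & s$parameter == "wealth=richest", ]
  expect_lt(abs(est$mean - 0.64), 0.35)
  est2 <- s[s$category == "underweight" & s$parameter == "wealth=richest", ]
  expect_lt(abs(est2$mean - (-0.6)), 0.5)
})

test_that("spatial and smooth draws honour their constraints every iteration", {
  smooth <- default_true_smooth_functions()
  cfg <- tiny_config(800, seed = 61, smooth = smooth)
  d <- simulate_dataset(cfg)
  fit <- run_mcmc(d, "M6", fast_chain(n_iter = 300, burn_in = 100, seed = 6),
                  graph = cfg$graph)
  # g and h drawn centred (sum zero) at every retained iteration
  expect_lt(max(abs(apply(fit$draws$g, c(1, 3), sum))), 1e-8)
  expect_lt(max(abs(apply(fit$draws$h, c(1, 3), sum))), 1e-8)
  # variance draws strictly positive
  expect_true(all(fit$draws$sigma2_e > 0))
  expect_true(all(fit$draws$delta > 0))
  expect_true(all(fit$draws$tau2 > 0))
  # fitted smooth curve is centred over the observed ages
  Bfit <- fit$design$B
  curve_mean <- colMeans(fit$draws$theta[, , 1] %*% t(Bfit))
  expect_lt(abs(mean(curve_mean)), 1e-6)
  # retained-draw count follows the floor((n_iter - burn_in)/thin) contract
  expect_identical(fit$n_keep, 100L)
})

test_that("the post-burn-in deviance trace has no drift", {
  for (k in 1:3) {
    cfg <- tiny_config(1000, seed = 400 + k)
    d <- simulate_dataset(cfg)
    fit <- run_mcmc(d, "M1", fast_chain(n_iter = 900, burn_in = 300,
                                        seed = k))
    dev <- fit$deviance
    h <- length(dev) %/% 2
    drift <- abs(mean(dev[(h + 1):length(dev)]) - mean(dev[1:h]))
    expect_lt(drift, 0.75 * sd(dev))
  }
})

test_that("category update order does not change the inference", {
  cfg <- tiny_config(1200, seed = 62)
  d <- simulate_dataset(cfg)
  f12 <- run_mcmc(d, "M1", fast_chain(n_iter = 1000, burn_in = 300, seed = 7,
                                      category_order = c(1L, 2L)))
  f21 <- run_mcmc(d, "M1", fast_chain(n_iter = 1000, burn_in = 300, seed = 7,
                                      category_order = c(2L, 1L)))
  s12 <- summarize_effects(f12)
  s21 <- summarize_effects(f21)
  # overlapping 95% intervals for every linear coefficient
  lin <- s12$block == "linear"
  expect_true(all(s12$lower[lin] <= s21$upper[lin] &
                  s21$lower[lin] <= s12$upper[lin]))
})

test_that("RW2 prior sampler matches its constrained covariance", {
  set.seed(77)
  J <- 9
  draws <- sample_rw2_prior(J, sigma2 = 2, n_draws = 30000)
  target <- rw2_constrained_covariance(J, sigma2 = 2)
  emp <- crossprod(draws) / nrow(draws)
  # elementwise Monte-Carlo tolerance ~ 3 * sd of a covariance estimate
  tol <- 3 * sqrt((diag(target) %o% diag(target) + target^2) / 30000)
  expect_true(all(abs(emp - target) <= tol + 1e-8))
  expect_lt(max(abs(colMeans(draws))),
            3.5 * sqrt(max(diag(target)) / 30000))
  # draws live in the penalised subspace: orthogonal to constants and trends
  expect_lt(max(abs(draws %*% rep(1, J) / sqrt(J))), 1e-8)
})
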