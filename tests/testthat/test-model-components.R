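test_that("B-spline basis rows are a partition of unity with J = m + degree", {
  z <- seq(15, 49, length.out = 211)
  B <- build_bspline_basis(z, n_knots = 20, degree = 3)
  expect_identical(ncol(B), 19L + 3L)  # m interior intervals + degree
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  expect_true(all(B >= 0))
})

test_that("degree-0 basis is the interval indicator", {
  B <- build_bspline_basis(c(0.1, 0.35, 0.9), n_knots = 5, degree = 0,
                           range = c(0, 1))
  expect_identical(ncol(B), 4L)
  expect_equal(unname(B[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(B[2, ]), c(0, 1, 0, 0))
  expect_equal(unname(B[3, ]), c(0, 0, 0, 1))
})

test_that("basis values agree with an independent Cox-de Boor recursion", {
  for (degree in c(1, 2, 3)) {
    B <- build_bspline_basis(c(0.13, 0.5, 0.77), n_knots = 5, degree = degree,
                             range = c(0, 1))
    oracle <- bspline_oracle(c(0.13, 0.5, 0.77), attr(B, "knots"), degree)
    expect_lt(max(abs(unclass(B) - oracle)), 1e-10)
  }
})

test_that("out-of-range ages error when fitting and clamp when asked", {
  expect_error(build_bspline_basis(c(20, 55), range = c(15, 49)),
               "outside the knot range")
  expect_warning(
    B <- build_bspline_basis(c(20, 55), range = c(15, 49),
                             outside = "clamp"),
    "clamped"
  )
  B49 <- build_bspline_basis(49, range = c(15, 49))
  expect_equal(unname(B[2, ]), unname(B49[1, ]))
})

test_that("RW2 penalty annihilates linear trends and sums second differences", {
  K <- rw2_penalty(8)
  for (ab in list(c(0, 0), c(2, 0), c(1, -3), c(-0.5, 0.25))) {
    theta <- ab[1] + ab[2] * seq_len(8)
    expect_lt(abs(drop(theta %*% K %*% theta)), 1e-12)
  }
  # single unit second difference
  theta <- c(0, 0, 0, 1)
  expect_equal(drop(theta %*% rw2_penalty(4) %*% theta), 1)
  # quadratic form equals the explicit sum for random theta
  set.seed(11)
  theta <- rnorm(12)
  expect_equal(drop(theta %*% rw2_penalty(12) %*% theta),
               sum(diff(theta, differences = 2)^2), tolerance = 1e-12)
  expect_error(rw2_penalty(2), ">= 3")
})

test_that("RW2 penalty has rank J - 2 and is PSD for J = 3..25", {
  for (J in 3:25) {
    K <- rw2_penalty(J)
    expect_identical(qr(K)$rank, J - 2L)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_equal(K, t(K))
  }
})

test_that("GMRF conditionals from Q match the neighbour-average form", {
  # path A-B-C: B given g_A = 1, g_C = 3 with delta = 2
  g <- region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  Q <- gmrf_precision(g, delta = 2)
  cond_var <- 1 / Q["B", "B"]
  cond_mean <- -cond_var * sum(Q["B", c("A", "C")] * c(1, 3))
  expect_equal(cond_mean, 2)
  expect_equal(cond_var, 1)
})

test_that("model specifications switch exactly the published blocks", {
  switches <- t(vapply(paste0("M", 1:6), function(v) {
    s <- model_spec(v)
    c(s$has_spline, s$has_struct, s$has_unstruct)
  }, logical(3)))
  expect_identical(unname(switches), rbind(
    c(FALSE, FALSE, FALSE),  # M1
    c(TRUE, FALSE, FALSE),   # M2
    c(FALSE, TRUE, TRUE),    # M3
    c(TRUE, TRUE, FALSE),    # M4
    c(TRUE, FALSE, TRUE),    # M5
    c(TRUE, TRUE, TRUE)      # M6
  ))
  expect_identical(model_spec("M4")$reference, "normal")
})

test_that("multinomial probabilities are correct, stable and simplex-valued", {
  expect_equal(unname(multinomial_probs(c(0, 0))), rep(1 / 3, 3))
  expect_equal(unname(multinomial_probs(c(log(2), 0))), c(0.5, 0.25, 0.25))
  # large predictors do not overflow
  p <- multinomial_probs(c(50, 0))
  expect_true(all(is.finite(p)))
  expect_gte(p[1], 1 - 1e-15)
  # simplex property on random inputs, including shift invariance of
  # the stabiliser
  set.seed(21)
  eta <- matrix(rnorm(200, sd = 15), 100, 2)
  P <- multinomial_probs(eta)
  expect_true(all(P > 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_error(multinomial_probs(c(NaN, 0)), "finite")
})

test_that("predictor assembly nests: larger specs with zeroed extras equal
          smaller specs", {
  cfg <- tiny_config(150, seed = 5)
  d <- simulate_dataset(cfg)
  g <- cfg$graph
  des2 <- build_design(d, model_spec("M2"), graph = g)
  des6 <- build_design(d, model_spec("M6"), graph = g)
  p <- ncol(des2$X)
  J <- ncol(des2$B)
  set.seed(99)
  pars2 <- lapply(1:2, function(r) list(beta = rnorm(p), theta = rnorm(J)))
  pars6 <- lapply(pars2, function(pr) {
    c(pr, list(g = rep(0, 4), h = rep(0, 4)))
  })
  expect_equal(assemble_predictor(des6, pars6), assemble_predictor(des2, pars2))

  # M1 with all-zero coefficients gives eta = 0
  des1 <- build_design(d, model_spec("M1"))
  z <- assemble_predictor(des1, lapply(1:2, function(r)
    list(beta = rep(0, p))))
  expect_true(all(z == 0))
})

test_that("predictor assembly matches a brute-force oracle", {
  cfg <- tiny_config(40, seed = 6)
  d <- simulate_dataset(cfg)
  des <- build_design(d, model_spec("M6"), graph = cfg$graph)
  set.seed(7)
  pars <- lapply(1:2, function(r) list(
    beta = rnorm(ncol(des$X), sd = 0.3),
    theta = rnorm(ncol(des$B), sd = 0.3),
    g = rnorm(4, sd = 0.3), h = rnorm(4, sd = 0.3)
  ))
  eta <- assemble_predictor(des, pars)
  for (i in c(1, 17, 40)) {
    for (r in 1:2) {
      manual <- sum(des$X[i, ] * pars[[r]]$beta) +
        sum(des$B[i, ] * pars[[r]]$theta) +
        pars[[r]]$g[des$region_idx[i]] + pars[[r]]$h[des$region_idx[i]]
      expect_equal(unname(eta[i, r]), unname(manual), tolerance = 1e-12)
    }
  }
})

test_that("deviance has the closed form at eta = 0 and matches brute force", {
  eta <- matrix(0, 3, 2)
  expect_equal(deviance_multinom(c(0L, 1L, 2L), eta), 6 * log(3),
               tolerance = 1e-12)
  set.seed(31)
  y <- sample(0:2, 20, replace = TRUE)
  eta <- matrix(rnorm(40), 20, 2)
  expect_equal(deviance_multinom(y, eta), deviance_oracle(y, eta),
               tolerance = 1e-9)
  # the saturated fit beats any other parameterisation
  eta_sat <- matrix(-30, 20, 2)
  eta_sat[cbind(which(y > 0), y[y > 0])] <- 30
  expect_lt(deviance_multinom(y, eta_sat), deviance_multinom(y, eta))
  expect_warning(dv <- deviance_multinom(1L, matrix(c(-800, 800), 1, 2)),
                 "zero predicted")
  expect_identical(dv, Inf)
})

test_that("design construction validates schema, rank and regions", {
  cfg <- tiny_config(60, seed = 8)
  d <- simulate_dataset(cfg)
  d2 <- d
  d2$wealth[1] <- "aristocracy"
  expect_error(build_design(d2, model_spec("M1")), "outside the schema")
  expect_error(build_design(d, model_spec("M3")), "region graph is required")
  d3 <- d
  d3$region[1] <- "Atlantis"
  expect_error(build_design(d3, model_spec("M3"), graph = cfg$graph),
               "not in the graph")
  # single-region graph cannot support a structured spatial term
  g1 <- region_graph("solo", matrix(character(), ncol = 2))
  d4 <- d
  d4$region <- "solo"
  expect_error(build_design(d4, model_spec("M3"), graph = g1), "at least 2")
  # constant covariate duplicating the intercept breaks full rank
  d5 <- d
  d5$working <- "yes"
  expect_error(build_design(d5, model_spec("M1")), "rank")
})
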