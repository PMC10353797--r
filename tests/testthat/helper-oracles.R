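# Independent oracles used to cross-check the implementation.

# Cox-de Boor recursion, written directly from the recurrence (independent
# of splines::splineDesign).  `knots` is the full extended knot sequence.
bspline_oracle <- function(x, knots, degree) {
  J <- length(knots) - degree - 1L
  basis_fun <- function(j, l) {
    if (l == 0L) {
      return(as.numeric(x >= knots[j] & x < knots[j + 1L]))
    }
    d1 <- knots[j + l] - knots[j]
    d2 <- knots[j + l + 1L] - knots[j + 1L]
    t1 <- if (d1 > 0) (x - knots[j]) / d1 * basis_fun(j, l - 1L) else 0
    t2 <- if (d2 > 0) {
      (knots[j + l + 1L] - x) / d2 * basis_fun(j + 1L, l - 1L)
    } else 0
    t1 + t2
  }
  vapply(seq_len(J), function(j) basis_fun(j, degree), numeric(length(x)))
}

# brute-force multinomial deviance, record by record, unstabilised formula
deviance_oracle <- function(y, eta) {
  tot <- 0
  for (i in seq_along(y)) {
    denom <- 1 + sum(exp(eta[i, ]))
    p <- if (y[i] == 0L) 1 / denom else exp(eta[i, y[i]]) / denom
    tot <- tot - 2 * log(p)
  }
  tot
}

# small fully-specified generator for fast MCMC tests: a handful of
# covariates, strong effects, 4-region lattice
tiny_config <- function(n, seed, smooth = NULL, structured = NULL,
                        unstructured = NULL) {
  g <- make_region_graph("lattice2x2")
  generator_config(
    n_records = n,
    marginals = list(
      wealth = c(poorest = 0.25, poorer = 0.2, middle = 0.2,
                 richer = 0.15, richest = 0.2),
      working = c(no = 0.5, yes = 0.5)
    ),
    graph = g,
    true_linear_effects = list(
      underweight = c("(Intercept)" = -0.8, "wealth=richest" = -0.6,
                      "working=yes" = 0.3),
      overweight_obese = c("(Intercept)" = 0.2, "wealth=richest" = 0.64,
                           "working=yes" = -0.3)
    ),
    true_smooth_functions = smooth,
    true_spatial_structured = structured,
    true_spatial_unstructured = unstructured,
    seed = seed
  )
}

fast_chain <- function(n_iter = 800, burn_in = 200, thin = 2, seed = 1, ...) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
              ...)
}
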