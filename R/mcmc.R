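#' MCMC configuration
#'
#' Chain settings for [run_mcmc()].  The defaults (35,000 iterations,
#' 5,000 burn-in, thinning 10, hence 3,000 retained draws) are the
#' full-length production settings; simulation studies in the test-suite
#' use shorter chains.
#'
#' @param n_iter total number of iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin retain every `thin`-th post-burn-in iteration.
#' @param seed integer RNG seed for the whole chain.
#' @param augmentation `"polya_gamma"` (exact Gaussian conditionals via
#'   Polya-Gamma augmentation; compiled, the default) or `"iwls_mh"`
#'   (independence Metropolis-Hastings with IWLS proposals; pure R,
#'   slower, kept as a cross-checking backend).
#' @param init_var initial value of every variance parameter.
#' @param prior_shape,prior_rate inverse-gamma hyperparameters shared by
#'   all variance priors (`a = b = c = d = omega1 = omega2 = 0.001`).
#' @param category_order order in which the two non-reference categories
#'   are updated each iteration (`c(1, 2)` = underweight first).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 35000, burn_in = 5000, thin = 10,
                        seed = 1L,
                        augmentation = c("polya_gamma", "iwls_mh"),
                        init_var = 0.1,
                        prior_shape = 0.001, prior_rate = 0.001,
                        category_order = c(1L, 2L)) {
  augmentation <- match.arg(augmentation)
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            init_var > 0, prior_shape > 0, prior_rate > 0)
  stopifnot(setequal(category_order, 1:2))
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = as.integer(seed),
         augmentation = augmentation, init_var = init_var,
         prior_shape = prior_shape, prior_rate = prior_rate,
         category_order = as.integer(category_order),
         n_keep = (as.integer(n_iter) - as.integer(burn_in)) %/%
                  as.integer(thin)),
    class = "mcmc_config"
  )
}

#' Fit a geo-additive multinomial logit model by MCMC
#'
#' Runs the category-wise Gibbs sampler for the chosen specification.
#' Each sweep augments one non-reference category's conditional logit
#' (holding the other category's predictor fixed as an offset), draws the
#' coefficient blocks from their Gaussian full conditionals (or via IWLS
#' Metropolis-Hastings), draws the variance parameters from their
#' conjugate inverse-gamma conditionals, and re-centres the smooth and
#' spatial blocks with the means absorbed into the per-category intercept.
#'
#' @param data data frame with `nutrition_category`, `age`, `region` and
#'   the categorical covariates.
#' @param spec a [model_spec] (or a variant string `"M1"`..`"M6"`).
#' @param config an [mcmc_config()].
#' @param graph a [region_graph]; required for specs with spatial blocks.
#' @param covariates,n_knots,degree,age_range passed to [build_design()].
#' @return Object of class `geomn_fit`: retained draws per block
#'   (`$draws`), the deviance trace (`$deviance`), the design, spec and
#'   config, and (for the IWLS backend) acceptance rates.
#' @export
run_mcmc <- function(data, spec, config = mcmc_config(), graph = NULL,
                     covariates = NULL, n_knots = 20, degree = 3,
                     age_range = c(15, 49)) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  design <- build_design(data, spec, graph = graph, covariates = covariates,
                         n_knots = n_knots, degree = degree,
                         age_range = age_range)
  if (is.null(design$y)) {
    stop("data must carry a 'nutrition_category' column for fitting")
  }
  if (config$n_keep < 2) stop("configuration retains fewer than 2 draws")

  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  if (config$augmentation == "polya_gamma") {
    raw <- gibbs_pg_cpp(
      y = design$y, X = design$X,
      B = if (spec$has_spline) design$B else matrix(0, nrow(design$X), 0),
      Kpen = if (spec$has_spline) design$penalty else matrix(0, 0, 0),
      region = if (is.null(design$region_idx)) integer(0)
               else design$region_idx,
      Qs = if (spec$has_struct) design$Qstruct else matrix(0, 0, 0),
      has_spline = spec$has_spline, has_struct = spec$has_struct,
      has_unstruct = spec$has_unstruct,
      n_regions = if (is.null(design$graph)) 0L
                  else length(design$graph$regions),
      rank_Qs = if (spec$has_struct) qr(design$Qstruct)$rank else 0L,
      n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
      prior_shape = config$prior_shape, prior_rate = config$prior_rate,
      init_var = config$init_var, cat_order = config$category_order
    )
    accept <- NULL
  } else {
    raw <- gibbs_iwls_r(design, config)
    accept <- raw$accept
  }
  wall <- proc.time()[["elapsed"]] - t0

  cats <- spec$categories
  nk <- raw$n_keep
  name_arr <- function(a, cols) {
    if (length(a) == 0) return(NULL)
    a <- array(a, dim = c(nk, length(cols), 2),
               dimnames = list(NULL, cols, cats))
    a
  }
  draws <- list(beta = name_arr(raw$beta, colnames(design$X)))
  if (spec$has_spline) {
    draws$theta <- name_arr(raw$theta, paste0("theta", seq_len(ncol(design$B))))
    draws$sigma2_e <- matrix(raw$sigma2_e, nk, 2, dimnames = list(NULL, cats))
  }
  if (spec$has_struct) {
    draws$g <- name_arr(raw$g, design$graph$regions)
    draws$delta <- matrix(raw$delta, nk, 2, dimnames = list(NULL, cats))
  }
  if (spec$has_unstruct) {
    draws$h <- name_arr(raw$h, design$graph$regions)
    draws$tau2 <- matrix(raw$tau2, nk, 2, dimnames = list(NULL, cats))
  }

  structure(
    list(draws = draws, deviance = as.numeric(raw$deviance),
         spec = spec, config = config, design = design,
         n_keep = nk, accept = accept, wall_clock = wall),
    class = "geomn_fit"
  )
}

#' @export
print.geomn_fit <- function(x, ...) {
  cat("geomn_fit:", x$spec$variant, "|", x$config$augmentation, "|",
      x$n_keep, "retained draws | mean deviance",
      round(mean(x$deviance), 2), "\n")
  invisible(x)
}

#' Conjugate inverse-gamma variance update
#'
#' Draws a variance parameter from its full conditional
#' `IG(shape + dim/2, rate + sum_sq/2)`, where `sum_sq` is the prior
#' quadratic form of the coefficient block (`theta' K theta` for the
#' spline, `g' Q g` for the structured effect, `h' h` for the unstructured
#' effect) and `dim` the rank of the prior precision.
#'
#' @param sum_sq non-negative quadratic form.
#' @param rank_or_dim effective dimension (rank of the prior precision).
#' @param prior length-2 vector `(shape, rate)` of the inverse-gamma prior.
#' @return One positive draw.
#' @export
update_variance <- function(sum_sq, rank_or_dim, prior = c(0.001, 0.001)) {
  if (!is.finite(sum_sq) || sum_sq < 0) {
    stop("sum_sq must be finite and non-negative")
  }
  stopifnot(rank_or_dim >= 0, length(prior) == 2L, all(prior > 0))
  1 / stats::rgamma(1, shape = prior[1L] + rank_or_dim / 2,
                    rate = prior[2L] + sum_sq / 2)
}

#' Sum-to-zero centring of an effect block
#'
#' Subtracts the (optionally weighted) mean from a block of effect values
#' and adds it to the per-category intercept, leaving the linear predictor
#' unchanged — the identifiability device separating level from shape for
#' smooth and spatial effects.
#'
#' @param values numeric vector of effect values.
#' @param intercept current intercept.
#' @param weights optional non-negative weights (e.g. basis-column usage
#'   for a spline block); default unweighted.
#' @return List with `values` (centred) and `intercept` (adjusted).
#' @export
center_block <- function(values, intercept, weights = NULL) {
  m <- if (is.null(weights)) mean(values) else
    sum(values * weights) / sum(weights)
  list(values = values - m, intercept = intercept + m)
}

#' The RW2 prior restricted to its identifiable subspace
#'
#' The second-order random-walk prior has precision `K / sigma2` with a
#' two-dimensional null space (constant and linear sequences).  On the
#' orthogonal complement of that null space the prior is the proper
#' Gaussian `N(0, sigma2 * K^+)` with `K^+` the Moore-Penrose
#' pseudo-inverse.  [rw2_constrained_covariance()] returns that covariance
#' analytically; [sample_rw2_prior()] draws from it via the
#' eigendecomposition.
#'
#' @param J number of coefficients.
#' @param sigma2 RW2 innovation variance.
#' @param n_draws number of draws.
#' @return `sample_rw2_prior`: an `n_draws x J` matrix;
#'   `rw2_constrained_covariance`: a `J x J` matrix.
#' @export
sample_rw2_prior <- function(J, sigma2 = 1, n_draws = 1) {
  K <- rw2_penalty(J)
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  sd <- sqrt(sigma2 / eg$values[pos])
  z <- matrix(stats::rnorm(n_draws * sum(pos)), n_draws, sum(pos))
  z %*% (t(V) * sd)
}

#' @rdname sample_rw2_prior
#' @export
rw2_constrained_covariance <- function(J, sigma2 = 1) {
  K <- rw2_penalty(J)
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  sigma2 * V %*% (t(V) / eg$values[pos])
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x < -35
  hi <- x > 35
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[hi] <- x[hi] + exp(-x[hi])
  out[mid] <- log1p(exp(x[mid]))
  out
}

# ---------------------------------------------------------------------------
# IWLS Metropolis-Hastings backend (pure R).  Same block structure, update
# order, centring and variance conditionals as the compiled Polya-Gamma
# backend; coefficient blocks are proposed from the Gaussian IWLS
# approximation at the current state and accepted/rejected by an MH step.
# ---------------------------------------------------------------------------
gibbs_iwls_r <- function(design, config) {
  spec <- design$spec
  y <- design$y
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  J <- if (spec$has_spline) ncol(design$B) else 0L
  R_ <- if (is.null(design$region_idx)) 0L else length(design$graph$regions)
  Z <- NULL
  if (R_ > 0L) {
    Z <- matrix(0, n, R_)
    Z[cbind(seq_len(n), design$region_idx)] <- 1
  }
  rank_Qs <- if (spec$has_struct) qr(design$Qstruct)$rank else 0L

  beta <- matrix(0, p, 2)
  theta <- matrix(0, max(J, 1L), 2)
  g <- matrix(0, max(R_, 1L), 2)
  h <- matrix(0, max(R_, 1L), 2)
  sigma2_e <- rep(config$init_var, 2)
  delta <- rep(config$init_var, 2)
  tau2 <- rep(config$init_var, 2)

  eta <- matrix(0, n, 2)
  compute_eta <- function(r) {
    e <- drop(X %*% beta[, r])
    if (spec$has_spline) e <- e + drop(design$B %*% theta[, r])
    if (spec$has_struct) e <- e + g[design$region_idx, r]
    if (spec$has_unstruct) e <- e + h[design$region_idx, r]
    e
  }
  eta[, 1] <- compute_eta(1)
  eta[, 2] <- compute_eta(2)

  nk <- config$n_keep
  out <- list(
    beta = array(NA_real_, c(nk, p, 2)),
    theta = if (spec$has_spline) array(NA_real_, c(nk, J, 2)),
    g = if (spec$has_struct) array(NA_real_, c(nk, R_, 2)),
    h = if (spec$has_unstruct) array(NA_real_, c(nk, R_, 2)),
    sigma2_e = if (spec$has_spline) matrix(NA_real_, nk, 2),
    delta = if (spec$has_struct) matrix(NA_real_, nk, 2),
    tau2 = if (spec$has_unstruct) matrix(NA_real_, nk, 2),
    deviance = numeric(nk), n_keep = nk
  )
  acc_n <- acc_a <- c(linear = 0, spline = 0, struct = 0, unstruct = 0)

  # IWLS Gaussian approximation of the conditional logit at coefficient
  # value `co` (psi = Xb co + offset); returns proposal mean/cholesky
  iwls_prop <- function(yr, Xb, co, offset, P0) {
    psi <- drop(Xb %*% co) + offset
    pr <- stats::plogis(psi)
    w <- pmax(pr * (1 - pr), 1e-8)
    tt <- psi + (yr - pr) / w
    P <- crossprod(Xb, Xb * w) + P0
    b <- drop(crossprod(Xb, w * (tt - offset)))
    U <- chol(P)  # P = U'U
    m <- backsolve(U, forwardsolve(t(U), b))
    list(U = U, m = m, P = P)
  }
  log_q <- function(x, prop) {
    d <- x - prop$m
    sum(log(diag(prop$U))) - 0.5 * drop(crossprod(prop$U %*% d))
  }
  loglik <- function(yr, psi) sum(yr * psi - log1pexp(psi))

  mh_block <- function(yr, Xb, co, offset, P0, which) {
    cur <- iwls_prop(yr, Xb, co, offset, P0)
    star <- drop(cur$m + backsolve(cur$U, stats::rnorm(length(co))))
    rev <- iwls_prop(yr, Xb, star, offset, P0)
    la <- loglik(yr, drop(Xb %*% star) + offset) -
      loglik(yr, drop(Xb %*% co) + offset) -
      0.5 * (drop(star %*% P0 %*% star) - drop(co %*% P0 %*% co)) +
      log_q(co, rev) - log_q(star, cur)
    acc_n[[which]] <<- acc_n[[which]] + 1
    if (is.finite(la) && log(stats::runif(1)) < la) {
      acc_a[[which]] <<- acc_a[[which]] + 1
      star
    } else co
  }

  keep <- 0L
  for (iter in seq_len(config$n_iter) - 1L) {
    for (r in config$category_order) {
      other <- 3L - r
      C <- log1pexp(eta[, other])
      yr <- as.numeric(y == r)

      # linear block (diffuse prior)
      partial <- eta[, r] - drop(X %*% beta[, r])
      beta[, r] <- mh_block(yr, X, beta[, r], partial - C,
                            matrix(0, p, p), "linear")
      eta[, r] <- partial + drop(X %*% beta[, r])

      if (spec$has_spline) {
        partial <- eta[, r] - drop(design$B %*% theta[, r])
        th <- mh_block(yr, design$B, theta[, r], partial - C,
                       design$penalty / sigma2_e[r], "spline")
        fit <- drop(design$B %*% th)
        eta[, r] <- partial + fit
        # basis rows sum to 1, so shifting all coefficients by the fitted
        # curve's mean centres the curve exactly
        cc <- mean(fit)
        theta[, r] <- th - cc
        beta[1L, r] <- beta[1L, r] + cc
      }
      if (spec$has_struct) {
        partial <- eta[, r] - g[design$region_idx, r]
        gr <- mh_block(yr, Z, g[, r], partial - C,
                       design$Qstruct / delta[r], "struct")
        eta[, r] <- partial + gr[design$region_idx]
        cb <- center_block(gr, beta[1L, r])
        g[, r] <- cb$values
        beta[1L, r] <- cb$intercept
      }
      if (spec$has_unstruct) {
        partial <- eta[, r] - h[design$region_idx, r]
        hr <- mh_block(yr, Z, h[, r], partial - C,
                       diag(R_) / tau2[r], "unstruct")
        eta[, r] <- partial + hr[design$region_idx]
        cb <- center_block(hr, beta[1L, r])
        h[, r] <- cb$values
        beta[1L, r] <- cb$intercept
      }

      prior <- c(config$prior_shape, config$prior_rate)
      if (spec$has_spline) {
        sigma2_e[r] <- update_variance(
          drop(theta[, r] %*% design$penalty %*% theta[, r]), J - 2, prior)
      }
      if (spec$has_struct) {
        delta[r] <- update_variance(
          drop(g[, r] %*% design$Qstruct %*% g[, r]), rank_Qs, prior)
      }
      if (spec$has_unstruct) {
        tau2[r] <- update_variance(sum(h[, r]^2), R_, prior)
      }
    }

    if (iter >= config$burn_in && (iter - config$burn_in) %% config$thin == 0 &&
        keep < nk) {
      keep <- keep + 1L
      out$beta[keep, , ] <- beta
      if (spec$has_spline) {
        out$theta[keep, , ] <- theta
        out$sigma2_e[keep, ] <- sigma2_e
      }
      if (spec$has_struct) {
        out$g[keep, , ] <- g
        out$delta[keep, ] <- delta
      }
      if (spec$has_unstruct) {
        out$h[keep, , ] <- h
        out$tau2[keep, ] <- tau2
      }
      out$deviance[keep] <- deviance_multinom(y, eta)
    }
  }
  out$accept <- ifelse(acc_n > 0, acc_a / acc_n, NA_real_)
  out
}
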