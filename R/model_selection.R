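#' DIC of a fitted model
#'
#' Deviance information criterion `DIC = Dbar + pD` with
#' `Dbar` the posterior mean of the deviance trace and
#' `pD = Dbar - D(thetabar)` (Spiegelhalter's effective number of
#' parameters), where `D(thetabar)` is the deviance at the posterior means
#' of all coefficient blocks.
#'
#' @param fit a `geomn_fit` from [run_mcmc()].
#' @return Object of class `dic_result`: list with `model`,
#'   `mean_deviance`, `pD`, `dic`, `deviance_at_mean`, `n_obs`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "geomn_fit"))
  if (length(fit$deviance) < 2L) stop("fewer than 2 retained deviance draws")
  dbar <- mean(fit$deviance)
  params <- posterior_mean_params(fit)
  dhat <- deviance_multinom(fit$design$y,
                            assemble_predictor(fit$design, params))
  pd <- dbar - dhat
  dic_result(fit$spec$variant, dbar, pd, n_obs = nrow(fit$design$X))
}

#' @rdname compute_dic
#' @param model model label (e.g. `"M4"`).
#' @param mean_deviance posterior mean deviance `Dbar`.
#' @param pD effective number of parameters.
#' @param n_obs number of observations (optional bookkeeping).
#' @export
dic_result <- function(model, mean_deviance, pD, n_obs = NA_integer_) {
  stopifnot(is.finite(mean_deviance), is.finite(pD))
  structure(
    list(model = model, mean_deviance = mean_deviance, pD = pD,
         dic = mean_deviance + pD, n_obs = n_obs),
    class = "dic_result"
  )
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("%s: Dbar = %.2f, pD = %.4f, DIC = %.1f\n",
              x$model, x$mean_deviance, x$pD, x$dic))
  invisible(x)
}

#' Posterior means of every coefficient block
#'
#' @param fit a `geomn_fit`.
#' @return List of per-category parameter lists suitable for
#'   [assemble_predictor()].
#' @export
posterior_mean_params <- function(fit) {
  stopifnot(inherits(fit, "geomn_fit"))
  spec <- fit$spec
  lapply(1:2, function(r) {
    pr <- list(beta = colMeans(fit$draws$beta[, , r, drop = FALSE][, , 1]))
    if (spec$has_spline) {
      pr$theta <- colMeans(fit$draws$theta[, , r, drop = FALSE][, , 1])
    }
    if (spec$has_struct) {
      pr$g <- colMeans(fit$draws$g[, , r, drop = FALSE][, , 1])
    }
    if (spec$has_unstruct) {
      pr$h <- colMeans(fit$draws$h[, , r, drop = FALSE][, , 1])
    }
    pr
  })
}

#' Compare fitted models by DIC
#'
#' Tabulates `Dbar`, `pD` and DIC for a set of fits of the *same* data and
#' reports each model's DIC difference against a reference model, flagging
#' models within 5 DIC units of the minimum as statistically
#' indistinguishable fits ("similar").
#'
#' @param dic_results list of [dic_result] (or `geomn_fit`) objects.
#' @param reference model label of the reference (default `"M6"` when
#'   present, otherwise the last model).
#' @param similar_margin DIC margin for the similarity flag (default 5).
#' @return Data frame with columns `model`, `mean_deviance`, `pD`, `dic`,
#'   `dic_diff` (model minus reference), `similar`.
#' @export
compare_models <- function(dic_results, reference = NULL,
                           similar_margin = 5) {
  dic_results <- lapply(dic_results, function(x) {
    if (inherits(x, "geomn_fit")) compute_dic(x) else x
  })
  stopifnot(all(vapply(dic_results, inherits, logical(1), "dic_result")))
  n_obs <- vapply(dic_results, function(x) as.integer(x$n_obs), integer(1))
  if (length(unique(n_obs[!is.na(n_obs)])) > 1L) {
    stop("DIC results come from different datasets (n differs); ",
         "comparison is meaningless")
  }
  tab <- data.frame(
    model = vapply(dic_results, `[[`, character(1), "model"),
    mean_deviance = vapply(dic_results, `[[`, numeric(1), "mean_deviance"),
    pD = vapply(dic_results, `[[`, numeric(1), "pD"),
    dic = vapply(dic_results, `[[`, numeric(1), "dic"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$model), , drop = FALSE]
  if (is.null(reference)) {
    reference <- if ("M6" %in% tab$model) "M6" else tab$model[nrow(tab)]
  }
  if (!reference %in% tab$model) stop("reference model not in the set")
  tab$dic_diff <- tab$dic - tab$dic[tab$model == reference]
  tab$similar <- tab$dic <= min(tab$dic) + similar_margin
  rownames(tab) <- NULL
  tab
}

#' Posterior summaries of every scalar parameter
#'
#' Posterior mean, central 95% credible interval (empirical 2.5% / 97.5%
#' quantiles, type-7 interpolation) and a significance flag (zero outside
#' the interval) for every scalar parameter of every block.
#'
#' @param fit a `geomn_fit`.
#' @param prob interval mass (default 0.95).
#' @return Data frame with columns `block`, `category`, `parameter`,
#'   `mean`, `lower`, `upper`, `significant`.
#' @export
summarize_effects <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "geomn_fit"))
  if (fit$n_keep < 100L) {
    warning("only ", fit$n_keep, " retained draws; summaries will be noisy")
  }
  a <- (1 - prob) / 2
  cats <- fit$spec$categories
  rows <- list()
  add <- function(block, category, parameter, x) {
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, category = category, parameter = parameter,
      mean = mean(x), lower = q[1L], upper = q[2L],
      significant = q[1L] > 0 || q[2L] < 0,
      stringsAsFactors = FALSE
    )
  }
  for (r in 1:2) {
    bet <- fit$draws$beta
    for (j in seq_len(dim(bet)[2L])) {
      add("linear", cats[r], dimnames(bet)[[2L]][j], bet[, j, r])
    }
    for (blk in c("sigma2_e", "delta", "tau2")) {
      if (!is.null(fit$draws[[blk]])) {
        add("variance", cats[r], blk, fit$draws[[blk]][, r])
      }
    }
  }
  do.call(rbind, rows)
}

#' Export posterior spatial effects per region
#'
#' Per region and outcome category: posterior mean and 95% credible
#' interval of the structured effect `g` (and the unstructured effect `h`
#' when present) plus a three-class significance code matching the usual
#' credible-interval map colouring: `"positive"` if the interval lies
#' above zero, `"negative"` if below, `"none"` otherwise.
#'
#' @param fit a `geomn_fit` whose spec has a spatial block.
#' @param prob interval mass (default 0.95).
#' @return Data frame keyed by `category`, `region`, `effect`.
#' @export
export_spatial_effects <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "geomn_fit"))
  if (!fit$spec$has_struct && !fit$spec$has_unstruct) {
    stop(fit$spec$variant, " has no spatial block")
  }
  a <- (1 - prob) / 2
  cats <- fit$spec$categories
  rows <- list()
  for (effect in c("g", "h")) {
    arr <- fit$draws[[effect]]
    if (is.null(arr)) next
    label <- if (effect == "g") "structured" else "unstructured"
    for (r in 1:2) {
      for (k in seq_len(dim(arr)[2L])) {
        x <- arr[, k, r]
        q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
        rows[[length(rows) + 1L]] <- data.frame(
          category = cats[r], region = dimnames(arr)[[2L]][k],
          effect = label, mean = mean(x), lower = q[1L], upper = q[2L],
          signif_class = if (q[1L] > 0) "positive"
                         else if (q[2L] < 0) "negative" else "none",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Export the posterior nonlinear age effect on a grid
#'
#' Evaluates the fitted smooth `f_r(age)` from the retained spline
#' coefficient draws on an age grid: pointwise posterior mean and 95%
#' band per non-reference category.  The grid must lie inside the training
#' knot range.
#'
#' @param fit a `geomn_fit` whose spec has a spline block.
#' @param grid numeric vector of ages (default 200 points over the
#'   training range).
#' @param prob interval mass (default 0.95).
#' @return Data frame with columns `category`, `age`, `mean`, `lower`,
#'   `upper`.
#' @export
export_nonlinear_effect <- function(fit, grid = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "geomn_fit"))
  if (!fit$spec$has_spline) stop(fit$spec$variant, " has no spline block")
  rng <- fit$design$age_range
  if (is.null(grid)) grid <- seq(rng[1L], rng[2L], length.out = 200L)
  if (any(grid < rng[1L] | grid > rng[2L])) {
    stop("grid outside the training knot range [", rng[1L], ", ",
         rng[2L], "]")
  }
  Bg <- build_bspline_basis(grid, n_knots = fit$design$n_knots,
                            degree = fit$design$degree, range = rng)
  a <- (1 - prob) / 2
  cats <- fit$spec$categories
  rows <- list()
  for (r in 1:2) {
    fdraws <- fit$draws$theta[, , r] %*% t(Bg)  # n_keep x n_grid
    qs <- apply(fdraws, 2L, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7)
    rows[[r]] <- data.frame(
      category = cats[r], age = grid, mean = colMeans(fdraws),
      lower = qs[1L, ], upper = qs[2L, ], stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
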