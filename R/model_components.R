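#' Equidistant B-spline basis
#'
#' Evaluates the B-spline basis used for the penalised-spline (P-spline)
#' representation of the nonlinear age effect: `n_knots` equally spaced
#' knots spanning `range` (so `m = n_knots - 1` interior intervals),
#' extended by `degree` boundary knots on each side with the same spacing,
#' giving `J = m + degree` basis functions.  Rows form a partition of
#' unity.
#'
#' @param z numeric vector of covariate values.
#' @param n_knots number of equidistant knots spanning the range
#'   (default 20).
#' @param degree spline degree `l` (default 3, cubic).
#' @param range length-2 numeric giving the knot span; defaults to
#'   `range(z)`.  Fits should pass the training range explicitly so
#'   prediction grids reuse it.
#' @param outside what to do with `z` outside `range`: `"error"` (default;
#'   keeps the penalty interpretation intact during fitting) or `"clamp"`
#'   (map onto the nearest boundary, with a warning; for prediction).
#' @return An `n x J` matrix with attributes `knots` (the full extended
#'   knot sequence), `interior_knots`, `degree` and `range`.
#' @examples
#' B <- build_bspline_basis(seq(15, 49, by = 1), n_knots = 20)
#' range(rowSums(B))  # partition of unity
#' @export
build_bspline_basis <- function(z, n_knots = 20, degree = 3, range = NULL,
                                outside = c("error", "clamp")) {
  outside <- match.arg(outside)
  stopifnot(is.numeric(z), all(is.finite(z)), n_knots >= 2, degree >= 0)
  if (n_knots < degree + 1) stop("n_knots must be at least degree + 1")
  if (is.null(range)) range <- base::range(z)
  stopifnot(length(range) == 2L, range[1L] < range[2L])
  if (any(z < range[1L] | z > range[2L])) {
    if (outside == "error") {
      stop("z outside the knot range [", range[1L], ", ", range[2L], "]")
    }
    warning("z outside the knot range clamped to the boundary")
    z <- pmin(pmax(z, range[1L]), range[2L])
  }
  inner <- seq(range[1L], range[2L], length.out = n_knots)
  h <- inner[2L] - inner[1L]
  knots <- c(range[1L] - h * (degree:1), inner, range[2L] + h * (1:degree))
  if (degree == 0L) knots <- inner
  B <- splines::splineDesign(knots, z, ord = degree + 1L)
  structure(B, knots = knots, interior_knots = inner,
            degree = degree, range = range)
}

#' Second-order random-walk penalty matrix
#'
#' The quadratic-form matrix `K = t(D2) %*% D2` of second differences, so
#' that for spline coefficients `theta`,
#' `t(theta) %*% K %*% theta = sum_j (theta_j - 2 theta_{j-1} + theta_{j-2})^2`.
#' This is the (scaled) prior precision implied by the RW2 prior
#' `theta_j = 2 theta_{j-1} - theta_{j-2} + e_j`.  `K` is symmetric
#' positive semidefinite of rank `J - 2`; its null space is spanned by
#' constant and linear sequences.
#'
#' @param J number of basis coefficients (`J >= 3`).
#' @return `J x J` matrix.
#' @export
rw2_penalty <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || J < 3) {
    stop("J must be an integer >= 3")
  }
  D2 <- diff(diag(J), differences = 2)
  crossprod(D2)
}

#' Model specifications M1-M6
#'
#' The six nested predictor specifications for the trichotomous outcome
#' (reference category `normal`):
#' \tabular{llll}{
#'   variant \tab spline f(age) \tab structured g(S) \tab unstructured h(S) \cr
#'   M1 \tab no  \tab no  \tab no  \cr
#'   M2 \tab yes \tab no  \tab no  \cr
#'   M3 \tab no  \tab yes \tab yes \cr
#'   M4 \tab yes \tab yes \tab no  \cr
#'   M5 \tab yes \tab no  \tab yes \cr
#'   M6 \tab yes \tab yes \tab yes
#' }
#' All variants include the dummy-coded linear block (with per-category
#' intercept).
#'
#' @param variant one of `"M1"` ... `"M6"`.
#' @return Object of class `model_spec` with logical switches
#'   `has_spline`, `has_struct`, `has_unstruct`.
#' @export
model_spec <- function(variant = c("M1", "M2", "M3", "M4", "M5", "M6")) {
  variant <- match.arg(variant)
  switches <- list(
    M1 = c(FALSE, FALSE, FALSE),
    M2 = c(TRUE, FALSE, FALSE),
    M3 = c(FALSE, TRUE, TRUE),
    M4 = c(TRUE, TRUE, FALSE),
    M5 = c(TRUE, FALSE, TRUE),
    M6 = c(TRUE, TRUE, TRUE)
  )[[variant]]
  structure(
    list(variant = variant, K = 3L, reference = "normal",
         categories = c("underweight", "overweight_obese"),
         has_spline = switches[1L], has_struct = switches[2L],
         has_unstruct = switches[3L]),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$variant, ": linear",
      if (x$has_spline) "+ f(age)",
      if (x$has_struct) "+ g(region)",
      if (x$has_unstruct) "+ h(region)", "\n")
  invisible(x)
}

#' Build the design objects of a model specification
#'
#' Dummy-codes the categorical covariates against their reference levels,
#' evaluates the B-spline basis of age and indexes regions against the
#' graph.  The linear design always carries an explicit per-category
#' intercept column.
#'
#' @param data data frame with columns `age`, `region`,
#'   `nutrition_category` (optional until fitting) and the covariates.
#' @param spec a [model_spec].
#' @param graph a [region_graph]; required when `spec` has a spatial block.
#' @param covariates named list mapping covariate name to its level vector,
#'   the first level being the reference (defaults to
#'   [default_reference_levels()] restricted to columns present).
#' @param n_knots,degree spline basis dimensions (defaults 20 knots,
#'   degree 3).
#' @param age_range knot span of the spline; defaults to `c(15, 49)`.
#' @return List of class `mn_design`: `X` (n x p linear design), `B`
#'   (n x J spline basis or NULL), `region_idx` (1-based region index or
#'   NULL), `penalty` (J x J RW2 matrix), `Qstruct` (unscaled ICAR
#'   structure matrix `gmrf_precision(graph, 1)`), `y` (integer outcome,
#'   0 = reference), plus the metadata needed to rebuild it.
#' @export
build_design <- function(data, spec, graph = NULL, covariates = NULL,
                         n_knots = 20, degree = 3, age_range = c(15, 49)) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  if (is.null(covariates)) {
    covariates <- default_reference_levels()
    covariates <- covariates[names(covariates) %in% names(data)]
  }
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in names(covariates)) {
    lev <- covariates[[v]]
    val <- as.character(data[[v]])
    bad <- setdiff(unique(val), c(lev, NA))
    if (length(bad)) {
      stop("covariate '", v, "' has level(s) outside the schema: ",
           paste(bad, collapse = ", "))
    }
    if (length(lev) < 2L) next
    for (l in lev[-1L]) {
      X <- cbind(X, as.numeric(val == l))
      colnames(X)[ncol(X)] <- paste0(v, "=", l)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("linear design is rank deficient (rank ", qrX$rank, " < ",
         ncol(X), " columns); the diffuse prior on beta requires full rank")
  }

  B <- NULL
  penalty <- NULL
  if (spec$has_spline) {
    B <- build_bspline_basis(data$age, n_knots = n_knots, degree = degree,
                             range = age_range, outside = "error")
    penalty <- rw2_penalty(ncol(B))
  }

  region_idx <- NULL
  Qstruct <- NULL
  if (spec$has_struct || spec$has_unstruct) {
    if (is.null(graph)) {
      stop(spec$variant, " includes a spatial block; a region graph is ",
           "required")
    }
    region_idx <- match(as.character(data$region), graph$regions)
    if (anyNA(region_idx)) {
      stop("region(s) not in the graph: ",
           paste(unique(data$region[is.na(region_idx)]), collapse = ", "))
    }
    if (spec$has_struct) {
      if (length(graph$regions) < 2L) {
        stop("structured spatial effect needs at least 2 regions")
      }
      Qstruct <- gmrf_precision(graph, delta = 1)
    }
  }

  y <- NULL
  if ("nutrition_category" %in% names(data)) {
    yf <- factor(as.character(data$nutrition_category),
                 levels = nutrition_levels())
    if (anyNA(yf)) stop("nutrition_category outside the three-level schema")
    # 0 = reference (normal), 1 = underweight, 2 = overweight_obese
    y <- ifelse(yf == "normal", 0L,
                ifelse(yf == "underweight", 1L, 2L))
  }

  structure(
    list(X = X, B = B, penalty = penalty, region_idx = region_idx,
         Qstruct = Qstruct, y = y, spec = spec, graph = graph,
         covariates = covariates, n_knots = n_knots, degree = degree,
         age_range = age_range, age = data$age),
    class = "mn_design"
  )
}

#' Reference levels of the standard covariates
#'
#' First level is the reference used for dummy coding (the "ref" rows of
#' the published posterior tables).
#' @return Named list of level vectors.
#' @export
default_reference_levels <- function() {
  list(
    residence = c("rural", "city_corporation", "other_urban"),
    wealth = c("poorest", "poorer", "middle", "richer", "richest"),
    education = c("no_education", "primary", "secondary", "higher"),
    working = c("no", "yes"),
    water = c("unprotected", "protected"),
    toilet = c("unimproved", "improved"),
    electricity = c("no", "yes"),
    newspaper = c("no", "yes"),
    radio = c("no", "yes"),
    television = c("no", "yes")
  )
}

#' Assemble the linear predictor of each non-reference category
#'
#' Sums the blocks the specification enables: `eta_r = X beta_r +
#' B theta_r + g_r[S] + h_r[S]`.  Disabled blocks contribute zero.
#'
#' @param design an [build_design()] result.
#' @param params list with one element per non-reference category (in the
#'   order `underweight`, `overweight_obese`), each a list with `beta`
#'   (length p), and, when enabled, `theta` (length J), `g`, `h`
#'   (length R).
#' @return `n x (K-1)` matrix of linear predictors.
#' @export
assemble_predictor <- function(design, params) {
  stopifnot(inherits(design, "mn_design"))
  spec <- design$spec
  stopifnot(length(params) == 2L)
  eta <- matrix(0, nrow(design$X), 2L,
                dimnames = list(NULL, spec$categories))
  for (r in 1:2) {
    pr <- params[[r]]
    stopifnot(length(pr$beta) == ncol(design$X))
    e <- drop(design$X %*% pr$beta)
    if (spec$has_spline) {
      stopifnot(length(pr$theta) == ncol(design$B))
      e <- e + drop(design$B %*% pr$theta)
    }
    if (spec$has_struct) e <- e + pr$g[design$region_idx]
    if (spec$has_unstruct) e <- e + pr$h[design$region_idx]
    eta[, r] <- e
  }
  eta
}

#' Multinomial logit probabilities
#'
#' Maps the `(K-1)` linear predictors of the non-reference categories to the
#' `K` category probabilities
#' `P[y = r] = exp(eta_r) / (1 + sum_s exp(eta_s))`, the reference category
#' receiving `1 / (1 + sum_s exp(eta_s))`.  Computation is stabilised by
#' shifting with the row maximum of `(0, eta)` so large predictors cannot
#' overflow.
#'
#' @param eta numeric vector of length `K-1` or an `n x (K-1)` matrix.
#' @return Probability vector/matrix with `K` columns, the non-reference
#'   categories first and the reference last; rows sum to one.
#' @examples
#' multinomial_probs(c(log(2), 0))  # 0.5, 0.25, reference 0.25
#' @export
multinomial_probs <- function(eta) {
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  if (any(!is.finite(eta))) stop("eta must be finite")
  m <- pmax(apply(eta, 1L, max), 0)
  ex <- exp(eta - m)
  ref <- exp(-m)
  denom <- ref + rowSums(ex)
  p <- cbind(ex / denom, reference = ref / denom)
  if (!is.null(colnames(eta))) {
    colnames(p) <- c(colnames(eta), "reference")
  }
  if (nrow(p) == 1L) drop(p) else p
}

#' Multinomial deviance
#'
#' `-2` times the multinomial log-likelihood of the observed categories
#' under the given linear predictors.
#'
#' @param y integer outcome vector: `0` for the reference category, `r` for
#'   the r-th non-reference category.
#' @param eta `n x (K-1)` matrix of linear predictors.
#' @return Scalar deviance; `+Inf` (with a warning) if any observed
#'   outcome has zero predicted probability.
#' @export
deviance_multinom <- function(y, eta) {
  if (is.null(dim(eta))) eta <- matrix(eta, ncol = 1L)
  stopifnot(length(y) == nrow(eta), all(y %in% 0:ncol(eta)))
  p <- multinomial_probs(eta)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  K <- ncol(p)
  # observed-category probability: reference (y = 0) sits in the last column
  idx <- ifelse(y == 0L, K, y)
  pobs <- p[cbind(seq_along(y), idx)]
  if (any(pobs == 0)) {
    warning("zero predicted probability for an observed outcome")
    return(Inf)
  }
  -2 * sum(log(pobs))
}
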