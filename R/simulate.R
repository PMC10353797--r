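#' Configuration of the synthetic DHS-like generator
#'
#' Bundles everything needed to simulate person-level survey records from
#' the geo-additive multinomial logit model with known ground truth:
#' covariate marginals, the age range, the region graph and per-category
#' true effects.  Covariates are drawn independently from their marginals
#' (no joint dependence is imposed); age is continuous uniform on
#' `age_range`, maximising coverage of the spline domain.
#'
#' @param n_records number of women to simulate.
#' @param marginals named list of probability vectors over covariate
#'   levels (default: the published 2017-18 column percentages,
#'   [default_table1_marginals()]).  Each vector must sum to 1 within
#'   `1e-12`.
#' @param age_range closed interval in years, within `[15, 49]`.
#' @param graph a [region_graph] (default `make_region_graph("bdhs2018")`).
#' @param region_probs probability vector over `graph$regions` (default
#'   uniform).
#' @param true_linear_effects list with elements `underweight` and
#'   `overweight_obese`, each a named numeric vector of coefficients keyed
#'   by `"(Intercept)"` and `"<covariate>=<level>"`; missing keys mean 0.
#'   Defaults to [default_true_linear_effects()].
#' @param true_smooth_functions `NULL`, or list of two functions of age
#'   (`underweight`, `overweight_obese`) giving the nonlinear age effect.
#' @param true_spatial_structured,true_spatial_unstructured `NULL`, or
#'   list of two named numeric vectors (one entry per region) giving
#'   `g_r(S)` / `h_r(S)`.
#' @param covariate_sampler optional function `(n, rng-ready) -> data.frame`
#'   replacing the independent-marginal covariate draw, for user-supplied
#'   joint distributions.
#' @param seed integer RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_records,
                             marginals = default_table1_marginals(2018),
                             age_range = c(15, 49),
                             graph = make_region_graph("bdhs2018"),
                             region_probs = NULL,
                             true_linear_effects = default_true_linear_effects(),
                             true_smooth_functions = NULL,
                             true_spatial_structured = NULL,
                             true_spatial_unstructured = NULL,
                             covariate_sampler = NULL,
                             seed = 1L) {
  stopifnot(length(n_records) == 1L, n_records >= 1)
  stopifnot(inherits(graph, "region_graph"))
  stopifnot(length(age_range) == 2L, age_range[1L] < age_range[2L],
            age_range[1L] >= 15, age_range[2L] <= 49)
  for (v in names(marginals)) {
    p <- marginals[[v]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("marginal for '", v, "' must be a named probability vector ",
           "summing to 1 within 1e-12")
    }
  }
  if (is.null(region_probs)) {
    region_probs <- rep(1 / length(graph$regions), length(graph$regions))
    names(region_probs) <- graph$regions
  }
  stopifnot(length(region_probs) == length(graph$regions),
            abs(sum(region_probs) - 1) < 1e-8)
  check_cat <- function(x, what, validator) {
    if (is.null(x)) return(invisible())
    if (!all(c("underweight", "overweight_obese") %in% names(x))) {
      stop(what, " must have elements 'underweight' and 'overweight_obese'")
    }
    lapply(x[c("underweight", "overweight_obese")], validator)
    invisible()
  }
  check_cat(true_linear_effects, "true_linear_effects",
            function(b) stopifnot(is.numeric(b), !is.null(names(b))))
  check_cat(true_smooth_functions, "true_smooth_functions",
            function(f) stopifnot(is.function(f)))
  check_spatial <- function(v) {
    stopifnot(is.numeric(v), length(v) == length(graph$regions))
    if (is.null(names(v))) stop("spatial effect vectors must be named by region")
    stopifnot(setequal(names(v), graph$regions))
  }
  check_cat(true_spatial_structured, "true_spatial_structured", check_spatial)
  check_cat(true_spatial_unstructured, "true_spatial_unstructured",
            check_spatial)
  structure(
    list(n_records = as.integer(n_records), marginals = marginals,
         age_range = age_range, graph = graph, region_probs = region_probs,
         true_linear_effects = true_linear_effects,
         true_smooth_functions = true_smooth_functions,
         true_spatial_structured = true_spatial_structured,
         true_spatial_unstructured = true_spatial_unstructured,
         covariate_sampler = covariate_sampler,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default ground-truth linear effects
#'
#' Per-category coefficient maps whose magnitudes echo the published
#' posterior means of the 2017-18 round (e.g. `wealth=richest` on the
#' overweight/obese log-odds is 0.64).  Intercepts are set so that, under
#' the default marginals and a linear-only predictor, the three outcome
#' categories occur at realistic rates (roughly 12% / 37% / 51%); adding
#' smooth or spatial truth shifts these somewhat.
#'
#' @return List with named coefficient vectors `underweight` and
#'   `overweight_obese`.
#' @export
default_true_linear_effects <- function() {
  list(
    underweight = c(
      "(Intercept)" = -1.17,
      "residence=city_corporation" = -0.10, "residence=other_urban" = 0.103,
      "wealth=poorer" = 0.192, "wealth=middle" = 0.023,
      "wealth=richer" = -0.108, "wealth=richest" = -0.454,
      "education=primary" = -0.21, "education=secondary" = -0.271,
      "education=higher" = 0.514,
      "working=yes" = 0.013, "water=protected" = 0.047,
      "toilet=improved" = -0.053, "electricity=yes" = 0.007,
      "newspaper=yes" = 0.151, "radio=yes" = -0.05,
      "television=yes" = -0.044
    ),
    overweight_obese = c(
      "(Intercept)" = 0.30,
      "residence=city_corporation" = 0.038, "residence=other_urban" = 0.036,
      "wealth=poorer" = -0.332, "wealth=middle" = -0.033,
      "wealth=richer" = 0.118, "wealth=richest" = 0.642,
      "education=primary" = 0.477, "education=secondary" = 0.508,
      "education=higher" = -1.311,
      "working=yes" = -0.12, "water=protected" = -0.013,
      "toilet=improved" = 0.032, "electricity=yes" = 0.019,
      "newspaper=yes" = 0.213, "radio=yes" = -0.124,
      "television=yes" = 0.124
    )
  )
}

#' Default ground-truth smooth age effects
#'
#' Centred sinusoids over the `[15, 49]` age span: a half-period cosine for
#' underweight (elevated risk at young ages, declining with age) and a
#' full-period sine for overweight/obese.  Both integrate to ~0 over the
#' span, matching the sum-to-zero identification of the fitted smooth.
#'
#' @return List of two functions of age.
#' @export
default_true_smooth_functions <- function() {
  list(
    underweight = function(a) 0.6 * cos(pi * (a - 15) / 34),
    overweight_obese = function(a) 0.5 * sin(2 * pi * (a - 15) / 34)
  )
}

#' Draw ground-truth spatial effects from the GMRF prior
#'
#' Samples one centred realisation per non-reference category from the
#' intrinsic GMRF with variance parameter `delta` on the non-null
#' eigenspace of the ICAR precision (drawn-truth mode: the realised values
#' are returned so recovery can be tested against them).  The unstructured
#' truth, when requested, is iid `N(0, tau2)` centred to sum to zero.
#'
#' @param graph a [region_graph].
#' @param delta GMRF variance parameter (default 0.15).
#' @param tau2 `NULL` for no unstructured truth, or an iid variance.
#' @param seed integer seed.
#' @return List with `structured` (and `unstructured` if `tau2` is given),
#'   each a list of two named region-effect vectors.
#' @export
draw_spatial_truth <- function(graph, delta = 0.15, tau2 = NULL, seed = 1L) {
  stopifnot(inherits(graph, "region_graph"))
  set.seed(seed)
  Q <- gmrf_precision(graph, delta = delta)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  draw_g <- function() {
    z <- stats::rnorm(sum(pos)) / sqrt(eg$values[pos])
    g <- drop(eg$vectors[, pos, drop = FALSE] %*% z)
    g <- g - mean(g)
    stats::setNames(g, graph$regions)
  }
  out <- list(structured = list(underweight = draw_g(),
                                overweight_obese = draw_g()))
  if (!is.null(tau2)) {
    draw_h <- function() {
      h <- stats::rnorm(length(graph$regions), sd = sqrt(tau2))
      stats::setNames(h - mean(h), graph$regions)
    }
    out$unstructured <- list(underweight = draw_h(),
                             overweight_obese = draw_h())
  }
  out
}

# linear predictor of one category for simulated covariates
sim_eta_category <- function(config, covs, age, region, category) {
  n <- length(age)
  eta <- rep(0, n)
  be <- config$true_linear_effects[[category]]
  if (!is.null(be)) {
    if ("(Intercept)" %in% names(be)) eta <- eta + be[["(Intercept)"]]
    for (key in setdiff(names(be), "(Intercept)")) {
      parts <- strsplit(key, "=", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[1L] %in% names(covs)) {
        stop("unusable linear-effect key '", key, "'")
      }
      eta <- eta + be[[key]] * (covs[[parts[1L]]] == parts[2L])
    }
  }
  f <- config$true_smooth_functions[[category]]
  if (!is.null(f)) eta <- eta + f(age)
  g <- config$true_spatial_structured[[category]]
  if (!is.null(g)) eta <- eta + g[region]
  h <- config$true_spatial_unstructured[[category]]
  if (!is.null(h)) eta <- eta + h[region]
  unname(eta)
}

#' Simulate a synthetic survey dataset
#'
#' Draws covariates from their marginals, age uniformly on the configured
#' range, regions from `region_probs`, and the three-level outcome from the
#' multinomial logit probabilities implied by the configured true effects
#' (the full geo-additive predictor; components left `NULL` contribute
#' zero).  A BMI value consistent with the drawn category is attached so
#' the preprocessing path can be exercised end to end.
#'
#' @param config a [generator_config].
#' @param debug if `TRUE`, the returned data frame carries the realised
#'   per-record category probabilities as an attribute `"probs"` and the
#'   per-record linear predictors as `"eta"`.
#' @return Data frame with columns `id`, `age`, `region`, one column per
#'   covariate, `bmi`, `nutrition_category`.
#' @export
simulate_dataset <- function(config, debug = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records
  if (is.null(config$covariate_sampler)) {
    covs <- lapply(config$marginals, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    covs <- as.data.frame(covs, stringsAsFactors = FALSE)
  } else {
    covs <- config$covariate_sampler(n)
    stopifnot(is.data.frame(covs), nrow(covs) == n)
  }
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  region <- sample(config$graph$regions, n, replace = TRUE,
                   prob = config$region_probs)
  eta <- cbind(
    underweight = sim_eta_category(config, covs, age, region, "underweight"),
    overweight_obese = sim_eta_category(config, covs, age, region,
                                        "overweight_obese")
  )
  probs <- multinomial_probs(eta)  # columns: uw, ov, reference(normal)
  u <- stats::runif(n)
  cum1 <- probs[, 1L]
  cum2 <- cum1 + probs[, 2L]
  category <- ifelse(u < cum1, "underweight",
                     ifelse(u < cum2, "overweight_obese", "normal"))
  # BMI consistent with the drawn category (uniform within the class band)
  bmi <- stats::runif(n)
  bmi <- ifelse(category == "underweight", 15 + bmi * (18.5 - 15),
                ifelse(category == "normal", 18.5 + bmi * (23 - 18.5),
                       23 + bmi * (33 - 23)))
  out <- data.frame(id = seq_len(n), age = age, region = region,
                    covs, bmi = bmi,
                    nutrition_category = factor(category,
                                                levels = nutrition_levels()),
                    stringsAsFactors = FALSE)
  if (debug) {
    attr(out, "probs") <- probs
    attr(out, "eta") <- eta
  }
  out
}

#' Write / read survey records as CSV
#'
#' Plain UTF-8 comma-separated files with a header row; region labels are
#' written as strings.  [read_survey_csv()] validates numeric `age`/`bmi`
#' (reporting the offending row) and, when a schema is supplied, that all
#' categorical values fall inside it.
#'
#' @param records data frame of survey records.
#' @param path file path.
#' @param schema optional named list of allowed level vectors (e.g.
#'   [default_reference_levels()]).
#' @return `read_survey_csv` returns the validated data frame.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, schema = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  for (col in intersect(c("age", "bmi"), names(d))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(d[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at data row ", bad[1L], ": '",
           d[[col]][bad[1L]], "'")
    }
    d[[col]] <- v
  }
  if ("id" %in% names(d)) d$id <- utils::type.convert(d$id, as.is = TRUE)
  if (!is.null(schema)) {
    for (v in intersect(names(schema), names(d))) {
      bad <- setdiff(unique(d[[v]]), c(schema[[v]], NA, ""))
      if (length(bad)) {
        stop("column '", v, "' has value(s) outside the schema: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  if ("nutrition_category" %in% names(d)) {
    d$nutrition_category <- factor(d$nutrition_category,
                                   levels = nutrition_levels())
  }
  d
}
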