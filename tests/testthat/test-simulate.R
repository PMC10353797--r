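test_that("generator config validates its inputs", {
  expect_error(
    generator_config(10, marginals = list(w = c(a = 0.6, b = 0.5))),
    "summing to 1"
  )
  expect_error(generator_config(10, age_range = c(15, 55)))
  g <- make_region_graph("lattice2x2")
  expect_error(
    generator_config(10, graph = g,
                     true_spatial_structured = list(
                       underweight = c(R11 = 1, R12 = -1),
                       overweight_obese = c(R11 = 0, R12 = 0))),
    "length"
  )
})

test_that("zero effects give symmetric thirds at large n", {
  cfg <- tiny_config(30000, seed = 101)
  cfg$true_linear_effects <- list(
    underweight = c("(Intercept)" = 0),
    overweight_obese = c("(Intercept)" = 0)
  )
  d <- simulate_dataset(cfg)
  freq <- table(d$nutrition_category) / nrow(d)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(freq - 1 / 3) < se3))
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  cfg <- tiny_config(400, seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(tiny_config(400, seed = 8))
  expect_false(identical(d1$nutrition_category, d3$nutrition_category))
})

test_that("a single 0.64 log-odds effect is recovered by logit inversion", {
  cfg <- generator_config(
    50000,
    marginals = list(wealth = c(poorest = 0.2, poorer = 0.2, middle = 0.2,
                                richer = 0.185, richest = 0.215)),
    true_linear_effects = list(
      underweight = c("(Intercept)" = 0),
      overweight_obese = c("(Intercept)" = 0, "wealth=richest" = 0.64)
    ),
    seed = 202
  )
  d <- simulate_dataset(cfg)
  rich <- d$wealth == "richest"
  lodds <- function(sel) {
    log(sum(d$nutrition_category[sel] == "overweight_obese") /
        sum(d$nutrition_category[sel] == "normal"))
  }
  diff_lo <- lodds(rich) - lodds(!rich)
  counts <- c(
    sum(d$nutrition_category[rich] == "overweight_obese"),
    sum(d$nutrition_category[rich] == "normal"),
    sum(d$nutrition_category[!rich] == "overweight_obese"),
    sum(d$nutrition_category[!rich] == "normal")
  )
  se <- sqrt(sum(1 / counts))
  expect_lt(abs(diff_lo - 0.64), 3 * se)
})

test_that("empirical category frequencies converge to enumerated means", {
  # small discrete covariate universe -> exact mean probabilities by
  # enumeration over the joint covariate/region distribution
  g <- make_region_graph("lattice2x2")
  struct <- list(
    underweight = c(R11 = 0.4, R12 = -0.4, R21 = 0.2, R22 = -0.2),
    overweight_obese = c(R11 = -0.3, R12 = 0.3, R21 = -0.1, R22 = 0.1)
  )
  cfg <- generator_config(
    50000,
    marginals = list(working = c(no = 0.6, yes = 0.4)),
    graph = g,
    true_linear_effects = list(
      underweight = c("(Intercept)" = -0.5, "working=yes" = 0.35),
      overweight_obese = c("(Intercept)" = 0.2, "working=yes" = -0.25)
    ),
    true_spatial_structured = struct,
    seed = 303
  )
  expected <- c(0, 0, 0)
  for (w in c("no", "yes")) {
    for (reg in g$regions) {
      eta <- c(-0.5 + 0.35 * (w == "yes") + struct$underweight[reg],
               0.2 - 0.25 * (w == "yes") + struct$overweight_obese[reg])
      pw <- cfg$marginals$working[w] * 0.25
      expected <- expected + pw * multinomial_probs(eta)
    }
  }
  d <- simulate_dataset(cfg)
  emp <- table(d$nutrition_category)[c("underweight", "overweight_obese",
                                       "normal")] / nrow(d)
  se3 <- 3 * sqrt(expected * (1 - expected) / 50000)
  expect_true(all(abs(emp - expected) < se3))
})

test_that("debug mode exposes the latent probabilities actually used", {
  cfg <- tiny_config(500, seed = 9)
  d <- simulate_dataset(cfg, debug = TRUE)
  probs <- attr(d, "probs")
  expect_identical(dim(probs), c(500L, 3L))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-12)
  # eta attribute reproduces the probabilities
  expect_equal(unname(multinomial_probs(attr(d, "eta"))), unname(probs))
  # BMI is consistent with the drawn category
  expect_identical(
    as.character(collapse_to_three(classify_bmi(d$bmi))),
    as.character(d$nutrition_category)
  )
})

test_that("survey CSV round-trips and validates", {
  cfg <- tiny_config(120, seed = 10)
  d <- simulate_dataset(cfg)
  p <- tempfile(fileext = ".csv")
  write_survey_csv(d, p)
  d2 <- read_survey_csv(p)
  expect_equal(d2$age, d$age, tolerance = 1e-12)
  expect_identical(d2$region, d$region)
  expect_identical(as.character(d2$nutrition_category),
                   as.character(d$nutrition_category))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,age,region", "1,fifteen,R11"), bad)
  expect_error(read_survey_csv(bad), "row 1")
  expect_error(
    read_survey_csv(p, schema = list(wealth = c("poorest", "poorer"))),
    "outside the schema"
  )
})
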