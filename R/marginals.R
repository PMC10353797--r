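#' Published BDHS descriptive counts
#'
#' Frequency distribution of the modelled characteristics of reproductive-age
#' women in the 2014 and 2017-18 Bangladesh DHS rounds, as published
#' (counts and column percentages per survey round).  These printed counts
#' are the only public summary of the gated microdata and serve two
#' purposes: seeding the synthetic generator's covariate marginals and
#' auditing the descriptive-table arithmetic.
#'
#' @return A data frame with columns `variable`, `level`, `n_2014`,
#'   `pct_2014`, `n_2018`, `pct_2018`.
#' @export
bdhs_table1_counts <- function() {
  # variable, level, n 2014, pct 2014, n 2017-18, pct 2017-18
  rows <- list(
    list("residence", "city_corporation", 1782, 11.88, 1630, 9.73),
    list("residence", "other_urban",      3383, 22.56, 4428, 26.43),
    list("residence", "rural",            9832, 65.56, 10693, 63.84),
    list("wealth", "poorest", 2774, 18.50, 3249, 19.40),
    list("wealth", "poorer",  2841, 18.94, 3252, 19.41),
    list("wealth", "middle",  3027, 20.18, 3273, 19.53),
    list("wealth", "richer",  3148, 21.00, 3378, 20.17),
    list("wealth", "richest", 3207, 21.38, 3599, 21.49),
    list("education", "no_education", 3884, 25.90, 2980, 17.79),
    list("education", "primary",      4521, 30.15, 5579, 33.31),
    list("education", "secondary",    5356, 35.71, 6258, 37.36),
    list("education", "higher",       1236,  8.24, 1934, 11.54),
    list("working", "no",  9951, 66.35, 8185, 48.86),
    list("working", "yes", 5046, 33.65, 8566, 51.14),
    list("water", "protected",   13942, 92.97, 15378, 91.80),
    list("water", "unprotected",  1055,  7.03,  1373,  8.20),
    list("toilet", "improved",   10405, 69.38, 10963, 65.45),
    list("toilet", "unimproved",  4592, 30.62,  5788, 34.55),
    list("electricity", "no",   5753, 38.36,  3846, 22.96),
    list("electricity", "yes",  9244, 61.64, 12905, 77.04),
    list("newspaper", "no",  14078, 93.87, 16152, 96.42),
    list("newspaper", "yes",   919,  6.13,   599,  3.58),
    list("radio", "no",  14663, 97.77, 16465, 98.29),
    list("radio", "yes",   334,  2.23,   286,  1.71),
    list("television", "no",  7344, 48.97,  7692, 45.92),
    list("television", "yes", 7653, 51.04,  9059, 54.08),
    list("nutrition", "underweight",      2730, 18.20, 1962, 11.71),
    list("nutrition", "normal",           6155, 41.04, 6294, 37.58),
    list("nutrition", "overweight_obese", 6112, 40.76, 8495, 50.71)
  )
  out <- data.frame(
    variable = vapply(rows, `[[`, character(1), 1L),
    level = vapply(rows, `[[`, character(1), 2L),
    n_2014 = vapply(rows, `[[`, numeric(1), 3L),
    pct_2014 = vapply(rows, `[[`, numeric(1), 4L),
    n_2018 = vapply(rows, `[[`, numeric(1), 5L),
    pct_2018 = vapply(rows, `[[`, numeric(1), 6L),
    stringsAsFactors = FALSE
  )
  out
}

#' Default covariate marginals for the synthetic generator
#'
#' Probability vectors over the levels of every modelled categorical
#' covariate, taken from the published column percentages of the chosen
#' survey round and normalised to sum exactly to one.  The outcome
#' (`nutrition`) is excluded: the generator draws it from the multinomial
#' logit model, not from a marginal.
#'
#' @param year survey round, `2014` or `2018` (the 2017-18 round).
#' @return Named list of named probability vectors, one per covariate.
#' @examples
#' m <- default_table1_marginals(2014)
#' m$residence
#' @export
default_table1_marginals <- function(year = 2018) {
  if (!year %in% c(2014, 2018)) {
    stop("unsupported year: ", year, " (use 2014 or 2018)")
  }
  tab <- bdhs_table1_counts()
  tab <- tab[tab$variable != "nutrition", , drop = FALSE]
  pct <- if (year == 2014) tab$pct_2014 else tab$pct_2018
  out <- lapply(split(seq_len(nrow(tab)), tab$variable), function(i) {
    p <- pct[i] / sum(pct[i])
    names(p) <- tab$level[i]
    p
  })
  # keep the table's variable order, not split()'s alphabetical order
  out[unique(tab$variable)]
}
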