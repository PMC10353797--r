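#' WHO Asian BMI classification
#'
#' Classifies body mass index (kg/m^2) into the four WHO Asian-specific
#' categories.  Intervals are left-closed / right-open, so the cutoff
#' values themselves belong to the upper class: underweight `< 18.5`,
#' normal `[18.5, 23)`, overweight `[23, 27.5)`, obese `>= 27.5`.  The
#' boundary convention at exact cutoffs is not fixed by the verbal
#' definitions ("18.5 to 23.0"), so the cutoffs are exposed as an argument.
#'
#' @param bmi numeric vector of BMI values (kg/m^2); must be finite and
#'   positive.
#' @param cutoffs increasing length-3 numeric vector of class boundaries
#'   (default `c(18.5, 23, 27.5)`).
#' @return Factor with levels `underweight`, `normal`, `overweight`,
#'   `obese`.
#' @examples
#' classify_bmi(c(17, 18.5, 26, 28))
#' @export
classify_bmi <- function(bmi, cutoffs = c(18.5, 23, 27.5)) {
  if (!is.numeric(bmi)) stop("bmi must be numeric")
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and positive")
  }
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs, strictly = TRUE))
  lv <- bmi_levels4()
  cut(bmi, breaks = c(-Inf, cutoffs, Inf), labels = lv, right = FALSE)
}

bmi_levels4 <- function() c("underweight", "normal", "overweight", "obese")

#' Three-level nutrition categories used throughout the analysis
#' (reference category `normal` second).
#' @export
nutrition_levels <- function() c("underweight", "normal", "overweight_obese")

#' Collapse the four BMI classes to the three analysed categories
#'
#' `overweight` and `obese` merge into `overweight_obese`; `underweight`
#' and `normal` are unchanged.
#'
#' @param category factor or character vector of four-level BMI classes.
#' @return Factor with levels `underweight`, `normal`, `overweight_obese`.
#' @export
collapse_to_three <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), c(bmi_levels4(), NA))
  if (length(bad)) stop("unknown BMI category: ", paste(bad, collapse = ", "))
  out <- ifelse(category %in% c("overweight", "obese"),
                "overweight_obese", category)
  factor(out, levels = nutrition_levels())
}

#' Apply the study's inclusion filters
#'
#' Drops records flagged as pregnant or as having given birth within the
#' previous two months, then performs listwise deletion on missing values
#' of the modelled covariates.  Each dropped record is counted once, under
#' the first applicable reason in a fixed priority order: `pregnant`,
#' `recent_birth`, then `missing_<covariate>` in the order of
#' `covariates`.
#'
#' @param records data frame of survey records; eligibility flag columns
#'   (`pregnant`, `recent_birth_within_2_months`) are optional and treated
#'   as `FALSE` when absent.
#' @param covariates character vector of modelled covariate columns checked
#'   for missingness (defaults to every covariate column present among the
#'   standard set).
#' @return List with `kept` (the surviving records, unaltered) and
#'   `exclusion_log` (named integer vector of drop counts per reason).
#' @export
apply_inclusion_filters <- function(records, covariates = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(covariates)) {
    covariates <- intersect(names(default_table1_marginals(2018)),
                            names(records))
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  flag <- function(col) {
    if (col %in% names(records)) {
      f <- records[[col]]
      !is.na(f) & as.logical(f)
    } else rep(FALSE, n)
  }
  reason[is.na(reason) & flag("pregnant")] <- "pregnant"
  reason[is.na(reason) & flag("recent_birth_within_2_months")] <- "recent_birth"
  for (cv in covariates) {
    reason[is.na(reason) & is.na(records[[cv]])] <- paste0("missing_", cv)
  }
  kept <- records[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0L) warning("all records excluded")
  log <- table(factor(reason[!is.na(reason)]))
  list(kept = kept,
       exclusion_log = stats::setNames(as.integer(log), names(log)))
}

#' Pooled two-sample test for proportions
#'
#' The large-sample z-test comparing two binomial proportions with the
#' pooled standard error (the "t-test for proportion" of survey reports;
#' at survey sample sizes the normal and t references are
#' indistinguishable).
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return List with `z` (signed statistic, group 1 minus group 2) and
#'   `p_value` (two-sided).
#' @examples
#' two_proportion_test(2730, 14997, 1962, 16751)
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    warning("degenerate pooled proportion; test is uninformative")
    return(list(z = 0, p_value = 1))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Column percentages within a variable
#'
#' @param counts numeric vector of level counts of one variable.
#' @param total denominator; defaults to `sum(counts)`.
#' @param digits rounding for display (half-up); `NULL` for unrounded.
#' @return Percentages summing to 100 (before rounding).
#' @export
column_percentages <- function(counts, total = sum(counts), digits = 2) {
  pct <- 100 * counts / total
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

# round half away from zero, the convention of the published tables
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Descriptive comparison table across two survey rounds
#'
#' For every level of every requested categorical variable: counts and
#' column percentages in each round and the pooled two-proportion test
#' p-value for the change in the level's share between rounds.
#'
#' @param records_year1,records_year2 data frames of (classified, filtered)
#'   records.
#' @param variables character vector of columns to tabulate; defaults to
#'   the categorical columns common to both data frames.
#' @param digits display rounding of percentages (raw percentages are also
#'   returned).
#' @return Data frame with columns `variable`, `level`, `count_year1`,
#'   `pct_year1`, `count_year2`, `pct_year2`, `p_value` plus unrounded
#'   `pct_year1_raw`, `pct_year2_raw`.
#' @export
descriptive_table <- function(records_year1, records_year2,
                              variables = NULL, digits = 2) {
  stopifnot(is.data.frame(records_year1), is.data.frame(records_year2))
  if (is.null(variables)) {
    shared <- intersect(names(records_year1), names(records_year2))
    variables <- shared[vapply(shared, function(v) {
      is.character(records_year1[[v]]) || is.factor(records_year1[[v]])
    }, logical(1))]
    variables <- setdiff(variables, c("id", "region"))
  }
  n1 <- nrow(records_year1)
  n2 <- nrow(records_year2)
  out <- list()
  for (v in variables) {
    lev <- union(levels(factor(records_year1[[v]])),
                 levels(factor(records_year2[[v]])))
    c1 <- table(factor(records_year1[[v]], levels = lev))
    c2 <- table(factor(records_year2[[v]], levels = lev))
    if (any(c1 == 0L) || any(c2 == 0L)) {
      missing_lev <- lev[c1 == 0L | c2 == 0L]
      warning("variable '", v, "': level(s) absent in one round: ",
              paste(missing_lev, collapse = ", "))
    }
    for (l in lev) {
      tst <- if (length(lev) == 1L) {
        list(z = 0, p_value = 1)
      } else {
        two_proportion_test(c1[[l]], n1, c2[[l]], n2)
      }
      out[[length(out) + 1L]] <- data.frame(
        variable = v, level = l,
        count_year1 = as.integer(c1[[l]]),
        pct_year1 = column_percentages(c1[[l]], n1, digits),
        count_year2 = as.integer(c2[[l]]),
        pct_year2 = column_percentages(c2[[l]], n2, digits),
        p_value = tst$p_value,
        pct_year1_raw = 100 * c1[[l]] / n1,
        pct_year2_raw = 100 * c2[[l]] / n2,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
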