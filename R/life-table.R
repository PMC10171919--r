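# General-population background mortality: a sex-specific life table of annual
# death probabilities, and the floor that prevents extrapolated trial curves
# (especially cure-model plateaus) from implying lower mortality than k times
# the general population.

#' Read a life table of annual death probabilities
#'
#' Expects a CSV with columns `age` (integer years), `sex`
#' (`male` / `female`), `qx` (annual probability of death). Ages must be
#' contiguous per sex and the terminal age must close the table with
#' `qx = 1`.
#'
#' @param path CSV path; the default is the packaged synthetic life table
#'   (Gompertz-Makeham mortality calibrated to modern Chinese period life
#'   expectancy; a constructed stand-in, not official statistics).
#' @return a `life_table` tibble.
#' @export
read_life_table <- function(path = system.file("extdata", "life_table_synthetic.csv",
                                               package = "immunocea")) {
  lt <- readr::read_csv(path, show_col_types = FALSE)
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    abort_validation("life table must have columns age, sex, qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) abort_validation("life table qx outside [0, 1]")
  for (s in unique(lt$sex)) {
    ages <- sort(lt$age[lt$sex == s])
    if (any(diff(ages) != 1)) abort_validation("life table ages must be contiguous")
    if (lt$qx[lt$sex == s & lt$age == max(ages)] < 1) {
      abort_validation("terminal life-table age must have qx = 1")
    }
  }
  structure(as_tibble(lt), class = c("life_table", class(as_tibble(lt))))
}

# sex-mix-averaged annual death probability at integer attained ages
lt_qx <- function(lt, ages, prop_male) {
  max_age <- max(lt$age)
  ages <- pmin(pmax(floor(ages), min(lt$age)), max_age)
  qm <- setNames(lt$qx[lt$sex == "male"], lt$age[lt$sex == "male"])
  qf <- setNames(lt$qx[lt$sex == "female"], lt$age[lt$sex == "female"])
  prop_male * qm[as.character(ages)] + (1 - prop_male) * qf[as.character(ages)]
}

#' Discretize a survival model onto cycle boundaries with a mortality floor
#'
#' Converts a fitted survival model into per-cycle survival on the 28-day
#' model grid, flooring each cycle's conditional death probability at the
#' k-fold general-population level: per cycle `j`, the model's conditional
#' death probability `1 - S(t_{j+1}) / S(t_j)` is replaced by
#' `max(d_model, 1 - (1 - d_pop)^k)`, where `d_pop` converts the sex-averaged
#' annual `qx` at the attained age via `1 - (1 - qx)^(28 / 365.25)`. The
#' output is the cumulative product of the floored per-cycle survivals, so
#' floored curves reach zero even when the model has a cure plateau.
#'
#' @param fit a `surv_fit` / `cure_fit` (or any object accepted by
#'   [survival_at()], or a function of time in months).
#' @param life_table a [read_life_table()] table.
#' @param start_age cohort age (years) at model start.
#' @param prop_male baseline proportion male (fixed over the horizon; cohort,
#'   not microsimulation, model).
#' @param k background-mortality multiplier (`k >= 1`; 2 in the base case,
#'   4 in the increased-death-risk scenario).
#' @param n_cycles number of 28-day cycles in the grid.
#' @return a `cycle_survival` tibble: `cycle` (0-based boundary index),
#'   `time_days`, `time_months`, `survival` with `S[0] = 1`, plus the
#'   unfloored discretized model survival in `survival_model`.
#' @export
apply_mortality_floor <- function(fit, life_table, start_age, prop_male,
                                  k = 2, n_cycles = 780) {
  if (k < 1) abort_config("`k` must be >= 1")
  check_probability(prop_male, "prop_male")
  if (start_age < min(life_table$age) || start_age > max(life_table$age)) {
    abort_config("`start_age` outside the life table's age range")
  }
  s_fun <- if (is.function(fit)) fit else function(t) survival_at(fit, t)
  bounds_m <- (0:n_cycles) * CYCLE_MONTHS
  s_model <- s_fun(bounds_m)
  s_model <- pmin(cummin(pmax(s_model, 0)), 1)

  j <- seq_len(n_cycles)
  d_model <- ifelse(s_model[j] > 0, 1 - s_model[j + 1] / s_model[j], 1)
  ages <- start_age + (j - 1) * CYCLE_YEARS
  qx <- lt_qx(life_table, ages, prop_male)
  d_pop <- 1 - (1 - qx)^(CYCLE_DAYS / 365.25)
  d_star <- pmax(d_model, 1 - (1 - d_pop)^k)
  surv <- c(1, cumprod(1 - d_star))

  structure(tibble(
    cycle = 0:n_cycles,
    time_days = (0:n_cycles) * CYCLE_DAYS,
    time_months = bounds_m,
    survival = surv,
    survival_model = s_model
  ), class = c("cycle_survival", class(tibble())),
     start_age = start_age, prop_male = prop_male, k = k)
}
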