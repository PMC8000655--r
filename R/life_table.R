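#' Construct a life table
#'
#' A life table maps integer age to the annual probability of dying from any
#' cause, `qx`. Ages must be contiguous and `qx` in \[0, 1\].
#'
#' @param age Integer ages, ascending and contiguous.
#' @param qx Annual death probabilities.
#' @return A data frame of class `"life_table"` with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  if (length(age) == 0L || length(age) != length(qx))
    stop("age and qx must be non-empty vectors of equal length")
  if (any(diff(age) != 1L)) stop("life-table ages must be contiguous and ascending")
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1))
    stop("life-table qx values must lie in [0,1]")
  structure(data.frame(age = age, qx = as.numeric(qx)), class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects a header row and two columns `age,qx` with ages ascending.
#'
#' @param path CSV path.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life-table CSV must have columns 'age' and 'qx'")
  life_table(df$age, df$qx)
}

#' Bundled female background-mortality table
#'
#' Single-year annual death probabilities for US women, ages 40-100,
#' interpolated (log-linearly) from published five-year 2017 vital-statistics
#' anchor values. The file is a synthetic reconstruction, not the original
#' publication table; see the fixture
#' `life_table_female_2017_synthetic.csv` shipped with the package.
#'
#' @return A `life_table` covering ages 40-100.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_female_2017_synthetic.csv",
                              package = "screenCEA", mustWork = TRUE))
}

#' Generate a Gompertz life table
#'
#' Fully parametric fallback with annual death probability
#' `q(a) = 1 - exp(-b * exp(c * a))`: an exponentially increasing hazard,
#' the classic adult-mortality law. Useful when no empirical table should be
#' shipped or for stress-testing the engine.
#'
#' @param b Baseline hazard at age 0, `> 0`.
#' @param c Log-hazard slope per year of age, `> 0` (0 gives a constant
#'   `q = 1 - exp(-b)`).
#' @param age_range Integer vector of ages (contiguous), default 0-110.
#' @return A `life_table`.
#' @examples
#' lt <- gompertz_life_table(3.0e-5, 0.095)
#' annual_death_probability(lt, 55)
#' @export
gompertz_life_table <- function(b = 3.0e-5, c = 0.095, age_range = 0:110) {
  if (!is.numeric(b) || b <= 0) stop("b must be > 0")
  if (!is.numeric(c) || c < 0) stop("c must be >= 0")
  qx <- 1 - exp(-b * exp(c * age_range))
  life_table(age_range, pmin(qx, 1))
}

#' Annual background death probability at an age
#'
#' Looks up `qx` at `floor(age)`. Ages above the table maximum clamp to the
#' last row (the model horizon is expected to end well inside the table);
#' ages below the minimum are an error.
#'
#' @param table A `life_table`.
#' @param age Age in years.
#' @return Annual death probability in \[0, 1\].
#' @export
annual_death_probability <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  a <- floor(age)
  if (any(a < table$age[1L]))
    stop("age ", min(a), " below life-table minimum ", table$age[1L])
  a <- pmin(a, table$age[nrow(table)])
  table$qx[match(a, table$age)]
}
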