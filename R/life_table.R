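# Background (all-cause) mortality from a life table.

#' Weeks per year used for all annual/weekly conversions (365.25 / 7)
#' @export
WEEKS_PER_YEAR <- 365.25 / 7  # 52.18

#' Construct a life table
#'
#' @param age Integer ages in years, strictly increasing.
#' @param qx Annual probability of death at each age, in [0, 1].
#' @return A \code{life_table} data frame with columns \code{age}, \code{qx}.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age); qx <- as.numeric(qx)
  if (length(age) != length(qx) || !length(age)) {
    stop("life_table: age and qx must be non-empty and of equal length", call. = FALSE)
  }
  if (any(diff(age) <= 0)) stop("life_table: ages must be strictly increasing", call. = FALSE)
  if (any(qx < 0 | qx > 1)) stop("life_table: qx must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read a life table from a two-column CSV (age, annual_mortality_probability)
#' @param path CSV file path.
#' @return A \code{life_table}.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("read_life_table: expected 2 columns", call. = FALSE)
  life_table(df[[1]], df[[2]])
}

#' Write a life table to CSV
#' @param table A \code{life_table}.
#' @param path Output file path.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(
    data.frame(age = table$age, annual_mortality_probability = table$qx),
    path, row.names = FALSE)
  invisible(path)
}

#' Annual background mortality probability at a given age
#'
#' Ages above the table maximum clamp to the last row (the cohort outlives the
#' table only at extreme ages); ages below the table minimum are an error.
#'
#' @param table A \code{life_table}.
#' @param age Age in years (fractional allowed; integer floor is looked up).
#' @return Annual probability of death.
#' @export
annual_background_mortality <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  a <- floor(age)
  if (any(a < table$age[1])) {
    stop("annual_background_mortality: age below life-table minimum (",
         table$age[1], ")", call. = FALSE)
  }
  idx <- findInterval(a, table$age)
  table$qx[idx]
}

#' Weekly background mortality probability at a given age
#'
#' Converts the annual probability q to a per-week probability
#' \eqn{1 - (1-q)^{1/52.18}} assuming a constant hazard within the year.
#'
#' @inheritParams annual_background_mortality
#' @return Weekly probability of death.
#' @examples
#' lt <- life_table(40:100, rep(0.02, 61))
#' weekly_background_mortality(lt, 71)  # ~0.000387
#' @export
weekly_background_mortality <- function(table, age) {
  q <- annual_background_mortality(table, age)
  1 - (1 - q)^(1 / WEEKS_PER_YEAR)
}
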