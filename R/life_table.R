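#' Synthesize a Gompertz-Makeham life table
#'
#' Generates an age-indexed table of annual death probabilities
#' \eqn{q_x = 1 - \exp(-(a + b e^{c \cdot age}))}, clipped to \[0, 1\], with
#' \eqn{q_x = 1} at \code{max_age} so the horizon is absorbing. The default
#' constants are calibrated so that life expectancy at birth falls in the
#' 80-83 year band typical of the 2015 Korean period life table, making the
#' generated table a download-free stand-in for that input.
#'
#' @param makeham_a age-independent background hazard (per year), \code{>= 0}.
#' @param gompertz_b baseline senescent hazard (per year), \code{> 0}.
#' @param gompertz_c exponential ageing rate (per year of age), \code{> 0}.
#' @param max_age terminal age; \code{qx} is forced to 1 there.
#' @return An \code{amd_life_table}: data.frame with integer \code{age}
#'   (0..\code{max_age}) and \code{qx}.
#' @export
#' @examples
#' lt <- synthesize_life_table()
#' life_expectancy(lt, 0)
synthesize_life_table <- function(makeham_a = 2e-4, gompertz_b = 3e-5,
                                  gompertz_c = 0.090, max_age = 100) {
  if (!is.numeric(makeham_a) || makeham_a < 0) {
    stop("makeham_a must be >= 0", call. = FALSE)
  }
  if (!is.numeric(gompertz_b) || gompertz_b <= 0) {
    stop("gompertz_b must be > 0", call. = FALSE)
  }
  if (!is.numeric(gompertz_c) || gompertz_c <= 0) {
    stop("gompertz_c must be > 0", call. = FALSE)
  }
  ages <- 0:max_age
  hazard <- makeham_a + gompertz_b * exp(gompertz_c * ages)
  qx <- pmin(1, pmax(0, 1 - exp(-hazard)))
  qx[length(qx)] <- 1
  structure(data.frame(age = ages, qx = qx),
            class = c("amd_life_table", "data.frame"))
}

.check_life_table <- function(lt, warn_monotone = TRUE) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  if (nrow(lt) == 0) stop("life table is empty", call. = FALSE)
  if (any(lt$age != as.integer(lt$age))) {
    stop("life table ages must be integers", call. = FALSE)
  }
  if (!identical(as.integer(lt$age), as.integer(seq(lt$age[1], by = 1,
                                                    length.out = nrow(lt))))) {
    stop("life table ages must be contiguous", call. = FALSE)
  }
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0 | lt$qx > 1)) {
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  }
  if (lt$qx[nrow(lt)] != 1) {
    stop("life table must end with qx = 1 at its terminal age", call. = FALSE)
  }
  adult <- lt$qx[lt$age >= 30]
  if (warn_monotone && length(adult) > 1 && any(diff(adult) < 0)) {
    warning("adult mortality (ages >= 30) is not monotone non-decreasing",
            call. = FALSE)
  }
  invisible(lt)
}

#' Read a life table from CSV
#'
#' Expects a header \code{age,qx} and one row per contiguous integer age.
#' The terminal row must carry \code{qx = 1} (absorbing horizon); all
#' invariants are checked and a non-monotone adult mortality pattern raises a
#' warning, not an error.
#'
#' @param path CSV file path (or literal CSV text containing a newline).
#' @return An \code{amd_life_table}.
#' @export
load_life_table <- function(path) {
  df <- if (length(path) == 1 && !grepl("\n", path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(text = paste(path, collapse = "\n"), stringsAsFactors = FALSE)
  }
  lt <- structure(df[, c("age", "qx")], class = c("amd_life_table", "data.frame"))
  .check_life_table(lt)
  lt
}

#' Write a life table to CSV
#'
#' @param lt an \code{amd_life_table}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Packaged synthetic Korean-2015-like life table
#'
#' Loads the CSV fixture shipped with the package: a synthetic stand-in for
#' the 2015 Korean period life table, generated by [synthesize_life_table()]
#' at its calibrated defaults.
#'
#' @return An \code{amd_life_table}.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "korea2015_synthetic_life_table.csv",
                      package = "amdscreen")
  if (!nzchar(path)) {
    # package not installed (e.g. load_all during development): regenerate
    return(synthesize_life_table())
  }
  load_life_table(path)
}

#' Annual death probability at an age
#'
#' @param lt an \code{amd_life_table}.
#' @param age age in whole years; ages above the table end return 1, ages
#'   below the table start are an error.
#' @return The annual death probability \code{qx(age)}.
#' @export
annual_death_prob <- function(lt, age) {
  if (any(age < lt$age[1])) {
    stop("age below the life table start (", lt$age[1], ")", call. = FALSE)
  }
  i <- pmin(age - lt$age[1] + 1, nrow(lt))
  lt$qx[i]
}

#' Period life expectancy from an age
#'
#' Curtate expectation of life: the sum over whole future years of the
#' probability of surviving to each. A table with \code{qx = 1} everywhere
#' yields 0; an immortal table (qx = 0 until the terminal age) yields the
#' number of whole years to the terminal age.
#'
#' @param lt an \code{amd_life_table}.
#' @param from_age age from which to compute the expectation (must be within
#'   the table).
#' @return Expected further whole years of life.
#' @export
life_expectancy <- function(lt, from_age) {
  if (from_age < lt$age[1] || from_age > lt$age[nrow(lt)]) {
    stop("from_age outside the life table", call. = FALSE)
  }
  q <- lt$qx[lt$age >= from_age]
  sum(cumprod(1 - q))
}
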