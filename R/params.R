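#' Base-case model parameters
#'
#' Returns the base-case parameter set of the AMD screening model: annual
#' transition probabilities, screening test characteristics, state utilities,
#' annual state costs in 2018 KRW, screening unit costs, the willingness-to-pay
#' threshold, and the cohort structure (start age 40, horizon age 100, 100,000
#' persons).
#'
#' Beyond the epidemiological and economic inputs, the set carries a few
#' structural switches that resolve points the model description leaves open:
#' \describe{
#'   \item{prevalence_split}{how the initial prevalent AMD cases are divided
#'     across (mild, moderate, severe); default puts everyone in mild, where
#'     Korean prevalence is concentrated.}
#'   \item{charge_low_vision}{whether undiagnosed severe AMD accrues the
#'     low-vision cost \code{c_low_vision} each year (default \code{TRUE}).}
#'   \item{follow_up_cost}{whether diagnosed patients who regressed to no AMD
#'     accrue an annual follow-up examination at \code{c_examination}
#'     (default \code{TRUE}).}
#'   \item{symptomatic_states}{which undiagnosed severities count as
#'     symptomatic for the opportunistic-treatment arm (default
#'     \code{"SEV"}).}
#'   \item{opportunistic_mode}{\code{"annual"} applies the presentation
#'     probability independently every cycle; \code{"baseline"} applies it in
#'     the first cycle only.}
#' }
#'
#' @return An object of class \code{amd_parameters}: a named list of
#'   parameter values.
#' @seealso [load_parameters()], [validate_parameters()], [default_ranges()]
#' @export
#' @examples
#' p <- amd_parameters()
#' p$sens
#' p$c_fundusphoto
amd_parameters <- function() {
  structure(list(
    prevalence      = 0.066,
    p_not_examined  = 0.34,
    p_no_to_mild    = 0.01,
    p_mild_to_mod   = 0.0022,
    p_mod_to_sev    = 0.0015,
    p_improve       = 0.1,
    effect_tx       = 0.5,
    p_tx_comp       = 0.005,
    p_recov         = 0.4,
    sens            = 0.86,
    spec            = 0.79,
    wtp             = 30000000,
    discount_rate   = 0.05,
    start_age       = 40,
    max_age         = 100,
    cohort_size     = 100000,
    u_no            = 1,
    u_mild          = 0.81,
    u_mod           = 0.57,
    u_sev           = 0.51,
    u_cx            = 0.4,
    c_no            = 0,
    c_mild          = 620702,
    c_mod           = 1757690,
    c_sev           = 5145366,
    c_low_vision    = 1000000,
    c_additional_cx = 3000000,
    c_fundusphoto   = 8930,
    c_examination   = 111958,
    prevalence_split   = c(mild = 1, mod = 0, sev = 0),
    charge_low_vision  = TRUE,
    follow_up_cost     = TRUE,
    symptomatic_states = "SEV",
    opportunistic_mode = "annual"
  ), class = "amd_parameters")
}

# field groups used by validation, ranges and PSA sampling
.prob_fields <- c("prevalence", "p_not_examined", "p_no_to_mild",
                  "p_mild_to_mod", "p_mod_to_sev", "p_improve", "effect_tx",
                  "p_tx_comp", "p_recov", "sens", "spec")
.util_fields <- c("u_no", "u_mild", "u_mod", "u_sev", "u_cx")
.cost_fields <- c("c_no", "c_mild", "c_mod", "c_sev", "c_low_vision",
                  "c_additional_cx", "c_fundusphoto", "c_examination")

.validate_messages <- function(params) {
  errors <- character()
  warnings <- character()
  num1 <- function(field) {
    x <- params[[field]]
    is.numeric(x) && length(x) == 1 && is.finite(x)
  }
  for (f in c(.prob_fields, .util_fields)) {
    if (!num1(f)) {
      errors <- c(errors, sprintf("%s: must be a single finite number", f))
    } else if (params[[f]] < 0 || params[[f]] > 1) {
      errors <- c(errors, sprintf("%s: must lie in [0, 1], got %g", f, params[[f]]))
    }
  }
  for (f in c(.cost_fields, "wtp")) {
    if (!num1(f)) {
      errors <- c(errors, sprintf("%s: must be a single finite number", f))
    } else if (params[[f]] < 0) {
      errors <- c(errors, sprintf("%s: must be >= 0, got %g", f, params[[f]]))
    }
  }
  if (!num1("discount_rate") || params$discount_rate < 0 || params$discount_rate >= 1) {
    errors <- c(errors, sprintf("discount_rate: must lie in [0, 1), got %s",
                                format(params$discount_rate)))
  }
  if (!num1("start_age") || !num1("max_age") || params$start_age >= params$max_age) {
    errors <- c(errors, "start_age: must be less than max_age")
  }
  if (!num1("cohort_size") || params$cohort_size <= 0) {
    errors <- c(errors, "cohort_size: must be positive")
  }
  ps <- params$prevalence_split
  if (!is.numeric(ps) || length(ps) != 3 || any(ps < 0) ||
      abs(sum(ps) - 1) > 1e-8) {
    errors <- c(errors, "prevalence_split: must be 3 non-negative weights summing to 1")
  }
  if (!all(params$symptomatic_states %in% c("MILD", "MOD", "SEV"))) {
    errors <- c(errors, "symptomatic_states: must be a subset of MILD, MOD, SEV")
  }
  if (!identical(params$opportunistic_mode, "annual") &&
      !identical(params$opportunistic_mode, "baseline")) {
    errors <- c(errors, "opportunistic_mode: must be 'annual' or 'baseline'")
  }
  if (length(errors) == 0) {
    u <- unlist(params[c("u_no", "u_mild", "u_mod", "u_sev")])
    if (any(diff(u) > 0)) {
      warnings <- c(warnings,
        "utility ordering violated: expected u_no >= u_mild >= u_mod >= u_sev")
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Validate a parameter set
#'
#' Checks every domain invariant (probabilities and utilities in \[0, 1\],
#' costs non-negative, discount rate in \[0, 1), start age below the horizon
#' age) and the severity-monotone utility ordering. Validation never throws;
#' it reports.
#'
#' @param params an \code{amd_parameters} object (or plain named list).
#' @return Character vector of violation messages, empty when all invariants
#'   hold. Ordering violations are reported as messages too (they are treated
#'   as warnings, not errors, by [load_parameters()]).
#' @export
validate_parameters <- function(params) {
  v <- .validate_messages(params)
  c(v$errors, v$warnings)
}

#' Load model parameters from a YAML or JSON config
#'
#' Reads a flat-key config (YAML or JSON; a file path or literal text),
#' overrides the base-case defaults with the supplied keys, and enforces all
#' invariants. Unknown keys are rejected so that typos never silently leave a
#' parameter at its default. An optional \code{ranges} block overrides the
#' default sensitivity ranges per parameter (keys \code{low}, \code{high},
#' \code{distribution}); it is carried along and applied by
#' [default_ranges()].
#'
#' @param config a file path, or a character string of YAML/JSON. An empty
#'   string (or empty mapping) returns the defaults unchanged.
#' @return An \code{amd_parameters} object.
#' @export
load_parameters <- function(config = "") {
  params <- amd_parameters()
  if (length(config) == 1 && is.character(config) && nzchar(config) &&
      !grepl("[\n:{]", config) && file.exists(config)) {
    config <- paste(readLines(config, warn = FALSE), collapse = "\n")
  }
  parsed <- if (is.list(config)) {
    config
  } else if (!nzchar(trimws(paste(config, collapse = "\n")))) {
    list()
  } else {
    txt <- paste(config, collapse = "\n")
    tryCatch(
      if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt, simplifyVector = TRUE)
      else yaml::yaml.load(txt),
      error = function(e) stop("config parse failure: ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  if (is.null(parsed)) parsed <- list()
  if (!is.list(parsed)) stop("config parse failure: expected a mapping", call. = FALSE)

  range_overrides <- parsed[["ranges"]]
  parsed[["ranges"]] <- NULL
  unknown <- setdiff(names(parsed), names(params))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (key in names(parsed)) {
    value <- parsed[[key]]
    if (key == "prevalence_split") value <- stats::setNames(unlist(value), c("mild", "mod", "sev"))
    if (key == "symptomatic_states") value <- as.character(unlist(value))
    params[[key]] <- value
  }
  v <- .validate_messages(params)
  if (length(v$errors) > 0) {
    stop("invalid parameter(s):\n  ", paste(v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  for (w in v$warnings) warning(w, call. = FALSE)
  if (!is.null(range_overrides)) attr(params, "range_overrides") <- range_overrides
  params
}

#' Serialize a parameter set to YAML
#'
#' Writes a flat-key YAML document that [load_parameters()] reads back into an
#' equal parameter set (round-trip identity).
#'
#' @param params an \code{amd_parameters} object.
#' @param path optional file path; when omitted the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
save_parameters <- function(params, path = NULL) {
  x <- unclass(params)
  x$prevalence_split <- as.list(stats::setNames(as.numeric(x$prevalence_split),
                                                c("mild", "mod", "sev")))
  txt <- yaml::as.yaml(x)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Default sensitivity ranges
#'
#' Builds one range per varied model parameter for the deterministic and
#' probabilistic sensitivity analyses: low = 0.75 x base and high = 1.25 x
#' base, clipped to the legal domain (probabilities and utilities to \[0, 1\],
#' costs to non-negative). Parameters with a base value of 0 get a degenerate
#' \code{fixed} range and are skipped by the analyses. The distribution tag
#' drives PSA sampling: \code{beta} for probabilities and utilities,
#' \code{gamma} for costs.
#'
#' The varied set covers the uncertain model inputs: all transition and test
#' probabilities, the disease-state utilities other than the perfect-health
#' anchor \code{u_no}, and the non-zero costs. The willingness-to-pay
#' threshold, discount rate, and cohort structure are not uncertainty
#' parameters and are excluded.
#'
#' Per-parameter overrides supplied through a config \code{ranges} block (see
#' [load_parameters()]) replace the defaults.
#'
#' @param params an \code{amd_parameters} object.
#' @return A data.frame with columns \code{parameter}, \code{base},
#'   \code{low}, \code{high}, \code{distribution}.
#' @export
default_ranges <- function(params) {
  varied <- c(setdiff(.prob_fields, character()),
              setdiff(.util_fields, "u_no"),
              .cost_fields)
  base <- vapply(varied, function(f) as.numeric(params[[f]]), numeric(1))
  low <- 0.75 * base
  high <- 1.25 * base
  bounded <- varied %in% c(.prob_fields, setdiff(.util_fields, "u_no"))
  high[bounded] <- pmin(high[bounded], 1)
  low <- pmax(low, 0)
  dist <- ifelse(varied %in% .cost_fields, "gamma", "beta")
  dist[base == 0] <- "fixed"
  ranges <- data.frame(parameter = varied, base = base, low = low, high = high,
                       distribution = dist, stringsAsFactors = FALSE,
                       row.names = NULL)
  overrides <- attr(params, "range_overrides")
  for (nm in names(overrides)) {
    i <- match(nm, ranges$parameter)
    if (is.na(i)) stop("range override for unknown parameter: ", nm, call. = FALSE)
    ov <- overrides[[nm]]
    if (!is.null(ov$low)) ranges$low[i] <- ov$low
    if (!is.null(ov$high)) ranges$high[i] <- ov$high
    if (!is.null(ov$distribution)) ranges$distribution[i] <- ov$distribution
    if (ranges$low[i] > ranges$base[i] || ranges$high[i] < ranges$base[i]) {
      stop("range override for ", nm, " must satisfy low <= base <= high",
           call. = FALSE)
    }
  }
  ranges
}

#' @export
print.amd_parameters <- function(x, ...) {
  cat("AMD screening model parameters\n")
  flat <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  df <- data.frame(value = unlist(flat))
  print(df, ...)
  cat("prevalence_split:", paste(sprintf("%s=%g", c("mild", "mod", "sev"),
                                         x$prevalence_split), collapse = " "), "\n")
  cat("symptomatic_states:", paste(x$symptomatic_states, collapse = ", "), "\n")
  cat("opportunistic_mode:", x$opportunistic_mode,
      "| charge_low_vision:", x$charge_low_vision,
      "| follow_up_cost:", x$follow_up_cost, "\n")
  invisible(x)
}
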