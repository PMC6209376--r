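#' Catalog of screening strategies
#'
#' The five arms compared by the model, in the base-case reporting order:
#' \describe{
#'   \item{no_screening}{status quo; no examination, no treatment.}
#'   \item{opportunistic_treatment}{only symptomatic undiagnosed patients
#'     (default: severe AMD) who present to an ophthalmologist (probability
#'     \code{1 - p_not_examined} per year) are examined and diagnosed.}
#'   \item{systematic_photography}{the whole undiagnosed population is
#'     screened annually by fundus photography (\code{c_fundusphoto} each);
#'     positives -- true with probability \code{sens}, false with
#'     \code{1 - spec} -- get a confirmatory ophthalmologist examination at
#'     \code{c_examination}; confirmed cases are diagnosed, false positives
#'     remain undiagnosed, negatives are re-screened next year.}
#'   \item{opportunistic_examination}{undiagnosed persons presenting to an
#'     ophthalmologist for any reason (probability \code{1 - p_not_examined}
#'     per year) are examined at \code{c_examination} with perfect accuracy.}
#'   \item{systematic_examination}{the whole undiagnosed population is
#'     examined annually by an ophthalmologist (gold standard,
#'     \code{c_examination} each).}
#' }
#'
#' @return A data.frame with \code{id} and \code{label}.
#' @export
strategy_catalog <- function() {
  data.frame(
    id = c("no_screening", "opportunistic_treatment", "systematic_photography",
           "opportunistic_examination", "systematic_examination"),
    label = c("No screening", "Opportunistic treatment",
              "Systematic photography", "Opportunistic examination",
              "Systematic examination"),
    stringsAsFactors = FALSE
  )
}

.sym_states_idx <- function(params) {
  match(params$symptomatic_states, c("MILD", "MOD", "SEV")) + 1L
}

#' Apply a strategy's screening/diagnosis update to an occupancy vector
#'
#' Moves mass from undiagnosed to diagnosed states per the strategy's rule
#' (expected-value update; mass is conserved exactly) and returns the
#' screening plus confirmatory-examination cost incurred this cycle
#' (undiscounted KRW). Screening never moves mass out of diagnosed states and
#' never touches the dead.
#'
#' @param occupancy numeric occupancy vector over the 12 model states.
#' @param params an \code{amd_parameters} object.
#' @param strategy a strategy id from [strategy_catalog()].
#' @param cycle zero-based cycle index; only used when
#'   \code{opportunistic_mode = "baseline"}, where opportunistic presentation
#'   happens in cycle 0 only.
#' @return A list with \code{occupancy} (updated vector) and \code{cost}
#'   (total KRW this cycle).
#' @export
screening_update <- function(occupancy, params, strategy, cycle = 0) {
  occ <- occupancy
  cost <- 0
  undx_amd <- 2:4
  dx_amd <- 6:8

  switch(strategy,
    no_screening = NULL,
    systematic_photography = {
      n_screened <- sum(occ[.UNDX])
      true_pos <- params$sens * occ[undx_amd]
      false_pos <- (1 - params$spec) * occ[.S$NO_undx]
      cost <- n_screened * params$c_fundusphoto +
        (sum(true_pos) + false_pos) * params$c_examination
      occ[dx_amd] <- occ[dx_amd] + true_pos
      occ[undx_amd] <- occ[undx_amd] - true_pos
    },
    systematic_examination = {
      cost <- sum(occ[.UNDX]) * params$c_examination
      occ[dx_amd] <- occ[dx_amd] + occ[undx_amd]
      occ[undx_amd] <- 0
    },
    opportunistic_examination = {
      if (params$opportunistic_mode == "annual" || cycle == 0) {
        f <- 1 - params$p_not_examined
        cost <- f * sum(occ[.UNDX]) * params$c_examination
        occ[dx_amd] <- occ[dx_amd] + f * occ[undx_amd]
        occ[undx_amd] <- (1 - f) * occ[undx_amd]
      }
    },
    opportunistic_treatment = {
      if (params$opportunistic_mode == "annual" || cycle == 0) {
        f <- 1 - params$p_not_examined
        sym <- .sym_states_idx(params)
        cost <- f * sum(occ[sym]) * params$c_examination
        occ[sym + 4L] <- occ[sym + 4L] + f * occ[sym]
        occ[sym] <- (1 - f) * occ[sym]
      }
    },
    stop("unknown strategy id: ", strategy, call. = FALSE)
  )
  list(occupancy = occ, cost = as.numeric(cost))
}
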