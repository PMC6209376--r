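#' The expanded state space
#'
#' The disease has five clinical states (no AMD, mild, moderate, severe,
#' dead), but costs and treatment depend on whether the disease has been
#' diagnosed, and a treatment complication must return the patient to the
#' state they came from. The chain therefore runs on an expanded space:
#' 4 severities x \{undiagnosed, diagnosed\}, plus 3 complication tunnel
#' states (one per diagnosed AMD severity, remembering the origin), plus
#' death -- 12 states, death last.
#'
#' @return A data.frame with one row per state: \code{name},
#'   \code{severity} (NO_AMD/MILD/MOD/SEV/DEAD), \code{status}
#'   (UNDIAGNOSED/DIAGNOSED/NA), \code{tunnel_origin} (the pre-complication
#'   severity, NA outside tunnels).
#' @export
model_states <- function() {
  data.frame(
    name = c("NO_undx", "MILD_undx", "MOD_undx", "SEV_undx",
             "NO_dx", "MILD_dx", "MOD_dx", "SEV_dx",
             "CX_MILD", "CX_MOD", "CX_SEV", "DEAD"),
    severity = c("NO_AMD", "MILD", "MOD", "SEV",
                 "NO_AMD", "MILD", "MOD", "SEV",
                 "MILD", "MOD", "SEV", "DEAD"),
    status = c(rep("UNDIAGNOSED", 4), rep("DIAGNOSED", 7), NA),
    tunnel_origin = c(rep(NA, 8), "MILD", "MOD", "SEV", NA),
    stringsAsFactors = FALSE
  )
}

# fixed state indices
.S <- list(NO_undx = 1L, MILD_undx = 2L, MOD_undx = 3L, SEV_undx = 4L,
           NO_dx = 5L, MILD_dx = 6L, MOD_dx = 7L, SEV_dx = 8L,
           CX_MILD = 9L, CX_MOD = 10L, CX_SEV = 11L, DEAD = 12L)
.N_STATES <- 12L
.UNDX <- 1:4
.DX_AMD <- 6:8
.TUNNELS <- 9:11

#' Initial cohort distribution
#'
#' Places \code{prevalence x cohort_size} persons in the undiagnosed AMD
#' states (divided by \code{prevalence_split}; by default everyone starts
#' mild) and the remainder in undiagnosed no-AMD. Nobody starts diagnosed,
#' in a complication tunnel, or dead.
#'
#' @param params an \code{amd_parameters} object.
#' @return Numeric occupancy vector (persons) over the 12 states.
#' @export
initial_distribution <- function(params) {
  occ <- numeric(.N_STATES)
  n_amd <- params$prevalence * params$cohort_size
  occ[.S$NO_undx] <- params$cohort_size - n_amd
  occ[2:4] <- n_amd * as.numeric(params$prevalence_split)
  names(occ) <- model_states()$name
  occ
}

# Transition probabilities conditional on surviving the year. Strategy
# membership is encoded in the state (diagnosed states are the treated
# states), so this matrix is shared by all strategies.
.conditional_matrix <- function(params) {
  M <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(model_states()$name, model_states()$name))
  p <- params
  # untreated: progression only, at the natural rates
  M[1, 2] <- p$p_no_to_mild
  M[2, 3] <- p$p_mild_to_mod
  M[3, 4] <- p$p_mod_to_sev
  # diagnosed no-AMD (regressed, off active treatment, under follow-up):
  # re-develops AMD and is detected immediately
  M[5, 6] <- p$p_no_to_mild
  # diagnosed AMD (treated): slowed progression, one-level regression,
  # complication entry; the three events are mutually exclusive in a cycle
  M[6, 7] <- p$p_mild_to_mod * p$effect_tx
  M[6, 5] <- p$p_improve
  M[6, 9] <- p$p_tx_comp
  M[7, 8] <- p$p_mod_to_sev * p$effect_tx
  M[7, 6] <- p$p_improve
  M[7, 10] <- p$p_tx_comp
  M[8, 7] <- p$p_improve
  M[8, 11] <- p$p_tx_comp
  # complication tunnels: recover back to the origin state or stay
  M[9, 6] <- p$p_recov
  M[10, 7] <- p$p_recov
  M[11, 8] <- p$p_recov
  leaving <- rowSums(M)
  if (any(leaving > 1 + 1e-12)) {
    bad <- rownames(M)[leaving > 1 + 1e-12]
    stop("transition probabilities out of state(s) ",
         paste(bad, collapse = ", "), " exceed 1; parameters are inconsistent",
         call. = FALSE)
  }
  diag(M) <- diag(M) + (1 - leaving)
  M[.S$DEAD, ] <- 0
  M[.S$DEAD, .S$DEAD] <- 1
  M
}

.compose_with_mortality <- function(M, qx) {
  P <- M * (1 - qx)
  P[, .S$DEAD] <- P[, .S$DEAD] + qx
  P[.S$DEAD, ] <- 0
  P[.S$DEAD, .S$DEAD] <- 1
  P
}

#' Age-specific transition matrix
#'
#' Row-stochastic matrix over the 12 model states at a given age: the annual
#' death probability \code{qx(age)} applies uniformly to every living state
#' (mortality depends only on age, with no excess AMD mortality), and the
#' disease transitions apply conditional on survival. Death is absorbing.
#' Treatment status is encoded in the state space, so the matrix is the same
#' for every strategy; the \code{strategy} argument is accepted for interface
#' symmetry with [run_cohort()].
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param strategy strategy id (unused; see Details).
#' @param age age in years, within the life table.
#' @return A 12 x 12 row-stochastic matrix.
#' @export
transition_matrix <- function(params, lt, strategy = "no_screening", age) {
  qx <- annual_death_prob(lt, age)
  .compose_with_mortality(.conditional_matrix(params), qx)
}

# state-indexed annual cost and utility vectors
.state_costs <- function(params) {
  c(0, 0, 0,
    if (isTRUE(params$charge_low_vision)) params$c_low_vision else 0,
    params$c_no + if (isTRUE(params$follow_up_cost)) params$c_examination else 0,
    params$c_mild, params$c_mod, params$c_sev,
    params$c_mild, params$c_mod, params$c_sev,   # tunnels keep origin-state care costs
    0)
}

.state_utils <- function(params) {
  c(params$u_no, params$u_mild, params$u_mod, params$u_sev,
    params$u_no, params$u_mild, params$u_mod, params$u_sev,
    params$u_cx, params$u_cx, params$u_cx,
    0)
}

#' Run the deterministic cohort projection for one strategy
#'
#' Projects the 100,000-person cohort from \code{start_age} until death or
#' \code{max_age} (one-year cycles). Each cycle applies, in order:
#' \enumerate{
#'   \item the strategy's screening/diagnosis update, accruing screening and
#'     confirmatory-examination costs;
#'   \item state cost and utility accrual on the post-screening occupancy;
#'   \item the age-specific transition, charging the one-time complication
#'     cost \code{c_additional_cx} on entry into a tunnel state.
#' }
#' Cycle-\code{t} accruals are discounted by \eqn{(1+r)^{-t}} with
#' \eqn{t = 0} for the first cycle. No half-cycle correction is applied.
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param strategy one of the ids in [strategy_catalog()].
#' @return A list of class \code{amd_cohort} with \code{trace} (one row per
#'   cycle: age, post-screening occupancy, undiscounted and discounted
#'   accruals, plus a terminal occupancy row) and \code{result} (a one-row
#'   data.frame: per-person expected discounted lifetime \code{cost} in KRW
#'   and \code{qaly}).
#' @export
run_cohort <- function(params, lt, strategy = "no_screening") {
  horizon <- params$max_age - params$start_age
  M <- .conditional_matrix(params)
  costs <- .state_costs(params)
  utils_ <- .state_utils(params)
  r <- params$discount_rate

  occ <- initial_distribution(params)
  state_names <- model_states()$name
  trace_occ <- matrix(NA_real_, horizon + 1, .N_STATES,
                      dimnames = list(NULL, state_names))
  acc <- matrix(0, horizon + 1, 4,
                dimnames = list(NULL, c("cost", "qaly", "disc_cost", "disc_qaly")))

  total_cost <- 0
  total_qaly <- 0
  for (t in 0:(horizon - 1)) {
    age <- params$start_age + t
    upd <- screening_update(occ, params, strategy, cycle = t)
    occ <- upd$occupancy
    trace_occ[t + 1, ] <- occ

    cycle_cost <- upd$cost + sum(occ * costs)
    cycle_qaly <- sum(occ * utils_)

    qx <- annual_death_prob(lt, age)
    P <- .compose_with_mortality(M, qx)
    new_occ <- as.numeric(occ %*% P)
    # one-time complication cost on tunnel entry (flows from non-tunnel states)
    entrants <- sum(occ[-.TUNNELS] %*% P[-.TUNNELS, .TUNNELS, drop = FALSE])
    cycle_cost <- cycle_cost + entrants * params$c_additional_cx

    disc <- (1 + r)^(-t)
    acc[t + 1, ] <- c(cycle_cost, cycle_qaly, cycle_cost * disc, cycle_qaly * disc)
    total_cost <- total_cost + cycle_cost * disc
    total_qaly <- total_qaly + cycle_qaly * disc
    occ <- stats::setNames(new_occ, state_names)
  }
  # absorbing horizon: the age-cap transition (qx = 1 at the table end) is
  # applied for bookkeeping, with no further accrual
  occ <- stats::setNames(
    as.numeric(occ %*% .compose_with_mortality(M, annual_death_prob(lt, params$max_age))),
    state_names)
  trace_occ[horizon + 1, ] <- occ

  trace <- data.frame(cycle = 0:horizon, age = params$start_age + 0:horizon,
                      trace_occ, acc, check.names = FALSE)
  result <- data.frame(strategy = strategy,
                       cost = total_cost / params$cohort_size,
                       qaly = total_qaly / params$cohort_size,
                       stringsAsFactors = FALSE)
  structure(list(trace = trace, result = result), class = "amd_cohort")
}

#' Run every strategy
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param strategies strategy ids; defaults to the full catalog.
#' @return A data.frame with one row per strategy: \code{strategy},
#'   per-person discounted \code{cost} (KRW) and \code{qaly}.
#' @export
run_all_strategies <- function(params, lt, strategies = strategy_catalog()$id) {
  out <- do.call(rbind, lapply(strategies,
                               function(s) run_cohort(params, lt, s)$result))
  rownames(out) <- NULL
  out
}

#' Any-AMD prevalence among survivors along a trace
#'
#' The natural-history validation measure: at each cycle, the proportion of
#' living cohort members who have (or have had) AMD -- everyone outside the
#' undiagnosed no-AMD state. Patients who regressed to no AMD under treatment
#' remain under follow-up and are counted, so the measure is the cumulative
#' ever-AMD prevalence among survivors.
#'
#' @param cohort an \code{amd_cohort} from [run_cohort()].
#' @return A data.frame with \code{cycle}, \code{age}, \code{prevalence}.
#' @export
amd_prevalence <- function(cohort) {
  tr <- cohort$trace
  states <- model_states()$name
  alive <- rowSums(tr[, setdiff(states, "DEAD")])
  ever <- alive - tr[["NO_undx"]]
  data.frame(cycle = tr$cycle, age = tr$age,
             prevalence = ifelse(alive > 0, ever / alive, NA_real_))
}
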