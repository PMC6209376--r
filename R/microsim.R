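#' Individual-level microsimulation oracle
#'
#' Simulates individual trajectories through the identical per-cycle event
#' logic as [run_cohort()] -- screening, accrual, transition, with the same
#' transition matrices and the same discounting -- replacing expected-value
#' mass flows by random draws. Used to validate the cohort engine: its mean
#' discounted cost and QALY estimate the cohort expectations, with Monte
#' Carlo standard errors shrinking as \eqn{1/\sqrt{n}}.
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param strategy a strategy id from [strategy_catalog()].
#' @param n_individuals number of simulated persons.
#' @param seed RNG seed; runs are bit-identical for a fixed seed.
#' @return A one-row data.frame: \code{strategy}, mean discounted \code{cost}
#'   and \code{qaly} per person, their standard errors \code{se_cost} and
#'   \code{se_qaly}, and \code{n}.
#' @export
microsim_oracle <- function(params, lt, strategy, n_individuals = 20000,
                            seed = 1) {
  stopifnot(n_individuals >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  horizon <- params$max_age - params$start_age
  M <- .conditional_matrix(params)
  costs <- .state_costs(params)
  utils_ <- .state_utils(params)
  r <- params$discount_rate
  f_present <- 1 - params$p_not_examined
  sym <- .sym_states_idx(params)
  n <- n_individuals

  # initial states drawn from the cohort's initial distribution
  init <- initial_distribution(params) / params$cohort_size
  state <- sample.int(.N_STATES, n, replace = TRUE, prob = init)

  cost_i <- numeric(n)
  qaly_i <- numeric(n)

  for (t in 0:(horizon - 1)) {
    disc <- (1 + r)^(-t)
    # --- screening -------------------------------------------------------
    if (strategy == "systematic_photography") {
      undx <- which(state %in% .UNDX)
      cost_i[undx] <- cost_i[undx] + params$c_fundusphoto * disc
      amd <- undx[state[undx] %in% 2:4]
      tp <- amd[stats::runif(length(amd)) < params$sens]
      healthy <- undx[state[undx] == .S$NO_undx]
      fp <- healthy[stats::runif(length(healthy)) < (1 - params$spec)]
      cost_i[c(tp, fp)] <- cost_i[c(tp, fp)] + params$c_examination * disc
      state[tp] <- state[tp] + 4L
    } else if (strategy == "systematic_examination") {
      undx <- which(state %in% .UNDX)
      cost_i[undx] <- cost_i[undx] + params$c_examination * disc
      amd <- undx[state[undx] %in% 2:4]
      state[amd] <- state[amd] + 4L
    } else if (strategy == "opportunistic_examination") {
      if (params$opportunistic_mode == "annual" || t == 0) {
        undx <- which(state %in% .UNDX)
        pres <- undx[stats::runif(length(undx)) < f_present]
        cost_i[pres] <- cost_i[pres] + params$c_examination * disc
        amd <- pres[state[pres] %in% 2:4]
        state[amd] <- state[amd] + 4L
      }
    } else if (strategy == "opportunistic_treatment") {
      if (params$opportunistic_mode == "annual" || t == 0) {
        symp <- which(state %in% sym)
        pres <- symp[stats::runif(length(symp)) < f_present]
        cost_i[pres] <- cost_i[pres] + params$c_examination * disc
        state[pres] <- state[pres] + 4L
      }
    } else if (strategy != "no_screening") {
      stop("unknown strategy id: ", strategy, call. = FALSE)
    }

    # --- accrual ---------------------------------------------------------
    cost_i <- cost_i + costs[state] * disc
    qaly_i <- qaly_i + utils_[state] * disc

    # --- transition ------------------------------------------------------
    qx <- annual_death_prob(lt, params$start_age + t)
    P <- .compose_with_mortality(M, qx)
    new_state <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      new_state[idx] <- sample.int(.N_STATES, length(idx), replace = TRUE,
                                   prob = P[s, ])
    }
    entered_tunnel <- which(!(state %in% .TUNNELS) & new_state %in% .TUNNELS)
    cost_i[entered_tunnel] <- cost_i[entered_tunnel] +
      params$c_additional_cx * disc
    state <- new_state
  }

  data.frame(strategy = strategy,
             cost = mean(cost_i), qaly = mean(qaly_i),
             se_cost = stats::sd(cost_i) / sqrt(n),
             se_qaly = stats::sd(qaly_i) / sqrt(n),
             n = n, stringsAsFactors = FALSE)
}
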