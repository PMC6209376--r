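#' Discount factor for a cycle
#'
#' @param cycle zero-based cycle index.
#' @param r annual discount rate.
#' @return \eqn{(1 + r)^{-cycle}}.
#' @export
discount_factor <- function(cycle, r) {
  stopifnot(all(cycle >= 0))
  (1 + r)^(-cycle)
}

#' Incremental cost-effectiveness ratio
#'
#' \eqn{\Delta C / \Delta E} of the comparator versus the reference; the sign
#' is preserved (interpretation of negative ICERs is left to the frontier
#' routine).
#'
#' @param reference,comparator strategy results: anything with \code{cost} and
#'   \code{qaly} elements (e.g. one-row data.frames from [run_cohort()]).
#' @return KRW per QALY.
#' @export
icer <- function(reference, comparator) {
  de <- comparator$qaly - reference$qaly
  if (isTRUE(all(de == 0))) {
    stop("ICER undefined: zero incremental effect", call. = FALSE)
  }
  (comparator$cost - reference$cost) / de
}

#' Net monetary benefit
#'
#' @param result strategy result(s) with \code{cost} and \code{qaly}
#'   (vectorized over rows of a data.frame).
#' @param wtp willingness-to-pay threshold, KRW per QALY.
#' @return \code{wtp * qaly - cost}, in KRW.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qaly - result$cost
}

#' NMB-optimal strategy at a threshold
#'
#' @param results data.frame of strategy results (\code{strategy},
#'   \code{cost}, \code{qaly}).
#' @param wtp willingness-to-pay threshold, KRW per QALY.
#' @return The strategy id maximizing net monetary benefit; ties broken
#'   toward lower cost, then input order.
#' @export
optimal_strategy <- function(results, wtp) {
  nmb <- net_monetary_benefit(results, wtp)
  best <- which(nmb == max(nmb))
  if (length(best) > 1) best <- best[order(results$cost[best])]
  results$strategy[best[1]]
}

#' Cost-effectiveness frontier with dominance elimination
#'
#' Classifies each strategy as on the frontier, strongly dominated (another
#' strategy costs no more and yields no less, with at least one strict), or
#' extended dominated (its incremental ICER along the cost-ordered survivors
#' exceeds that of the next, more effective survivor; such strategies are
#' removed iteratively until frontier ICERs strictly increase). Frontier
#' entries carry incremental cost/effect and ICER versus the previous
#' frontier member.
#'
#' @param results data.frame of strategy results (\code{strategy},
#'   \code{cost}, \code{qaly}).
#' @return A data.frame sorted by cost: \code{strategy}, \code{cost},
#'   \code{qaly}, \code{status}, \code{inc_cost}, \code{inc_qaly},
#'   \code{icer} (NA off the frontier and for the cheapest frontier entry).
#' @export
dominance_frontier <- function(results) {
  stopifnot(nrow(results) >= 1)
  res <- results[order(results$cost, -results$qaly), , drop = FALSE]
  n <- nrow(res)
  status <- rep("frontier", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          res$cost[j] <= res$cost[i] && res$qaly[j] >= res$qaly[i] &&
          (res$cost[j] < res$cost[i] || res$qaly[j] > res$qaly[i])) {
        status[i] <- "strongly_dominated"
        break
      }
    }
  }

  repeat {
    surv <- which(status == "frontier")
    if (length(surv) < 3) break
    icers <- diff(res$cost[surv]) / diff(res$qaly[surv])
    drop <- which(diff(icers) <= 0)  # ICER_k >= ICER_{k+1}: k+1-th survivor out
    if (length(drop) == 0) break
    status[surv[drop[1] + 1]] <- "extended_dominated"
  }

  res$status <- status
  res$inc_cost <- NA_real_
  res$inc_qaly <- NA_real_
  res$icer <- NA_real_
  front <- which(status == "frontier")
  if (length(front) > 1) {
    for (k in 2:length(front)) {
      i <- front[k]; prev <- front[k - 1]
      res$inc_cost[i] <- res$cost[i] - res$cost[prev]
      res$inc_qaly[i] <- res$qaly[i] - res$qaly[prev]
      res$icer[i] <- res$inc_cost[i] / res$inc_qaly[i]
    }
  }
  rownames(res) <- NULL
  res
}

#' All-strategies incremental table (sequential comparisons)
#'
#' The companion "all strategies" view: strategies sorted by cost, each
#' compared to the previous non-strongly-dominated row (so after a strongly
#' dominated strategy, the comparison reverts to the last valid comparator).
#' Negative ICERs are reported as computed.
#'
#' @param results data.frame of strategy results.
#' @return A data.frame sorted by cost with \code{inc_cost}, \code{inc_qaly},
#'   \code{icer} and the dominance \code{status} from [dominance_frontier()].
#' @export
incremental_table <- function(results) {
  fr <- dominance_frontier(results)
  n <- nrow(fr)
  inc_cost <- rep(NA_real_, n)
  inc_qaly <- rep(NA_real_, n)
  icer_col <- rep(NA_real_, n)
  comparator <- NA_integer_
  for (i in seq_len(n)) {
    if (!is.na(comparator)) {
      inc_cost[i] <- fr$cost[i] - fr$cost[comparator]
      inc_qaly[i] <- fr$qaly[i] - fr$qaly[comparator]
      icer_col[i] <- inc_cost[i] / inc_qaly[i]
    }
    if (fr$status[i] != "strongly_dominated") comparator <- i
  }
  fr$inc_cost <- inc_cost
  fr$inc_qaly <- inc_qaly
  fr$icer <- icer_col
  fr
}
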