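#' One-way (tornado) sensitivity analysis
#'
#' For each varied parameter, re-runs all strategies with that parameter at
#' its low and at its high value (everything else at base) and records the
#' outcome: the net monetary benefit, at the given threshold, of the strategy
#' that is NMB-optimal in the base case. Strategy switches at either end are
#' recorded. Entries are sorted by spread (|high - low| of the outcome),
#' descending -- the tornado ordering.
#'
#' @param params an \code{amd_parameters} object.
#' @param ranges data.frame of ranges from [default_ranges()]; rows with
#'   \code{distribution == "fixed"} or degenerate ranges contribute spread 0
#'   without re-running.
#' @param lt an \code{amd_life_table}.
#' @param wtp willingness-to-pay threshold; defaults to \code{params$wtp}.
#' @return A data.frame: \code{parameter}, \code{low}, \code{high},
#'   \code{nmb_low}, \code{nmb_high}, \code{spread}, \code{opt_low},
#'   \code{opt_high}, \code{switches}, sorted by decreasing spread.
#' @export
one_way_sa <- function(params, ranges = default_ranges(params), lt,
                       wtp = params$wtp) {
  base_results <- run_all_strategies(params, lt)
  base_opt <- optimal_strategy(base_results, wtp)
  base_nmb <- net_monetary_benefit(
    base_results[base_results$strategy == base_opt, ], wtp)

  eval_at <- function(field, value) {
    if (value < 0) stop("range for ", field, " violates the parameter domain",
                        call. = FALSE)
    p2 <- params
    p2[[field]] <- value
    v <- .validate_messages(p2)
    if (length(v$errors) > 0) {
      stop("range for ", field, " violates the parameter domain: ",
           v$errors[1], call. = FALSE)
    }
    results <- run_all_strategies(p2, lt)
    list(nmb = net_monetary_benefit(results[results$strategy == base_opt, ], wtp),
         opt = optimal_strategy(results, wtp))
  }

  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    rg <- ranges[i, ]
    if (rg$distribution == "fixed" || rg$low == rg$high) {
      return(data.frame(parameter = rg$parameter, low = rg$low, high = rg$high,
                        nmb_low = base_nmb, nmb_high = base_nmb, spread = 0,
                        opt_low = base_opt, opt_high = base_opt,
                        switches = FALSE, stringsAsFactors = FALSE))
    }
    lo <- eval_at(rg$parameter, rg$low)
    hi <- eval_at(rg$parameter, rg$high)
    data.frame(parameter = rg$parameter, low = rg$low, high = rg$high,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               spread = abs(hi$nmb - lo$nmb),
               opt_low = lo$opt, opt_high = hi$opt,
               switches = lo$opt != base_opt | hi$opt != base_opt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_optimal") <- base_opt
  attr(out, "base_nmb") <- base_nmb
  out
}

#' Two-way sensitivity analysis
#'
#' Evaluates the NMB-optimal strategy on a \code{grid_n x grid_n} lattice over
#' two parameter ranges, producing the strategy-region map.
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param wtp willingness-to-pay threshold.
#' @param param_x,param_y parameter names (must differ).
#' @param range_x,range_y length-2 numeric \code{c(low, high)} for each axis.
#' @param grid_n lattice points per axis (\code{>= 2}).
#' @return A data.frame with one row per cell: \code{x}, \code{y},
#'   \code{optimal}; parameter names kept in attributes \code{param_x},
#'   \code{param_y}.
#' @export
two_way_sa <- function(params, lt, wtp = params$wtp, param_x, range_x,
                       param_y, range_y, grid_n = 11) {
  stopifnot(grid_n >= 2)
  if (identical(param_x, param_y)) {
    stop("param_x and param_y must be different parameters", call. = FALSE)
  }
  xs <- seq(range_x[1], range_x[2], length.out = grid_n)
  ys <- seq(range_y[1], range_y[2], length.out = grid_n)
  grid <- expand.grid(x = xs, y = ys)
  grid$optimal <- vapply(seq_len(nrow(grid)), function(i) {
    p2 <- params
    p2[[param_x]] <- grid$x[i]
    p2[[param_y]] <- grid$y[i]
    optimal_strategy(run_all_strategies(p2, lt), wtp)
  }, character(1))
  attr(grid, "param_x") <- param_x
  attr(grid, "param_y") <- param_y
  grid
}

# one PSA draw of each sampled parameter
.psa_sample <- function(ranges) {
  vals <- numeric(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    m <- ranges$base[i]
    vals[i] <- switch(ranges$distribution[i],
      fixed = m,
      beta = {
        s <- 0.2 * m
        if (m <= 0 || m >= 1) m
        else {
          v <- s^2
          if (v >= m * (1 - m)) {
            stop("invalid beta distribution parameters for ",
                 ranges$parameter[i], call. = FALSE)
          }
          k <- m * (1 - m) / v - 1
          stats::rbeta(1, m * k, (1 - m) * k)
        }
      },
      gamma = {
        if (m == 0) 0
        else {
          shape <- 1 / 0.2^2          # SD = 20% of the mean
          stats::rgamma(1, shape = shape, rate = shape / m)
        }
      },
      stop("unknown distribution tag: ", ranges$distribution[i], call. = FALSE)
    )
  }
  stats::setNames(vals, ranges$parameter)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every sampled parameter from its distribution (beta for
#' probabilities and utilities, gamma for costs, both moment-matched with a
#' standard deviation of 20% of the base mean; \code{fixed} rows stay at
#' base), runs all strategies per draw, and records the (cost, QALY) pair of
#' each strategy. Fully reproducible for a fixed seed.
#'
#' @param params an \code{amd_parameters} object.
#' @param ranges data.frame from [default_ranges()] (its \code{distribution}
#'   column selects the sampled parameters).
#' @param lt an \code{amd_life_table}.
#' @param n_draws number of parameter draws (the study design uses 10,000).
#' @param seed RNG seed.
#' @return A data.frame with columns \code{draw}, \code{strategy},
#'   \code{cost}, \code{qaly}.
#' @export
psa_run <- function(params, ranges = default_ranges(params), lt,
                    n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    draw <- .psa_sample(ranges)
    p2 <- params
    for (nm in names(draw)) p2[[nm]] <- unname(draw[nm])
    res <- run_all_strategies(p2, lt)
    res$draw <- d
    out[[d]] <- res
  }
  res <- do.call(rbind, out)
  res[, c("draw", "strategy", "cost", "qaly")]
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which each
#' strategy has the highest net monetary benefit. Probabilities sum to 1 at
#' every threshold.
#'
#' @param psa_results data.frame from [psa_run()].
#' @param wtp_grid numeric vector of thresholds (KRW/QALY); default 0 to 60
#'   million in steps of 1 million.
#' @return A data.frame: \code{wtp}, \code{strategy}, \code{probability}.
#' @export
ceac <- function(psa_results, wtp_grid = seq(0, 6e7, by = 1e6)) {
  stopifnot(length(wtp_grid) >= 1, nrow(psa_results) >= 1)
  draws <- split(psa_results, psa_results$draw)
  strategies <- unique(psa_results$strategy)
  rows <- lapply(wtp_grid, function(w) {
    winners <- vapply(draws, optimal_strategy, character(1), wtp = w)
    prob <- vapply(strategies, function(s) mean(winners == s), numeric(1))
    data.frame(wtp = w, strategy = strategies, probability = unname(prob),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
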