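# the published five (cost, QALY) pairs are packaged inputs for the frontier algebra
published <- amdscreen::published_strategy_results()
row_of <- function(id) published[published$strategy == id, ]

test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(-1, 0.05))
})

test_that("ICER algebra matches the published no-screening vs photography comparison", {
  ic <- icer(row_of("no_screening"), row_of("systematic_photography"))
  expect_equal(ic, (9351964.25 - 289013.77) / (40.47 - 37.73))
  expect_equal(ic, 3.31e6, tolerance = 0.01)

  expect_error(icer(row_of("no_screening"), row_of("no_screening")), "zero incremental")
  # antisymmetric increments: the ratio is direction-invariant
  expect_equal(icer(row_of("systematic_photography"), row_of("no_screening")), ic)
  # cheaper-and-better comparator gives a negative ICER, flagged downstream
  expect_lt(icer(row_of("systematic_photography"), row_of("opportunistic_examination")), 0)
})

test_that("net monetary benefit is wtp x effect - cost and linear in wtp", {
  ph <- row_of("systematic_photography")
  expect_equal(net_monetary_benefit(ph, 3e7), 3e7 * 40.47 - 9351964.25)
  expect_equal(net_monetary_benefit(ph, 3e7), 1204748035.75)
  expect_equal(net_monetary_benefit(ph, 0), -ph$cost)
  slope <- (net_monetary_benefit(ph, 2e7) - net_monetary_benefit(ph, 1e7)) / 1e7
  expect_equal(slope, ph$qaly)
})

test_that("NMB-optimal strategy at the published pairs follows the threshold", {
  expect_equal(optimal_strategy(published, 3e7), "systematic_examination")
  expect_equal(optimal_strategy(published, 3e6), "no_screening")
  expect_equal(optimal_strategy(published[3, ], 5e6), "systematic_photography")
})

test_that("dominance elimination reproduces the published frontier structure", {
  fr <- dominance_frontier(published)
  status <- stats::setNames(fr$status, fr$strategy)
  expect_equal(status[["opportunistic_examination"]], "strongly_dominated")
  expect_equal(status[["opportunistic_treatment"]], "extended_dominated")
  expect_setequal(fr$strategy[fr$status == "frontier"],
                  c("no_screening", "systematic_photography",
                    "systematic_examination"))
  front <- fr[fr$status == "frontier", ]
  expect_true(all(diff(front$cost) > 0))
  expect_true(all(diff(front$qaly) > 0))
  expect_true(all(diff(front$icer[-1]) > 0))
})

test_that("dominance handles degenerate inputs: single strategy and cost ties", {
  single <- data.frame(strategy = "only", cost = 10, qaly = 1)
  fr <- dominance_frontier(single)
  expect_equal(fr$status, "frontier")
  expect_true(is.na(fr$icer))

  tie <- data.frame(strategy = c("a", "b"), cost = c(10, 10), qaly = c(2, 1))
  fr2 <- dominance_frontier(tie)
  expect_equal(fr2$status[fr2$strategy == "b"], "strongly_dominated")
  expect_equal(fr2$status[fr2$strategy == "a"], "frontier")
})

test_that("strong dominance is invariant to affine rescaling of costs", {
  fr1 <- dominance_frontier(published)
  scaled <- published
  scaled$cost <- 2.5 * scaled$cost + 1e4
  fr2 <- dominance_frontier(scaled)
  strong1 <- fr1$strategy[fr1$status == "strongly_dominated"]
  strong2 <- fr2$strategy[fr2$status == "strongly_dominated"]
  expect_setequal(strong1, strong2)
})

test_that("the optimum walks the frontier from cheapest to most effective as wtp grows", {
  fr <- dominance_frontier(published)
  frontier_ids <- fr$strategy[fr$status == "frontier"]
  wtps <- c(0, 1e6, 3e6, 5e6, 1e7, 3e7, 6e7, 1e8)
  opts <- vapply(wtps, function(w) optimal_strategy(published, w), character(1))
  expect_true(all(opts %in% frontier_ids))
  ranks <- match(opts, frontier_ids)  # frontier is cost-ordered
  expect_true(all(diff(ranks) >= 0))
})

test_that("the sequential all-strategies table chains to the last valid comparator", {
  tab <- incremental_table(published)
  get <- function(id, col) tab[tab$strategy == id, col]
  expect_equal(get("opportunistic_treatment", "inc_cost"), 74679.08)
  expect_equal(get("systematic_photography", "inc_cost"), 8988271.40)
  expect_equal(get("opportunistic_examination", "inc_qaly"), -0.35)
  # systematic examination reverts to photography, skipping the dominated arm
  expect_equal(get("systematic_examination", "inc_cost"),
               12309783.34 - 9351964.25)
})
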