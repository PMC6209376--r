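test_that("strategy catalog lists the five arms once each", {
  cat_ <- strategy_catalog()
  expect_equal(nrow(cat_), 5)
  expect_equal(anyDuplicated(cat_$id), 0)
  expect_setequal(cat_$id, c("no_screening", "opportunistic_examination",
                             "opportunistic_treatment", "systematic_photography",
                             "systematic_examination"))
})

test_that("photography detects with its sensitivity and false-positives with 1 - specificity", {
  p <- base_params()
  occ <- initial_distribution(p) * 0
  occ["MILD_undx"] <- 1000
  upd <- screening_update(occ, p, "systematic_photography")
  expect_equal(upd$occupancy[["MILD_dx"]], 860)   # 1000 x 0.86
  expect_equal(upd$occupancy[["MILD_undx"]], 140)
  expect_equal(upd$cost, 1000 * p$c_fundusphoto + 860 * p$c_examination)

  occ2 <- occ * 0
  occ2["NO_undx"] <- 1000
  upd2 <- screening_update(occ2, p, "systematic_photography")
  # 210 expected false positives pay the confirmatory exam but stay undiagnosed
  expect_equal(upd2$occupancy, occ2)
  expect_equal(upd2$cost, 1000 * p$c_fundusphoto + 210 * p$c_examination)
})

test_that("no screening is the identity with zero cost; the gold standard diagnoses everyone", {
  p <- base_params()
  occ <- initial_distribution(p)
  upd <- screening_update(occ, p, "no_screening")
  expect_identical(upd$occupancy, occ)
  expect_equal(upd$cost, 0)

  upd2 <- screening_update(occ, p, "systematic_examination")
  expect_equal(sum(upd2$occupancy[2:4]), 0)
  expect_equal(upd2$occupancy[["MILD_dx"]], 6600)
  expect_equal(upd2$cost, 1e5 * p$c_examination)
})

test_that("opportunistic arms screen the presenting fraction of their eligible states", {
  p <- base_params()  # 1 - p_not_examined = 0.66
  occ <- initial_distribution(p) * 0
  occ[1:4] <- c(1000, 100, 50, 20)
  upd <- screening_update(occ, p, "opportunistic_examination")
  expect_equal(unname(upd$occupancy[6:8]), 0.66 * c(100, 50, 20))
  expect_equal(upd$cost, 0.66 * 1170 * p$c_examination)

  updt <- screening_update(occ, p, "opportunistic_treatment")
  expect_equal(unname(updt$occupancy[6:7]), c(0, 0))   # only severe is symptomatic
  expect_equal(updt$occupancy[["SEV_dx"]], 0.66 * 20)
  expect_equal(updt$cost, 0.66 * 20 * p$c_examination)

  p2 <- base_params(symptomatic_states = c("MOD", "SEV"))
  updt2 <- screening_update(occ, p2, "opportunistic_treatment")
  expect_equal(unname(updt2$occupancy[7:8]), 0.66 * c(50, 20))
})

test_that("screening conserves mass and never un-diagnoses, for every arm", {
  p <- base_params()
  set.seed(421)
  for (rep in 1:5) {
    occ <- stats::setNames(stats::runif(12, 0, 1000), model_states()$name)
    for (s in all_strategy_ids()) {
      upd <- screening_update(occ, p, s)
      expect_equal(sum(upd$occupancy), sum(occ), tolerance = 1e-12)
      expect_true(all(upd$occupancy[5:11] >= occ[5:11] - 1e-12))
      expect_true(all(upd$occupancy[1:4] <= occ[1:4] + 1e-12))
      expect_equal(upd$occupancy[["DEAD"]], occ[["DEAD"]])
      expect_gte(upd$cost, 0)
    }
  }
})

test_that("a perfect photograph reproduces the gold-standard occupancy path", {
  p <- base_params(sens = 1, spec = 1, c_fundusphoto = base_params()$c_examination)
  lt <- fixture_lt()
  a <- run_cohort(p, lt, "systematic_photography")
  b <- run_cohort(p, lt, "systematic_examination")
  occ_cols <- model_states()$name
  expect_equal(a$trace[, occ_cols], b$trace[, occ_cols], tolerance = 1e-12)
  expect_equal(a$result$qaly, b$result$qaly, tolerance = 1e-12)
})

test_that("when nobody presents, opportunistic arms collapse to no screening", {
  p <- base_params(p_not_examined = 1)
  lt <- fixture_lt()
  ref <- run_cohort(p, lt, "no_screening")$result
  for (s in c("opportunistic_examination", "opportunistic_treatment")) {
    res <- run_cohort(p, lt, s)$result
    expect_equal(res$cost, ref$cost, tolerance = 1e-12)
    expect_equal(res$qaly, ref$qaly, tolerance = 1e-12)
  }
})

test_that("unknown strategy ids are rejected", {
  expect_error(screening_update(initial_distribution(base_params()),
                                base_params(), "mail_order"), "unknown strategy")
})
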