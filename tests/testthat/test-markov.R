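test_that("expanded state space has 12 states, death last and absorbing, 3 tunnels", {
  st <- model_states()
  expect_equal(nrow(st), 12)
  expect_equal(st$name[12], "DEAD")
  expect_equal(sum(!is.na(st$tunnel_origin)), 3)
  expect_equal(st$tunnel_origin[!is.na(st$tunnel_origin)],
               c("MILD", "MOD", "SEV"))
  P <- transition_matrix(amd_parameters(), fixture_lt(), age = 70)
  absorbing <- which(diag(P) == 1 & rowSums(P) == 1)
  expect_equal(unname(absorbing), 12L)
})

test_that("initial distribution allocates prevalence to undiagnosed AMD and conserves the cohort", {
  p <- base_params()
  occ <- initial_distribution(p)
  expect_equal(sum(occ[2:4]), 6600)   # 0.066 x 100,000
  expect_equal(occ[["MILD_undx"]], 6600)  # default split: all mild
  expect_equal(sum(occ[5:12]), 0)
  expect_equal(sum(occ), 1e5)

  occ0 <- initial_distribution(base_params(prevalence = 0))
  expect_equal(occ0[["NO_undx"]], 1e5)

  ps <- base_params(prevalence_split = c(mild = 0.5, mod = 0.3, sev = 0.2))
  occs <- initial_distribution(ps)
  expect_equal(unname(occs[2:4]), 6600 * c(0.5, 0.3, 0.2))
  expect_equal(sum(occs), 1e5)
})

test_that("transition matrix composes the base-case rates with age-only mortality", {
  p <- base_params()
  lt <- fixture_lt()
  age <- 55
  q <- annual_death_prob(lt, age)
  P <- transition_matrix(p, lt, age = age)

  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P >= 0))
  # untreated progression at the natural rate
  expect_equal(P["MILD_undx", "MOD_undx"], (1 - q) * 0.0022)
  # treated progression is halved; regression and complication compete
  expect_equal(P["MILD_dx", "MOD_dx"], (1 - q) * 0.0022 * 0.5)
  expect_equal(P["MILD_dx", "NO_dx"], (1 - q) * 0.1)
  expect_equal(P["MILD_dx", "CX_MILD"], (1 - q) * 0.005)
  # tunnels return to their origin
  expect_equal(P["CX_MILD", "MILD_dx"], (1 - q) * 0.4)
  expect_equal(P["CX_MOD", "MOD_dx"], (1 - q) * 0.4)
  # undiagnosed states never regress, never enter tunnels
  expect_equal(unname(P["MILD_undx", c("NO_undx", "CX_MILD")]), c(0, 0))
  # uniform mortality
  expect_true(all(abs(P[1:11, "DEAD"] - q) < 1e-15))
})

test_that("inconsistent parameters that overfill a row are rejected", {
  p <- base_params(p_improve = 0.9, p_tx_comp = 0.2)
  expect_error(transition_matrix(p, fixture_lt(), age = 40), "exceed 1")
})

test_that("closed-form limits: undiscounted healthy immortal cohort accrues horizon x u_no", {
  p <- base_params(discount_rate = 0, prevalence = 0, p_no_to_mild = 0)
  lt <- immortal_lt()
  for (s in all_strategy_ids()) {
    res <- run_cohort(p, lt, s)$result
    expect_equal(res$qaly, 60, tolerance = 1e-12)
  }
  # certain death: exactly one cycle's accrual
  p2 <- base_params()
  lt2 <- lethal_lt()
  expected_qaly <- (1 - 0.066) * p2$u_no + 0.066 * p2$u_mild
  res2 <- run_cohort(p2, lt2, "no_screening")$result
  expect_equal(res2$qaly, expected_qaly, tolerance = 1e-12)
  expect_equal(res2$cost, 0)  # undiagnosed mild carries no cost
})

test_that("cohort traces conserve mass and the dead fraction is monotone, reaching 1", {
  p <- base_params()
  lt <- fixture_lt()
  for (s in all_strategy_ids()) {
    tr <- run_cohort(p, lt, s)$trace
    occ <- as.matrix(tr[, model_states()$name])
    expect_true(all(abs(rowSums(occ) - 1e5) < 1e-6))
    expect_true(all(occ >= -1e-9))
    expect_true(all(diff(tr$DEAD) >= -1e-9))
    expect_equal(tr$DEAD[nrow(tr)], 1e5, tolerance = 1e-9)
  }
})

test_that("any-AMD prevalence among survivors rises under a progression-only chain", {
  co <- run_cohort(base_params(), fixture_lt(), "no_screening")
  pv <- amd_prevalence(co)
  expect_equal(pv$prevalence[1], 0.066, tolerance = 1e-12)
  expect_true(all(diff(pv$prevalence[1:60]) > 0))
})

test_that("treatment with no effect leaves every strategy's QALYs at the no-screening level", {
  p <- base_params(effect_tx = 1, p_improve = 0, p_tx_comp = 0,
                   c_fundusphoto = 0, c_examination = 0)
  lt <- fixture_lt()
  qalys <- vapply(all_strategy_ids(),
                  function(s) run_cohort(p, lt, s)$result$qaly, numeric(1))
  expect_true(all(abs(qalys - qalys[["no_screening"]]) < 1e-9))
})

test_that("systematic examination yields at least the no-screening QALYs at base parameters", {
  p <- base_params()
  lt <- fixture_lt()
  expect_gte(run_cohort(p, lt, "systematic_examination")$result$qaly,
             run_cohort(p, lt, "no_screening")$result$qaly)
})

test_that("microsimulation equals the cohort engine exactly in the deterministic limit", {
  # all transition events have probability 0 or 1: prevalent mild cohort that
  # progresses every year under no treatment, then dies at the cap
  p <- base_params(prevalence = 1, prevalence_split = c(1, 0, 0),
                   p_no_to_mild = 0, p_mild_to_mod = 1, p_mod_to_sev = 1,
                   p_improve = 0, p_tx_comp = 0)
  lt <- immortal_lt()
  det <- run_cohort(p, lt, "no_screening")$result
  ms <- microsim_oracle(p, lt, "no_screening", n_individuals = 50, seed = 3)
  expect_equal(ms$qaly, det$qaly, tolerance = 1e-12)
  expect_equal(ms$cost, det$cost, tolerance = 1e-12)
  expect_equal(ms$se_qaly, 0)
})

test_that("microsimulation standard errors shrink as 1/sqrt(n)", {
  p <- base_params()
  lt <- fixture_lt()
  m1 <- microsim_oracle(p, lt, "no_screening", n_individuals = 1000, seed = 5)
  m2 <- microsim_oracle(p, lt, "no_screening", n_individuals = 4000, seed = 6)
  expect_gt(m1$se_qaly / m2$se_qaly, 1.7)
  expect_lt(m1$se_qaly / m2$se_qaly, 2.3)
})

test_that("microsimulation is bit-identical for a fixed seed", {
  p <- base_params()
  lt <- fixture_lt()
  m1 <- microsim_oracle(p, lt, "systematic_photography", 500, seed = 9)
  m2 <- microsim_oracle(p, lt, "systematic_photography", 500, seed = 9)
  expect_identical(m1, m2)
})
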