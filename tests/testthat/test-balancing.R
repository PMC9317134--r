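# Optimisation-based balancing: weights, QP, LP, generalized slacks.

test_that("weight schemes resolve as documented", {
  sc <- flux_scenario(c(R4 = 2, R10 = 4))
  expect_equal(compute_weights(sc, weight_spec("W2")),
               c(R4 = 0.5, R10 = 0.25))
  expect_equal(unname(compute_weights(sc, weight_spec("W3"))), c(1, 1))
  sc0 <- flux_scenario(c(R4 = 0, R10 = 4))
  expect_equal(compute_weights(sc0, weight_spec("W2")),
               c(R4 = 1e6, R10 = 0.25))
  expect_equal(compute_weights(sc0, weight_spec("W2", pin_zero_rates = TRUE)),
               c(R4 = Inf, R10 = 0.25))
  expect_error(compute_weights(sc, weight_spec("W1")), "variances")
  scv <- flux_scenario(c(R4 = 2, R10 = 4), c(R4 = 0.25, R10 = 0.5))
  expect_equal(compute_weights(scv, weight_spec("W1")),
               c(R4 = 4, R10 = 2))
  expect_error(weight_spec("W2", zero_flux_weight = 10), ">= 1000")
})

test_that("QP balancing matches the printed coupled-pair corrections", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  q3 <- qp_balance(mod, sc, weight_spec("W3"))
  expect_equal(q3$status, "optimal")
  expect_equal(unname(q3$corrected_values), c(3, 3), tolerance = 1e-9)
  expect_equal(q3$objective_value, 2, tolerance = 1e-9)
  expect_true(q3$unique)
  q2 <- qp_balance(mod, sc, weight_spec("W2"))
  expect_equal(unname(q2$corrected_values), c(8 / 3, 8 / 3),
               tolerance = 1e-9)
  # an upper bound bends the optimum away from the algebraic solution
  modb <- metabolic_model(mod$N, mod$reaction_ids, mod$metabolite_ids,
                          lb = c(0, 0), ub = c(2.5, Inf))
  qb <- qp_balance(modb, flux_scenario(c(R4 = 2, R10 = 4), model = modb),
                   weight_spec("W3"))
  expect_equal(unname(qb$corrected_values), c(2.5, 2.5), tolerance = 1e-7)
  expect_equal(unname(qb$deltas), c(-0.5, 1.5), tolerance = 1e-7)
  # feasible input: zero corrections, zero objective
  ok <- qp_balance(mod, flux_scenario(c(R4 = 3, R10 = 3), model = mod))
  expect_equal(max(abs(ok$deltas)), 0, tolerance = 1e-9)
  expect_equal(ok$objective_value, 0, tolerance = 1e-12)
})

test_that("LP balancing reproduces the printed objective and W2 solution", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  l3 <- lp_balance(mod, sc, weight_spec("W3"), check_unique = TRUE)
  expect_equal(l3$objective_value, 2, tolerance = 1e-9)
  v <- unname(l3$corrected_values)
  expect_equal(v[1], v[2], tolerance = 1e-9)
  expect_gte(v[1], 2 - 1e-9); expect_lte(v[1], 4 + 1e-9)
  expect_false(l3$unique)                 # whole face [2,4] is optimal
  l2 <- lp_balance(mod, sc, weight_spec("W2"), check_unique = TRUE)
  expect_equal(unname(l2$corrected_values), c(2, 2), tolerance = 1e-9)
  expect_true(l2$unique)
  # at every optimum one of each slack pair is zero
  expect_equal(unname(pmin(l3$lp_slacks$plus, l3$lp_slacks$minus)),
               c(0, 0), tolerance = 1e-9)
  # feasible scenario: all slacks zero
  ok <- lp_balance(mod, flux_scenario(c(R4 = 3, R10 = 3), model = mod))
  expect_equal(max(ok$lp_slacks$plus, ok$lp_slacks$minus), 0,
               tolerance = 1e-9)
})

test_that("empty fixed set yields empty zero-objective results", {
  mod <- coupled_pair()
  for (res in list(qp_balance(mod, flux_scenario()),
                   lp_balance(mod, flux_scenario()))) {
    expect_equal(res$status, "optimal")
    expect_length(res$deltas, 0)
    expect_equal(res$objective_value, 0)
  }
})

test_that("infeasible base systems are refused with a pointer to slacks", {
  # lb > 0 forces flux, but a general constraint caps it below
  N <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("R1", "R2")))
  mod <- metabolic_model(N, lb = c(2, 0), ub = c(Inf, Inf),
                         A = matrix(c(1, 0), 1, 2), b = 1)
  res <- qp_balance(mod, flux_scenario(c(R1 = 3), model = mod))
  expect_equal(res$status, "infeasible_base")
  expect_match(res$message, "generalized_balance")
  res2 <- lp_balance(mod, flux_scenario(c(R1 = 3), model = mod))
  expect_equal(res2$status, "infeasible_base")
})

test_that("apply_corrections composes by the documented sign conventions", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  q <- qp_balance(mod, sc, weight_spec("W3"))
  sc2 <- apply_corrections(sc, q)
  expect_equal(unname(sc2$fixed), c(3, 3), tolerance = 1e-9)
  expect_equal(sc$fixed, c(R4 = 2, R10 = 4))   # original untouched
  # corrected = f - delta for QP
  expect_equal(sc2$fixed, sc$fixed - q$deltas)
  # corrected = f + d+ - d- for LP
  l <- lp_balance(mod, sc, weight_spec("W2"))
  scl <- apply_corrections(sc, l)
  expect_equal(scl$fixed,
               sc$fixed + l$lp_slacks$plus - l$lp_slacks$minus)
  bad <- q; bad$status <- "solver_failure"
  expect_error(apply_corrections(sc, bad), "solver_failure")
})

test_that("generalized steady-state QP slacks equal the pseudoinverse residual", {
  ch <- chain3(lb = rep(-Inf, 3))
  sc <- flux_scenario(c(R1 = 5, R3 = 7), model = ch)
  g <- generalized_balance(ch, sc, targets = "steady_state", engine = "qp")
  expect_equal(unname(g$constraint_slacks$steady_state), c(-1, -1),
               tolerance = 1e-8)
  expect_equal(unname(g$corrected_values), c(5, 7))  # rates untouched
  r_full <- pinv_full_flux(ch, sc)
  expect_equal(unname(g$constraint_slacks$steady_state),
               unname(drop(ch$N %*% r_full)), tolerance = 1e-8)
  # consistent scenario: all slacks vanish
  g0 <- generalized_balance(ch, flux_scenario(c(R1 = 5, R3 = 5), model = ch),
                            targets = "steady_state", engine = "qp")
  expect_equal(max(abs(g0$constraint_slacks$steady_state)), 0,
               tolerance = 1e-8)
})

test_that("bound-only slacks cannot fix a balance violation and say so", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  expect_error(generalized_balance(mod, sc, targets = "bounds"),
               "malformed|failed even with slacks")
})

test_that("generalized LP slacks repair irreversibility conflicts", {
  # fixed rates force R2 backwards; only a bound slack can allow it
  br <- branch_network()
  sc <- flux_scenario(c(R1 = 2, R2 = 3, R3 = 0), model = br)
  expect_equal(diagnose(br, sc)$consistency, "inconsistent")
  g <- generalized_balance(br, sc, targets = c("steady_state", "bounds"),
                           engine = "lp")
  expect_equal(g$status, "optimal")
  expect_gt(g$objective_value, 0)
})

test_that("scaling all weights scales the objective and keeps the argmin", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  w <- c(R4 = 0.5, R10 = 0.25)
  for (fun in list(qp_balance, lp_balance)) {
    a <- fun(mod, sc, w)
    b <- fun(mod, sc, 7 * w)
    expect_equal(b$corrected_values, a$corrected_values, tolerance = 1e-7)
    expect_equal(b$objective_value, 7 * a$objective_value,
                 tolerance = 1e-7)
  }
})

test_that("enlarging the slack target set never increases the optimum", {
  set.seed(59)
  for (case in 1:6) {
    ss <- random_scenario(seed = 2100 + case, m = 4, n = 9, k = 5,
                          sigma = 0.4, require_redundant = TRUE)
    mod <- ss$model
    sc <- ss$scenario
    obj <- function(model, targets)
      generalized_balance(model, sc, targets = targets,
                          engine = "qp")$objective_value
    # slacking steady state + bounds is always enough on these models
    o1 <- obj(mod, c("steady_state", "bounds"))
    o2 <- obj(mod, c("steady_state", "bounds", "fixed_rates"))
    expect_lte(o2, o1 + 1e-7)
    # with wide bounds, steady-state slacks alone suffice as baseline
    wide <- widen_bounds(mod, 1e6)
    w1 <- obj(wide, "steady_state")
    w2 <- obj(wide, c("steady_state", "bounds"))
    w3 <- obj(wide, c("steady_state", "bounds", "fixed_rates"))
    expect_lte(w2, w1 + 1e-7)
    expect_lte(w3, w2 + 1e-7)
  }
})

test_that("LP optimum is a lower bound on the QP corrections' absolute cost", {
  set.seed(61)
  for (case in 1:8) {
    ss <- random_scenario(seed = 2400 + case, m = sample(3:6, 1),
                          n = sample(8:12, 1), k = 5, sigma = 0.4,
                          require_redundant = TRUE)
    w <- compute_weights(ss$scenario, weight_spec("W1"))
    q <- qp_balance(ss$model, ss$scenario, w)
    l <- lp_balance(ss$model, ss$scenario, w)
    if (q$status != "optimal" || l$status != "optimal") next
    expect_lte(l$objective_value, sum(w * abs(q$deltas)) + 1e-6)
  }
})

test_that("pinned zero rates receive no correction", {
  # branch: R1 = 2, R2 pinned at 0, R3 = 1: only R1/R3 may move
  br <- branch_network()
  sc <- flux_scenario(c(R1 = 2, R2 = 0, R3 = 1), model = br)
  ws <- weight_spec("W2", pin_zero_rates = TRUE)
  for (res in list(qp_balance(br, sc, ws), lp_balance(br, sc, ws))) {
    expect_equal(res$status, "optimal")
    expect_equal(unname(res$corrected_values["R2"]), 0)
    expect_equal(unname(res$corrected_values["R1"]),
                 unname(res$corrected_values["R3"]), tolerance = 1e-8)
  }
})
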