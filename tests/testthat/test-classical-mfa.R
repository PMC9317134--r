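# Classical MFA: partitioning, rank diagnostics, redundancy matrix,
# pseudoinverse solutions and the analytical WLS correction.

test_that("partition splits N into known and unknown blocks", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  p <- partition(mod, sc)
  expect_equal(ncol(p$NU), 0)
  expect_equal(unname(p$NF), matrix(c(1, -1), 1, 2))
  expect_equal(unname(p$z), 2)                 # -(1*2 + (-1)*4)

  p0 <- partition(mod, flux_scenario())
  expect_equal(unname(p0$NU), unname(mod$N))
  expect_equal(unname(p0$z), 0)

  p3 <- partition(chain3(), flux_scenario(c(R1 = 5, R3 = 7), model = chain3()))
  expect_equal(unname(p3$NU), matrix(c(-1, 1), 2, 1))
  expect_equal(p3$ids_U, "R2")
})

test_that("diagnose reproduces the four-class taxonomy on hand cases", {
  mod <- coupled_pair()
  dg <- diagnose(mod, flux_scenario(c(R4 = 2, R10 = 4), model = mod))
  expect_equal(dg$degR, 1)
  expect_equal(dg$determinacy, "determined")
  expect_equal(dg$redundancy, "redundant")
  expect_equal(dg$consistency, "inconsistent")
  expect_equal(unname(dg$residual), -2)
  expect_setequal(dg$redundant_rate_ids, c("R4", "R10"))

  dg0 <- diagnose(mod, flux_scenario())
  expect_equal(dg0$degR, 0)
  expect_equal(dg0$dof, 1)
  expect_equal(dg0$determinacy, "underdetermined")
  expect_equal(dg0$redundancy, "non-redundant")
  expect_equal(dg0$consistency, "consistent")

  ch <- chain3()
  dg2 <- diagnose(ch, flux_scenario(c(R1 = 5, R3 = 7), model = ch))
  expect_equal(dg2$degR, 1)
  expect_equal(dg2$determinacy, "determined")
  expect_equal(dg2$consistency, "inconsistent")

  dg3 <- diagnose(ch, flux_scenario(c(R1 = 5), model = ch))
  expect_equal(dg3$degR, 0)
  expect_equal(dg3$determinacy, "determined")
  expect_equal(dg3$consistency, "consistent")
  expect_setequal(dg3$determined_unknowns, c("R2", "R3"))

  br <- branch_network()
  dg4 <- diagnose(br, flux_scenario(c(R1 = 5), model = br))
  expect_equal(dg4$determinacy, "underdetermined")
  expect_length(dg4$determined_unknowns, 0)
})

test_that("redundancy matrix follows NF - NU NU^+ NF and vanishes when non-redundant", {
  mod <- coupled_pair()
  p <- partition(mod, flux_scenario(c(R4 = 2, R10 = 4), model = mod))
  expect_equal(unname(redundancy_matrix(p)), matrix(c(1, -1), 1, 2))

  ch <- chain3()
  p1 <- partition(ch, flux_scenario(c(R1 = 5), model = ch))
  expect_equal(max(abs(redundancy_matrix(p1))), 0, tolerance = 1e-12)

  p0 <- partition(ch, flux_scenario())
  expect_equal(dim(redundancy_matrix(p0)), c(2, 0))
})

test_that("pseudoinverse solution minimises the residual with minimal norm", {
  ch <- chain3()
  # inconsistent: minimise (5 - r)^2 + (r - 7)^2  ->  r = 6
  r1 <- pseudoinverse_solution(
    partition(ch, flux_scenario(c(R1 = 5, R3 = 7), model = ch)))
  expect_equal(r1, c(R2 = 6))
  # consistent determined: exact
  r2 <- pseudoinverse_solution(
    partition(ch, flux_scenario(c(R1 = 5), model = ch)))
  expect_equal(r2, c(R2 = 5, R3 = 5))
  # fully fixed: empty, not an error
  mod <- coupled_pair()
  r3 <- pseudoinverse_solution(
    partition(mod, flux_scenario(c(R4 = 2, R10 = 4), model = mod)))
  expect_length(r3, 0)
})

test_that("pseudoinverse residual beats 1000 random candidates", {
  set.seed(31)
  for (case in 1:5) {
    ss <- random_scenario(seed = 300 + case, m = 4, n = 9, k = 4, sigma = 0.5)
    p <- partition(ss$model, ss$scenario)
    rU <- unname(pseudoinverse_solution(p))
    res_opt <- sum((p$NU %*% rU - p$z)^2)
    x <- length(rU)
    cands <- matrix(rnorm(1000 * x, 0, 3), 1000, x)
    cand_res <- rowSums((cands %*% t(p$NU) -
                           matrix(p$z, 1000, length(p$z), byrow = TRUE))^2)
    expect_true(all(res_opt <= cand_res + 1e-9))
    # minimal norm among least-squares solutions: perturbing inside the
    # kernel of NU keeps the residual but grows the norm
    K <- fluxbalancer:::nullspace_basis(p$NU)
    if (ncol(K) > 0) {
      pert <- rU + drop(K %*% rnorm(ncol(K)))
      expect_equal(sum((p$NU %*% pert - p$z)^2), res_opt, tolerance = 1e-6)
      expect_gte(sum(pert^2), sum(rU^2) - 1e-9)
    }
  }
})

test_that("degR equals independent rank difference on random models", {
  set.seed(17)
  for (case in 1:20) {
    ss <- random_scenario(seed = 600 + case, m = sample(3:6, 1),
                          n = sample(7:12, 1), k = sample(2:6, 1),
                          sigma = 0.1)
    dg <- ss$diagnosis
    p <- partition(ss$model, ss$scenario)
    # independent oracle: base-R QR rank, not the package SVD path
    qrank <- function(M) if (ncol(M) == 0) 0L else qr(M)$rank
    expect_equal(dg$degR, qrank(ss$model$N) - qrank(p$NU))
    expect_equal(dg$degR, nrow(dg$reduced_redundancy_matrix))
    expect_gte(dg$degR, 0)
    expect_equal(dg$redundancy == "redundant", dg$degR > 0)
    if (dg$redundancy == "non-redundant")
      expect_equal(dg$consistency, "consistent")
  }
})

test_that("algebraic consistency agrees with LP feasibility of the equality system", {
  set.seed(19)
  for (case in 1:15) {
    ss <- random_scenario(seed = 900 + case, m = sample(3:6, 1),
                          n = sample(7:12, 1), k = sample(3:6, 1),
                          sigma = sample(c(0, 0.3), 1))
    mod <- ss$model
    dg <- diagnose(mod, ss$scenario, consistency_tol = 1e-7)
    n <- length(mod$reaction_ids)
    Fidx <- match(names(ss$scenario$fixed), mod$reaction_ids)
    Afix <- matrix(0, length(Fidx), n)
    Afix[cbind(seq_along(Fidx), Fidx)] <- 1
    # pure equality system, bounds removed
    lp <- fluxbalancer:::lp_solve(
      rep(0, n), Aeq = rbind(mod$N, Afix),
      beq = c(rep(0, nrow(mod$N)), unname(ss$scenario$fixed)),
      feas_tol = 1e-7)
    expect_equal(dg$consistency == "consistent", lp$status == "optimal",
                 info = paste("seed", 900 + case))
  }
})

test_that("WLS correction reproduces hand-computed corrections", {
  mod <- coupled_pair()
  sc <- flux_scenario(c(R4 = 2, R10 = 4), model = mod)
  p <- partition(mod, sc); dg <- diagnose(mod, sc)

  w3 <- wls_correction(p, dg, weight_spec("W3"))
  expect_equal(w3$deltas, c(R4 = -1, R10 = 1))
  expect_equal(w3$corrected_values, c(R4 = 3, R10 = 3))

  w2 <- wls_correction(p, dg, weight_spec("W2"))
  expect_equal(unname(w2$corrected_values), c(8 / 3, 8 / 3), tolerance = 1e-12)

  # non-redundant scenario: nothing to correct whatever the weights
  ch <- chain3()
  sc1 <- flux_scenario(c(R1 = 5), model = ch)
  w0 <- wls_correction(partition(ch, sc1), diagnose(ch, sc1),
                       weight_spec("W2"))
  expect_equal(unname(w0$deltas), 0)
})

test_that("WLS corrected rates satisfy Rr (f - delta) = 0 and spare non-redundant rates", {
  set.seed(41)
  for (case in 1:10) {
    ss <- random_scenario(seed = 1200 + case, m = sample(3:6, 1),
                          n = sample(8:14, 1), k = 6, sigma = 0.4,
                          require_redundant = TRUE)
    p <- partition(ss$model, ss$scenario)
    dg <- ss$diagnosis
    res <- wls_correction(p, dg, weight_spec("W1"))
    corrected <- unname(res$corrected_values)
    expect_lt(max(abs(dg$reduced_redundancy_matrix %*% corrected)),
              1e-7 * max(1, max(abs(corrected))))
    non_red <- setdiff(p$ids_F, dg$redundant_rate_ids)
    if (length(non_red))
      expect_lt(max(abs(res$deltas[non_red])), 1e-9)
  }
})

test_that("the WLS correction is invariant to the choice of independent rows", {
  set.seed(43)
  for (case in 1:8) {
    ss <- random_scenario(seed = 1500 + case, m = sample(4:7, 1),
                          n = sample(9:14, 1), k = 7, sigma = 0.4,
                          require_redundant = TRUE)
    p <- partition(ss$model, ss$scenario)
    dg <- ss$diagnosis
    base <- wls_correction(p, dg, weight_spec("W3"))$deltas
    # alternative row basis: random invertible recombination of Rr
    dg2 <- dg
    degR <- dg$degR
    Q <- matrix(rnorm(degR^2), degR)
    while (abs(det(Q)) < 1e-3) Q <- matrix(rnorm(degR^2), degR)
    dg2$reduced_redundancy_matrix <- Q %*% dg$reduced_redundancy_matrix
    alt <- wls_correction(p, dg2, weight_spec("W3"))$deltas
    expect_equal(alt, base, tolerance = 1e-8)
  }
})

test_that("kernel-determined unknowns are a subset of FVA-determined rates", {
  set.seed(47)
  for (case in 1:6) {
    ss <- random_scenario(seed = 1800 + case, m = sample(3:5, 1),
                          n = sample(7:10, 1), k = 4, sigma = 0)
    mod <- ss$model
    dg <- diagnose(mod, ss$scenario)
    fv <- fva(mod, ss$scenario, det_tol = 1e-6, feas_tol = 1e-7)
    expect_true(all(dg$determined_unknowns %in% determined_rates(fv)))
  }
})
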