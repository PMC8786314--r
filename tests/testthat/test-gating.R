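twoState <- function(kPlus = 3, kMinus = 1) {
  buildScheme(list(
    states = list(list(name = "C"), list(name = "O", conducting = TRUE)),
    transitions = list(list(from = "C", to = "O", rate = kPlus),
                       list(from = "O", to = "C", rate = kMinus))))
}

test_that("scheme files build, validate, and expose state classes", {
  two <- twoState()
  expect_identical(nrow(two@states), 2L)
  expect_identical(nrow(two@transitions), 2L)

  for (v in c("preactive", "desensitized")) {
    sch <- buildScheme(exampleScheme(v))
    expect_identical(nrow(sch@states), if (v == "preactive") 10L else 12L)
    expect_identical(sum(sch@states$conducting), 2L)
    expect_setequal(unique(sch@states$class),
                    c("resting", "agonist-bound", "pre-active", "open",
                      "desensitized"))
    expect_identical(sum(sch@states$inhibitorBound),
                     if (v == "preactive") 5L else 6L)
  }

  ## named validation errors
  expect_error(buildScheme(list(
    states = list(list(name = "C")),
    transitions = list(list(from = "C", to = "Z", rate = 1)))), "Z")
  expect_error(buildScheme(list(
    states = list(list(name = "C"), list(name = "O")),
    transitions = list(list(from = "C", to = "O", rate = -1)))), "negative")
  expect_error(buildScheme(list(
    states = list(list(name = "C"), list(name = "O"), list(name = "X")),
    transitions = list(list(from = "C", to = "O", rate = 1),
                       list(from = "O", to = "C", rate = 1)))),
    "disconnected")
})

test_that("generator matrix rows sum to zero with ligand scaling", {
  sch <- buildScheme(exampleScheme("preactive"))
  for (conc in list(c(0, 0), c(0.03, 1e-5))) {
    Q <- generatorMatrix(sch, conc[1], conc[2])
    expect_lt(max(abs(rowSums(Q))), 1e-9)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
  ## agonist scaling: R->A rate equals kon * [A]
  Q <- generatorMatrix(sch, agonist = 0.03)
  expect_equal(Q["R", "A"], 2e4 * 0.03)
  expect_equal(Q["R", "RI"], 0)
})

test_that("steady states match detailed balance and the long-time limit", {
  expect_equal(steadyState(twoState(1, 1)), c(C = 0.5, O = 0.5))
  expect_equal(steadyState(twoState(3, 1)), c(C = 0.25, O = 0.75))

  ## RK4 integration from a non-equilibrium start converges to pi
  sch <- buildScheme(exampleScheme("preactive"))
  pi0 <- steadyState(sch, agonist = 0.03, inhibitor = 1e-5)
  Q <- generatorMatrix(sch, 0.03, 1e-5)
  expect_lt(max(abs(pi0 %*% Q)), 1e-10)           # pi Q = 0 residual
  ev <- eigen(t(Q))$values
  slow <- min(abs(Re(ev[abs(ev) > 1e-9])))
  tEnd <- min(100 / slow, 200)
  p <- rep(1 / 10, 10)
  rec <- lipsite:::.cpp_rk4(p, Q, ceiling(tEnd / 1e-4), 1e-4, 1e6)
  expect_lt(max(abs(rec[nrow(rec), ] - pi0)), 1e-8)
})

test_that("RK4 matches the two-state closed form with 4th-order convergence", {
  kP <- 3; kM <- 1
  sch <- twoState(kP, kM)
  errAt <- function(dt) {
    pr <- methods::new("GatingProtocol", preAgonist = 0, preInhibitor = 0,
                       steps = data.frame(duration = 1, agonist = 0,
                                          inhibitor = 0), dt = dt)
    ## start from pure C (not the steady state): integrate manually
    n <- ceiling(1 / dt)
    rec <- lipsite:::.cpp_rk4(c(1, 0), generatorMatrix(sch), n, dt, 1L)
    t <- (0:n) * dt
    exact <- kP / (kP + kM) * (1 - exp(-(kP + kM) * t))
    max(abs(rec[, 2] - exact))
  }
  e1 <- errAt(1e-2)
  e2 <- errAt(5e-3)
  expect_lt(errAt(1e-5), 1e-8)
  ## halving dt reduces the error ~16x
  expect_equal(e1 / e2, 16, tolerance = 0.25)
})

test_that("protocol integration conserves probability and stays nonnegative", {
  sch <- buildScheme(exampleScheme("preactive"))
  pr <- gatingProtocol(agonist = 0.03, inhibitor = 1e-5, duration = 25,
                       dt = 1e-4)
  trc <- integrateProtocol(sch, pr)
  expect_lt(max(abs(rowSums(trc@prob) - 1)), 1e-9)
  expect_gt(min(trc@prob), -1e-12)
  ## zero agonist throughout: state vector constant at the resting state
  pr0 <- gatingProtocol(agonist = 0, inhibitor = 0, duration = 1, dt = 1e-4)
  trc0 <- integrateProtocol(sch, pr0)
  expect_lt(max(abs(sweep(trc0@prob, 2, trc0@prob[1, ]))), 1e-12)
  ## stepsize guard
  prBad <- gatingProtocol(agonist = 0.03, duration = 1, dt = 1e-2)
  expect_error(integrateProtocol(sch, prBad), "stepsize")
})

test_that("RK4 agrees with matrix-exponential propagation", {
  sch <- buildScheme(exampleScheme("desensitized"))
  p0 <- steadyState(sch, 0, 1e-5)
  times <- c(0.05, 0.2, 1)
  exm <- propagateExpm(sch, p0, agonist = 0.03, inhibitor = 1e-5,
                       times = times)
  pr <- gatingProtocol(agonist = 0.03, inhibitor = 1e-5, duration = 1,
                       dt = 1e-5)
  trc <- integrateProtocol(sch, pr, recordEvery = 1000L)
  for (k in seq_along(times)) {
    idx <- which.min(abs(trc@time - times[k]))
    expect_lt(max(abs(trc@prob[idx, ] - exm[k, ])), 1e-6)
  }
})

test_that("current observables summarize a decaying response", {
  sch <- buildScheme(exampleScheme("preactive"))
  pr <- gatingProtocol(agonist = 0.03, inhibitor = 0, duration = 25,
                       dt = 1e-5)
  trc <- integrateProtocol(sch, pr)
  obs <- currentObservables(trc)
  expect_gt(obs$peak, obs$steady_state)
  expect_equal(obs$ss_peak_ratio, obs$steady_state / obs$peak)
  expect_true(obs$decay_fit %in% c("single", "biexponential"))
  expect_true(is.finite(obs$weighted_tau) && obs$weighted_tau > 0)
  ## current sign convention: inward current is negative
  expect_lt(min(currentOf(trc)), 0)

  ## flat zero trace: observables zero / not applicable
  prRest <- gatingProtocol(agonist = 0, inhibitor = 0, duration = 2,
                           dt = 1e-4)
  obs0 <- currentObservables(integrateProtocol(sch, prRest))
  expect_equal(obs0$peak, 0)
  expect_identical(obs0$decay_fit, "not applicable")
})

test_that("constructed single-exponential trace recovers tau within 1%", {
  ## two-state opening relaxation: decay of P_O after an agonist step off
  tau <- 0.5
  t <- seq(0, 4, by = 0.002)
  y <- 0.6 * exp(-t / tau)
  fit <- fitCurrentDecay(data.frame(time_s = t, current = y))
  expect_equal(fit@tau1, tau, tolerance = 0.01)
  expect_equal(fittedWeightedTau(fit), tau, tolerance = 0.01)
})

test_that("inhibition is monotone and traps the stabilized class", {
  for (v in c("preactive", "desensitized")) {
    sch <- buildScheme(exampleScheme(v))
    grid <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
    obs <- do.call(rbind, lapply(grid, function(ic) {
      pr <- gatingProtocol(agonist = 0.03, inhibitor = ic, duration = 25,
                           dt = 1e-5)
      currentObservables(integrateProtocol(sch, pr))
    }))
    expect_true(all(diff(obs$peak) <= 1e-9))
    ## near-complete inhibition at the top concentration: the stabilized
    ## class dominates every other class at end of step
    top <- obs[nrow(obs), ]
    expect_lt(top$peak / obs$peak[1], 0.12)
    tgt <- if (v == "preactive") top$preactive_final
           else top$desensitized_final
    other <- if (v == "preactive") top$desensitized_final
             else top$preactive_final
    expect_gt(tgt, other)
    expect_gt(tgt, 0.5)
  }
})
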