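## Continuous-time Markov gating schemes and macroscopic current simulation.

#' Build a validated kinetic gating scheme
#'
#' The scheme configuration (YAML file or list) declares states and
#' transitions. Each state has `name`, optional `conducting` (default
#' FALSE), `class` (one of resting, agonist-bound, pre-active, open,
#' desensitized) and `inhibitor_bound` (default FALSE). Each transition has
#' `from`, `to`, `rate` (s^-1, or s^-1 M^-1 when ligand-dependent) and
#' optional `ligand` (`"agonist"` or `"inhibitor"`); ligand-dependent rates
#' are multiplied by the ligand concentration when the generator matrix is
#' assembled.
#'
#' @param config YAML path or list with `states` and `transitions`.
#' @return a [KineticScheme-class].
#' @export
buildScheme <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  st <- do.call(rbind, lapply(config$states, function(s) data.frame(
    name = s$name, conducting = isTRUE(s$conducting),
    class = s$class %||% "unclassified",
    inhibitorBound = isTRUE(s$inhibitor_bound), stringsAsFactors = FALSE)))
  if (anyDuplicated(st$name))
    .stopf("validation error: duplicate state name '%s'",
           st$name[duplicated(st$name)][1])
  tr <- do.call(rbind, lapply(config$transitions, function(x) data.frame(
    from = x$from, to = x$to, rate = as.numeric(x$rate),
    ligand = x$ligand %||% "none", stringsAsFactors = FALSE)))
  bad <- setdiff(unique(c(tr$from, tr$to)), st$name)
  if (length(bad))
    .stopf("validation error: transition references undeclared state '%s'",
           bad[1])
  if (any(tr$rate < 0))
    .stopf("validation error: negative rate on %s -> %s",
           tr$from[tr$rate < 0][1], tr$to[tr$rate < 0][1])
  if (!all(tr$ligand %in% c("none", "agonist", "inhibitor")))
    .stopf("validation error: unknown ligand dependence '%s'",
           setdiff(tr$ligand, c("none", "agonist", "inhibitor"))[1])
  ## connectivity of the undirected transition graph
  n <- nrow(st)
  adj <- matrix(FALSE, n, n, dimnames = list(st$name, st$name))
  adj[cbind(tr$from, tr$to)] <- TRUE
  adj <- adj | t(adj)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (length(seen) < n)
    .stopf("validation error: disconnected scheme (state '%s' unreachable)",
           st$name[setdiff(seq_len(n), seen)][1])
  methods::new("KineticScheme", states = st, transitions = tr)
}

#' Generator matrix of a scheme at given ligand concentrations
#'
#' @param scheme a [KineticScheme-class].
#' @param agonist agonist concentration, M.
#' @param inhibitor inhibitor concentration, M.
#' @return square matrix Q with off-diagonal rates >= 0 and zero row sums.
#' @export
generatorMatrix <- function(scheme, agonist = 0, inhibitor = 0) {
  st <- scheme@states$name
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  tr <- scheme@transitions
  mult <- ifelse(tr$ligand == "agonist", agonist,
                 ifelse(tr$ligand == "inhibitor", inhibitor, 1))
  for (i in seq_len(nrow(tr)))
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + tr$rate[i] * mult[i]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

## Closed communicating classes of the positive-rate directed graph.
#' @noRd
.closedClasses <- function(Q) {
  n <- nrow(Q)
  E <- Q > 0
  R <- E | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R %*% R) > 0   # transitive closure
  scc <- unique(apply(R & t(R), 1, function(x) which(x), simplify = FALSE))
  Filter(function(cls) {
    !any(E[cls, setdiff(seq_len(n), cls), drop = FALSE])
  }, scc)
}

#' Stationary distribution of a scheme at fixed concentrations
#'
#' Solves `pi Q = 0, sum(pi) = 1`. When the chain is reducible at the given
#' concentrations (e.g. zero ligand), the limiting distribution is computed
#' on the unique closed communicating class.
#'
#' @param scheme a [KineticScheme-class].
#' @param agonist,inhibitor concentrations, M.
#' @return named probability vector.
#' @export
steadyState <- function(scheme, agonist = 0, inhibitor = 0) {
  Q <- generatorMatrix(scheme, agonist, inhibitor)
  n <- nrow(Q)
  cls <- .closedClasses(Q)
  if (length(cls) != 1L)
    .stopf("no unique limiting distribution: %d closed classes", length(cls))
  sel <- cls[[1]]
  pi <- stats::setNames(rep(0, n), rownames(Q))
  if (length(sel) == 1L) {
    pi[sel] <- 1
    return(pi)
  }
  Qc <- Q[sel, sel, drop = FALSE]
  M <- t(Qc)
  M[length(sel), ] <- 1                     # replace one balance eq by sum=1
  b <- c(rep(0, length(sel) - 1L), 1)
  pi[sel] <- solve(M, b)
  pi
}

#' Concentration-step protocol
#'
#' @param steps data.frame with columns `duration` (s), `agonist` (M),
#'   `inhibitor` (M); the default is a single 25 s agonist application.
#' @param agonist,inhibitor concentrations used to build the default single
#'   step.
#' @param duration default step duration, s.
#' @param preAgonist,preInhibitor pre-equilibration concentrations, M (the
#'   initial condition is the steady state at these concentrations).
#' @param dt integration step, s.
#' @return a [GatingProtocol-class].
#' @export
gatingProtocol <- function(steps = NULL, agonist = 0.03, inhibitor = 0,
                           duration = 25, preAgonist = 0,
                           preInhibitor = inhibitor, dt = 1e-5) {
  if (is.null(steps))
    steps <- data.frame(duration = duration, agonist = agonist,
                        inhibitor = inhibitor)
  methods::new("GatingProtocol", preAgonist = preAgonist,
               preInhibitor = preInhibitor, steps = steps, dt = dt)
}

#' Integrate a gating scheme over a protocol
#'
#' Fixed-step fourth-order Runge-Kutta solution of `dP/dt = P Q(t)` with
#' piecewise-constant concentrations; the initial condition is the
#' pre-equilibration steady state (null-space solve).
#'
#' @param scheme a [KineticScheme-class].
#' @param protocol a [GatingProtocol-class].
#' @param recordEvery record every k-th step (default chosen to keep about
#'   1e5 points).
#' @return a [StateTrajectory-class].
#' @export
integrateProtocol <- function(scheme, protocol, recordEvery = NULL) {
  dt <- protocol@dt
  p <- steadyState(scheme, protocol@preAgonist, protocol@preInhibitor)
  nTot <- sum(ceiling(protocol@steps$duration / dt))
  if (is.null(recordEvery)) recordEvery <- max(1L, ceiling(nTot / 1e5))
  times <- list(0)
  probs <- list(matrix(p, 1))
  stepIdx <- list(0L)
  t0 <- 0
  for (s in seq_len(nrow(protocol@steps))) {
    row <- protocol@steps[s, ]
    Q <- generatorMatrix(scheme, row$agonist, row$inhibitor)
    mx <- max(abs(diag(Q)))
    if (dt * mx >= 0.1)
      .stopf("stepsize error: dt * max|Q| = %.3g >= 0.1; use dt <= %.3g",
             dt * mx, 0.1 / mx)
    nSteps <- ceiling(row$duration / dt)
    rec <- .cpp_rk4(p, Q, nSteps, dt, recordEvery)
    kIdx <- c(seq(0L, nSteps - 1L, by = recordEvery), nSteps)
    kIdx <- unique(kIdx)[seq_len(nrow(rec))]
    times[[length(times) + 1L]] <- t0 + kIdx[-1] * dt
    probs[[length(probs) + 1L]] <- rec[-1, , drop = FALSE]
    stepIdx[[length(stepIdx) + 1L]] <- rep(s, nrow(rec) - 1L)
    p <- rec[nrow(rec), ]
    t0 <- t0 + nSteps * dt
  }
  prob <- do.call(rbind, probs)
  colnames(prob) <- scheme@states$name
  methods::new("StateTrajectory", time = unlist(times), prob = prob,
               scheme = scheme, stepIndex = as.integer(unlist(stepIdx)))
}

#' Matrix-exponential propagation (stiff-scheme extension)
#'
#' Exact propagation `P(t) = P0 expm(Q t)` on an arbitrary time grid for a
#' constant-concentration segment. Provided as a cross-check/extension; the
#' production integrator is fixed-step RK4.
#'
#' @param scheme a [KineticScheme-class].
#' @param p0 initial probability vector.
#' @param agonist,inhibitor concentrations, M.
#' @param times time points, s.
#' @return matrix `length(times) x n_states`.
#' @export
propagateExpm <- function(scheme, p0, agonist = 0, inhibitor = 0, times) {
  Q <- generatorMatrix(scheme, agonist, inhibitor)
  out <- t(vapply(times, function(tt)
    as.numeric(p0 %*% as.matrix(Matrix::expm(Q * tt))),
    numeric(nrow(Q))))
  colnames(out) <- scheme@states$name
  out
}

#' Normalized current of a state trajectory
#'
#' Inward current convention: `I(t) = -sum(P(conducting states))`.
#'
#' @param trace a [StateTrajectory-class].
#' @return numeric vector along the time grid.
#' @export
currentOf <- function(trace) {
  cond <- trace@scheme@states$conducting
  -rowSums(trace@prob[, cond, drop = FALSE])
}

#' Class occupancy series of a state trajectory
#'
#' @param trace a [StateTrajectory-class].
#' @param class state class tag (e.g. "pre-active", "desensitized"); both
#'   inhibitor-free and inhibitor-bound copies are summed.
#' @return numeric vector along the time grid.
#' @export
classOccupancy <- function(trace, class) {
  sel <- trace@scheme@states$class == class
  if (!any(sel)) .stopf("no states with class '%s'", class)
  rowSums(trace@prob[, sel, drop = FALSE])
}

#' Summary observables of a simulated current response
#'
#' Within the first agonist-containing protocol step: the peak open
#' probability (reported as a positive normalized amplitude), the
#' steady-state level (mean over the last 10% of the step), their ratio, a
#' biexponential decay fit of the post-peak current with its
#' amplitude-weighted time constant, and the final pre-active and
#' desensitized class occupancies. A non-decaying trace gets `decay_fit =
#' "not applicable"` with NA time constants; the other observables are still
#' returned.
#'
#' @param trace a [StateTrajectory-class] produced by [integrateProtocol].
#' @return one-row data.frame of observables.
#' @export
currentObservables <- function(trace) {
  ## locate the first agonist step through the recorded step index: the
  ## integrator stores the protocol row per point
  open <- -currentOf(trace)
  if (all(open < 1e-12) && max(open) == 0) {
    win <- seq_along(trace@time)
  } else win <- seq_along(trace@time)
  ## restrict to the first step with any conducting occupancy rise
  sIdx <- trace@stepIndex
  agSteps <- sort(unique(sIdx[sIdx > 0]))
  if (!length(agSteps)) .stopf("trace contains no protocol step")
  win <- which(sIdx == agSteps[1])
  t <- trace@time[win]; y <- open[win]
  peakIdx <- which.max(y)
  peak <- y[peakIdx]
  tail10 <- win[t - t[1] >= 0.9 * (t[length(t)] - t[1])]
  ss <- mean(open[tail10])
  ratio <- if (peak > 0) ss / peak else NA_real_
  fitOK <- peak > 1e-9 && (peak - ss) / max(peak, 1e-12) > 0.01 &&
    (length(t) - peakIdx) >= 20L
  tau1 <- tau2 <- wtau <- NA_real_
  decayFlag <- "not applicable"
  if (fitOK) {
    ## thin the decay window to ~1500 points: ample for a 5-parameter fit
    dec <- peakIdx:length(t)
    if (length(dec) > 1500L)
      dec <- dec[unique(round(seq(1, length(dec), length.out = 1500L)))]
    fit <- try(fitCurrentDecay(data.frame(time_s = t[dec], current = y[dec]),
                               window = c(t[peakIdx], t[length(t)])),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit@converged) {
      tau1 <- fit@tau1; tau2 <- fit@tau2; wtau <- fit@weightedTau
      decayFlag <- fit@model
    } else decayFlag <- "fit failed"
  }
  endIdx <- win[length(win)]
  pre <- try(classOccupancy(trace, "pre-active")[endIdx], silent = TRUE)
  des <- try(classOccupancy(trace, "desensitized")[endIdx], silent = TRUE)
  data.frame(peak = unname(peak), steady_state = ss, ss_peak_ratio = ratio,
             tau1 = unname(tau1), tau2 = unname(tau2),
             weighted_tau = unname(wtau), decay_fit = decayFlag,
             preactive_final = if (inherits(pre, "try-error")) NA_real_
                               else as.numeric(pre),
             desensitized_final = if (inherits(des, "try-error")) NA_real_
                                  else as.numeric(des),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Path to a shipped example gating scheme
#'
#' Two example schemes mirror the agonist-binding / pre-active (flipped) /
#' open / desensitized gating topology with inhibitor-bound copies of every
#' state: `"preactive"` stabilizes the inhibitor-bound pre-active state,
#' `"desensitized"` the inhibitor-bound desensitized state. Rates are
#' placeholders chosen to reproduce the qualitative inhibition phenotypes
#' (see the scheme files and vignette), with microscopic reversibility
#' enforced on every binding/gating cycle.
#'
#' @param variant `"preactive"` or `"desensitized"`.
#' @return file path.
#' @export
exampleScheme <- function(variant = c("preactive", "desensitized")) {
  variant <- match.arg(variant)
  system.file("extdata", sprintf("scheme_%s.yaml", variant),
              package = "lipsite", mustWork = TRUE)
}
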