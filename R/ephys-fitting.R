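## Current-decay and dose-response fitting.

#' Amplitude-weighted time constant
#'
#' `weightedTau = (A1*tau1 + A2*tau2) / (A1 + A2)`.
#'
#' @param A1,A2 component amplitudes.
#' @param tau1,tau2 component time constants, s (must be > 0).
#' @return weighted time constant, s.
#' @export
weightedTau <- function(A1, tau1, A2, tau2) {
  if (any(c(tau1, tau2) <= 0, na.rm = TRUE))
    .stopf("time constants must be positive")
  if (A1 + A2 == 0) .stopf("undefined weighted tau: A1 + A2 = 0")
  unname((A1 * tau1 + A2 * tau2) / (A1 + A2))
}

## single- and biexponential residual models
#' @noRd
.expModel1 <- function(t, p) p[1] * exp(-t / p[2]) + p[3]
#' @noRd
.expModel2 <- function(t, p) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) +
  p[5]

#' Fit a current decay with a (bi)exponential
#'
#' Nonlinear least squares of `I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) + C`
#' over the requested window, with multi-start initialization (log-spaced
#' time-constant grid spanning the window). When the biexponential does not
#' improve the residual sum of squares over a single exponential by at least
#' `improveFactor`, the single-exponential fit is returned (`A2 = 0`).
#'
#' @param trace data.frame with columns `time_s` and `current`.
#' @param window length-2 numeric `(t_start, t_end)`; default the full trace.
#' @param improveFactor minimum RSS improvement ratio required to accept the
#'   biexponential over the single exponential (default 1.5).
#' @return a [DecayFit-class]; non-convergence is flagged with best-effort
#'   parameters rather than an error.
#' @export
fitCurrentDecay <- function(trace, window = NULL, improveFactor = 1.5) {
  stopifnot(all(c("time_s", "current") %in% names(trace)))
  if (is.null(window)) window <- range(trace$time_s)
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  t <- trace$time_s[sel] - window[1]
  y <- trace$current[sel]
  if (length(t) < 20L) .stopf("need at least 20 samples in the fit window")
  amp0 <- y[1] - y[length(y)]
  scale <- max(abs(y), 1e-12)
  failed <- function() methods::new("DecayFit", A1 = amp0, tau1 = NA_real_,
                                    A2 = 0, tau2 = NA_real_,
                                    offset = y[length(y)],
                                    weightedTau = NA_real_, rss = Inf,
                                    converged = FALSE, model = "single")
  if (stats::sd(y) < 1e-12 * scale || abs(amp0) < 1e-10 * scale)
    return(failed())

  span <- max(t)
  tauGrid <- exp(seq(log(span / 200), log(span * 2), length.out = 8))
  bestFit <- function(kind) {
    best <- NULL
    starts <- if (kind == "single") {
      lapply(tauGrid, function(tau) c(A1 = amp0, tau1 = tau,
                                      C = y[length(y)]))
    } else {
      out <- list()
      for (i in seq_along(tauGrid)) for (j in seq_along(tauGrid))
        if (i < j) out[[length(out) + 1L]] <-
          c(A1 = amp0 * 0.6, tau1 = tauGrid[i], A2 = amp0 * 0.4,
            tau2 = tauGrid[j], C = y[length(y)])
      out
    }
    fn <- if (kind == "single") function(p) y - .expModel1(t, p)
          else function(p) y - .expModel2(t, p)
    lowerTau <- span * 1e-5
    for (st in starts) {
      fit <- try(minpack.lm::nls.lm(
        par = st, fn = fn,
        lower = if (kind == "single") c(-Inf, lowerTau, -Inf)
                else c(-Inf, lowerTau, -Inf, lowerTau, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(par = fit$par, rss = rss,
                     ok = fit$info %in% 1:4)
    }
    best
  }

  s1 <- bestFit("single")
  if (is.null(s1)) return(failed())
  ## a numerically perfect single fit needs no second component
  tinyRSS <- (1e-8 * scale)^2 * length(y)
  if (s1$rss > tinyRSS) {
    s2 <- bestFit("biexp")
  } else s2 <- NULL
  useBi <- !is.null(s2) && s2$rss * improveFactor < s1$rss &&
    s2$rss < s1$rss - tinyRSS
  if (useBi) {
    p <- s2$par
    ## order components by time constant
    if (p[2] > p[4]) p <- p[c(3, 4, 1, 2, 5)]
    methods::new("DecayFit", A1 = unname(p[1]), tau1 = unname(p[2]),
                 A2 = unname(p[3]), tau2 = unname(p[4]), offset = unname(p[5]),
                 weightedTau = weightedTau(p[1], p[2], p[3], p[4]),
                 rss = s2$rss, converged = s2$ok, model = "biexponential")
  } else {
    p <- s1$par
    methods::new("DecayFit", A1 = unname(p[1]), tau1 = unname(p[2]), A2 = 0,
                 tau2 = NA_real_, offset = unname(p[3]),
                 weightedTau = unname(p[2]), rss = s1$rss,
                 converged = s1$ok, model = "single")
  }
}

#' Fit a Hill activation curve with fixed slope
#'
#' Least-squares fit of `R = Rmax * [A]^n / ([A]^n + EC50^n)` with the Hill
#' coefficient fixed (default n = 2, the convention for this channel's
#' agonist responses).
#'
#' @param doses agonist concentrations, M.
#' @param responses peak responses (any consistent units).
#' @param hillN fixed Hill coefficient (default 2).
#' @return a [DoseResponseFit-class].
#' @export
fitHillEC50 <- function(doses, responses, hillN = 2) {
  stopifnot(length(doses) == length(responses))
  ord <- order(doses)
  doses <- doses[ord]; responses <- responses[ord]
  if (length(doses) < 4L) .stopf("need at least 4 dose points")
  if (stats::sd(responses) < 1e-12 * max(abs(responses), 1e-300))
    .stopf("unidentifiable fit: responses do not vary")
  half <- max(responses) / 2
  ec0 <- doses[which.min(abs(responses - half))]
  fn <- function(p) responses - p[1] * doses^hillN /
    (doses^hillN + p[2]^hillN)
  fit <- minpack.lm::nls.lm(par = c(rmax = max(responses), ec50 = ec0),
                            fn = fn, lower = c(0, .Machine$double.xmin),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["ec50"]],
                 error = function(e) NA_real_)
  methods::new("DoseResponseFit", ec50 = unname(fit$par[["ec50"]]),
               ec50SE = se, hill = hillN, rmax = unname(fit$par[["rmax"]]),
               kind = "EC50", rss = sum(fit$fvec^2),
               data = data.frame(conc = doses, response = responses))
}

#' Fit a sigmoidal inhibition curve
#'
#' Least-squares fit of `y = 1 / (1 + ([I]/IC50)^h)` to control-normalized
#' peak responses; the floor is fixed at 0 and the top at 1 (configurable
#' slope).
#'
#' @param doses inhibitor concentrations, M.
#' @param normalizedPeaks responses normalized to control (= 1).
#' @param hillN `NULL` (default) to fit the slope freely, or a fixed value.
#' @return a [DoseResponseFit-class].
#' @export
fitIC50 <- function(doses, normalizedPeaks, hillN = NULL) {
  stopifnot(length(doses) == length(normalizedPeaks))
  ord <- order(doses)
  doses <- doses[ord]; y <- normalizedPeaks[ord]
  if (min(y) > 0.8)
    .stopf("unidentifiable fit: no inhibition in the data")
  pos <- doses > 0
  ic0 <- doses[pos][which.min(abs(y[pos] - 0.5))]
  if (is.null(hillN)) {
    fn <- function(p) y - 1 / (1 + (doses / p[1])^p[2])
    fit <- minpack.lm::nls.lm(par = c(ic50 = ic0, h = 1), fn = fn,
                              lower = c(.Machine$double.xmin, 0.05),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    h <- unname(fit$par[["h"]])
  } else {
    fn <- function(p) y - 1 / (1 + (doses / p[1])^hillN)
    fit <- minpack.lm::nls.lm(par = c(ic50 = ic0), fn = fn,
                              lower = .Machine$double.xmin,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    h <- hillN
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["ic50"]],
                 error = function(e) NA_real_)
  methods::new("DoseResponseFit", ec50 = unname(fit$par[["ic50"]]),
               ec50SE = se, hill = h, rmax = 1, kind = "IC50",
               rss = sum(fit$fvec^2),
               data = data.frame(conc = doses, response = y))
}
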