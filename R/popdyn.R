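## Discrete-time, density-independent, frequency-dependent projection
## of the four classes ZZ male / intersex / WZ female / WW female.

## newborn distribution given sire/dam class frequencies u = P(sire WZ),
## v = P(dam WW); shared by the step operator and the direct solver
.newbornFromUV <- function(u, v, alpha) {
  pZZ <- (1 - v) * (2 - u) / 4
  pWW <- u * (1 + v) / 4
  pWZ <- 1 - pZZ - pWW
  c(ZZ_MALE = pZZ, IS = alpha * pWZ,
    WZ_FEMALE = (1 - alpha) * pWZ, WW_FEMALE = pWW)
}

#' Class distribution of newborns given the current population
#'
#' Sires are drawn proportional to male-class abundances (ZZ males and
#' intersex WZ males are equally fertile) and dams proportional to
#' female-class abundances; the offspring genotype distribution is the
#' corresponding mixture of the four cross tables, partitioned into
#' classes with \code{alpha}.  With no functional males or no females
#' recruitment is impossible and an all-zero distribution is returned.
#'
#' @param state Named abundance vector (see
#'   \code{\link{populationState}}).
#' @param alpha Intersex-emergence fraction in [0, 1].
#' @return Named numeric vector over \code{phenotypeClassLevels()}
#'   summing to 1, or to 0 when recruitment is impossible.
#' @examples
#' newbornClassDistribution(populationState(IS = 100, WZ = 100), alpha = 0)
#' @export
newbornClassDistribution <- function(state, alpha) {
  state <- .checkState(state)
  .checkProb(alpha, "alpha")
  M <- state[["ZZ"]] + state[["IS"]]
  F <- state[["WZ"]] + state[["WW"]]
  if (M <= 0 || F <= 0)
    return(setNames(numeric(4), phenotypeClassLevels()))
  .newbornFromUV(state[["IS"]] / M, state[["WW"]] / F, alpha)
}

## recruits enter the adult classes directly (one-step maturation)
.recruitVector <- function(p) {
  setNames(as.numeric(p[phenotypeClassLevels()]), .stateLevels())
}

#' One projection step
#'
#' \code{projectStep} applies the density-independent recurrence
#' \eqn{N'_k = \sigma_a N_k + \sigma_0 \phi F p_k}, where \eqn{F} is
#' the total number of functional females (WZ + WW) and \eqn{p} the
#' newborn class distribution.  \code{constantPopulationStep} is the
#' constant-size variant in which exactly the \eqn{(1-\sigma_a) N}
#' adults that die are replaced by recruits, conserving total
#' abundance; both variants share the same structural fixed point.
#'
#' @param state Named abundance vector.
#' @param params A \code{\link{DemographicParams}}.
#' @return The next state (named numeric vector).
#' @examples
#' projectStep(populationState(ZZ = 100, WZ = 100), DemographicParams())
#' @export
projectStep <- function(state, params) {
  stopifnot(is(params, "DemographicParams"))
  state <- .checkState(state)
  F <- state[["WZ"]] + state[["WW"]]
  p <- newbornClassDistribution(state, params@alpha)
  params@sigmaA * state +
    params@sigma0 * params@phi * F * .recruitVector(p)
}

#' @rdname projectStep
#' @export
constantPopulationStep <- function(state, params) {
  stopifnot(is(params, "DemographicParams"))
  state <- .checkState(state)
  N <- sum(state)
  if (N <= 0) stop("total population must be positive", call. = FALSE)
  p <- newbornClassDistribution(state, params@alpha)
  recruits <- if (sum(p) > 0) (1 - params@sigmaA) * N * .recruitVector(p)
              else setNames(numeric(4), .stateLevels())
  params@sigmaA * state + recruits
}

#' Simulate a population trajectory
#'
#' Repeats \code{\link{projectStep}} for \code{nSteps} steps.  In
#' stochastic mode, survivors of each class are binomial with
#' probability \code{sigmaA}, the number of recruits is Poisson with
#' mean \code{sigma0 * phi} per female, and recruit classes are
#' multinomial from the newborn class distribution; a run whose total
#' reaches zero is truncated and flagged extinct.
#'
#' @param initial Named abundance vector (integers in stochastic mode).
#' @param params A \code{\link{DemographicParams}}.
#' @param nSteps Number of steps (>= 1).
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param seed Optional integer seed (stochastic mode).
#' @return A \code{\link[=Trajectory-class]{Trajectory}}.
#' @examples
#' tr <- simulateTrajectory(populationState(IS = 100, WZ = 100),
#'                          DemographicParams(), nSteps = 10)
#' head(as.data.frame(tr))
#' @export
simulateTrajectory <- function(initial, params, nSteps,
                               mode = c("deterministic", "stochastic"),
                               seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(params, "DemographicParams"), nSteps >= 1)
  state <- .checkState(initial)
  if (!is.null(seed)) withr::local_seed(seed)
  states <- matrix(NA_real_, nrow = nSteps + 1L, ncol = 4L,
                   dimnames = list(NULL, .stateLevels()))
  states[1L, ] <- state
  lambda <- numeric(0)
  extinct <- FALSE
  for (t in seq_len(nSteps)) {
    nxt <- if (mode == "deterministic") {
      projectStep(state, params)
    } else {
      .stochasticStep(state, params)
    }
    lambda <- c(lambda, if (sum(state) > 0) sum(nxt) / sum(state) else NA_real_)
    states[t + 1L, ] <- nxt
    state <- nxt
    if (mode == "stochastic" && sum(state) == 0) {
      states <- states[seq_len(t + 1L), , drop = FALSE]
      extinct <- TRUE
      break
    }
  }
  new("Trajectory", states = states, lambda = lambda, params = params,
      mode = mode, extinct = extinct,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.stochasticStep <- function(state, params) {
  survivors <- vapply(state, function(n)
    as.numeric(rbinom(1L, round(n), params@sigmaA)), numeric(1))
  F <- round(state[["WZ"]] + state[["WW"]])
  p <- newbornClassDistribution(state, params@alpha)
  recruits <- setNames(numeric(4), .stateLevels())
  if (F > 0 && sum(p) > 0) {
    nNew <- rpois(1L, F * params@sigma0 * params@phi)
    if (nNew > 0)
      recruits <- .recruitVector(
        setNames(as.numeric(rmultinom(1L, nNew, p)), names(p)))
  }
  survivors + recruits
}

#' Long-term stable distribution (LTSD)
#'
#' The asymptotic class fractions of the projection model, which are a
#' function of \code{alpha} alone (the survival and fecundity
#' parameters only shape transients and the growth rate).  Method
#' \code{"iterate"} iterates the projection from ZZ = WZ = 50\% until
#' the largest class-fraction change drops below \code{tol}; method
#' \code{"solve"} solves the newborn-fraction fixed-point equations
#' directly (reduction to one scalar root in the sire-class frequency),
#' serving as an independent check of the iterative route.
#'
#' @param alpha Intersex-emergence fraction in [0, 1].
#' @param params A \code{\link{DemographicParams}} (its alpha is
#'   overridden by \code{alpha}).
#' @param tol Convergence tolerance on class fractions.
#' @param maxIter Iteration cap; exceeding it is an error.
#' @param method \code{"iterate"} or \code{"solve"}.
#' @return A \code{\link[=StableDistribution-class]{StableDistribution}}.
#' @examples
#' stableDistribution(alpha = 0.04)
#' @export
stableDistribution <- function(alpha = 0.04, params = DemographicParams(),
                               tol = 1e-10, maxIter = 10000L,
                               method = c("iterate", "solve")) {
  method <- match.arg(method)
  .checkProb(alpha, "alpha")
  stopifnot(tol > 0)
  params@alpha <- alpha
  lambdaInf <- function(f) params@sigmaA +
    params@sigma0 * params@phi * (f[["WZ"]] + f[["WW"]])
  if (method == "solve") {
    f <- .solveLTSD(alpha)
    return(new("StableDistribution", fractions = f, lambda = lambdaInf(f),
               iterations = 0L, method = method, alpha = alpha))
  }
  frac <- populationState(ZZ = 0.5, WZ = 0.5)
  for (i in seq_len(maxIter)) {
    nxt <- projectStep(frac, params)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - frac)) < tol)
      return(new("StableDistribution", fractions = nxt,
                 lambda = lambdaInf(nxt), iterations = i,
                 method = method, alpha = alpha))
    frac <- nxt
  }
  stop("LTSD iteration did not converge within ", maxIter, " steps",
       call. = FALSE)
}

## direct fixed point: at equilibrium the class fractions equal the
## newborn distribution, so with u = P(sire is WZ), v = P(dam is WW),
## A = P(ZZ) = (1-v)(2-u)/4, C = P(WW) = u(1+v)/4, B = 1-A-C:
##   u (A + alpha B) = alpha B  and  v ((1-alpha) B + C) = C.
## Eliminating v gives v(u) = alpha(1-u) / [(1-alpha)(2-u) - alpha(1-u)];
## the remaining scalar equation in u is solved by uniroot.
.solveLTSD <- function(alpha) {
  if (alpha == 0) return(populationState(ZZ = 0.5, WZ = 0.5))
  vOf <- function(u) alpha * (1 - u) /
    ((1 - alpha) * (2 - u) - alpha * (1 - u))
  res <- function(u) {
    v <- vOf(u)
    A <- (1 - v) * (2 - u) / 4
    C <- u * (1 + v) / 4
    B <- 1 - A - C
    u * (A + alpha * B) - alpha * B
  }
  ## the elimination is only meaningful where v(u) lies in [0, 1]
  ## (for large alpha that region starts above u = 0); bracket there
  grid <- seq(1e-8, 1 - 1e-8, length.out = 2001)
  ok <- vapply(grid, function(u) {
    v <- vOf(u); is.finite(v) && v >= 0 && v <= 1
  }, logical(1))
  grid <- grid[ok]
  vals <- vapply(grid, res, numeric(1))
  flip <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
  if (is.na(flip))
    stop("fixed-point solve failed to bracket a root", call. = FALSE)
  u <- uniroot(res, grid[c(flip, flip + 1L)], tol = 1e-15)$root
  v <- vOf(u)
  p <- .newbornFromUV(u, v, alpha)
  .recruitVector(p)
}

#' Generations until the class structure stabilises
#'
#' Iterates the deterministic projection from \code{initial} and
#' returns the first step at which every class fraction is within
#' \code{tolPP} percentage points of the alpha-LTSD, together with the
#' equivalent in years (\code{stepMonths / 12} years per step).
#'
#' @param initial Named abundance vector.
#' @param params A \code{\link{DemographicParams}}.
#' @param tolPP Tolerance in percentage points (> 0), default 0.1.
#' @param maxIter Step cap; exceeding it is an error.
#' @return List with elements \code{generations} and \code{years}.
#' @examples
#' generationsToConvergence(populationState(ZZ = 0.5, WZ = 0.5),
#'                          DemographicParams())
#' @export
generationsToConvergence <- function(initial, params, tolPP = 0.1,
                                     maxIter = 10000L) {
  stopifnot(is(params, "DemographicParams"), tolPP > 0)
  target <- classFractions(stableDistribution(params@alpha,
                                              method = "solve"))
  state <- .checkState(initial)
  for (t in 0:maxIter) {
    frac <- state / sum(state)
    if (max(abs(frac - target)) < tolPP / 100)
      return(list(generations = t,
                  years = t * params@stepMonths / 12))
    state <- projectStep(state, params)
  }
  stop("class fractions did not come within ", tolPP,
       " pp of the LTSD in ", maxIter, " steps", call. = FALSE)
}

#' Time for the population to reach a size threshold
#'
#' First step at which total abundance reaches or exceeds
#' \code{nTarget} under the deterministic projection.
#'
#' @param initial Named abundance vector.
#' @param params A \code{\link{DemographicParams}}.
#' @param nTarget Threshold population size.
#' @param maxIter Step cap; a population that has not reached the
#'   target within it raises an error (non-growing populations never
#'   will).
#' @return Integer step count (0 if already at or above target).
#' @examples
#' timeToThreshold(populationState(IS = 100, WZ = 100),
#'                 DemographicParams(), nTarget = 1000)
#' @export
timeToThreshold <- function(initial, params, nTarget, maxIter = 10000L) {
  stopifnot(is(params, "DemographicParams"), nTarget > 0)
  state <- .checkState(initial)
  for (t in 0:maxIter) {
    if (sum(state) >= nTarget) return(t)
    nxt <- projectStep(state, params)
    if (sum(nxt) <= sum(state) && sum(nxt) < nTarget && t > 0 &&
        params@sigmaA + 0.5 * params@sigma0 * params@phi <= 1)
      stop("population is not growing (lambda_inf <= 1) and will not ",
           "reach ", nTarget, call. = FALSE)
    state <- nxt
  }
  stop("population did not reach ", nTarget, " within ", maxIter,
       " steps", call. = FALSE)
}

#' Estimate alpha from the intersex fraction of a cohort
#'
#' Near the long-term stable distribution the intersex class fraction
#' is about half of alpha, so \eqn{\hat\alpha = 2 \times} the observed
#' intersex fraction.  (The exact coefficient is the stable
#' WZ-genotype fraction, about 0.51 for small alpha.)
#'
#' @param isFraction Observed intersex fraction(s), each in [0, 0.5].
#' @return Estimated alpha value(s).
#' @examples
#' estimateAlphaFromCohort(0.0204)
#' @export
estimateAlphaFromCohort <- function(isFraction) {
  if (any(is.na(isFraction)) || any(isFraction < 0) ||
      any(isFraction > 0.5))
    stop("isFraction must be in [0, 0.5]: at the stable distribution ",
         "the intersex fraction cannot exceed half the population",
         call. = FALSE)
  2 * isFraction
}
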