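## S4 classes for the projection model, test results and tag matrices.

#' Demographic parameters of the four-class projection model
#'
#' Holds the parameters of the discrete-time, density-independent
#' model: the intersex-emergence fraction \code{alpha} (fraction of WZ
#' progeny emerging as intersex functional males), newborn survival
#' \code{sigma0}, per-step adult survival \code{sigmaA}, per-capita
#' female fecundity \code{phi} (offspring per female per step) and the
#' step length in months (one step is one generation, about 6 months).
#' Recruitment per female per step is \code{sigma0 * phi}; adult life
#' expectancy is \code{1 / (-log(sigmaA))} steps.
#'
#' @slot alpha,sigma0,sigmaA,phi,stepMonths Numeric scalars; see
#'   Description.
#' @export
setClass("DemographicParams",
         representation(alpha = "numeric", sigma0 = "numeric",
                        sigmaA = "numeric", phi = "numeric",
                        stepMonths = "numeric"))

setValidity("DemographicParams", function(object) {
  msg <- character()
  for (s in c("alpha", "sigma0", "sigmaA", "phi", "stepMonths"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, paste0(s, " must be a single non-NA number"))
  if (length(msg)) return(msg)
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must be in [0, 1]")
  if (object@sigma0 < 0 || object@sigma0 > 1) msg <- c(msg, "sigma0 must be in [0, 1]")
  if (object@sigmaA < 0 || object@sigmaA > 1) msg <- c(msg, "sigmaA must be in [0, 1]")
  if (object@phi < 0) msg <- c(msg, "phi must be >= 0")
  if (object@stepMonths <= 0) msg <- c(msg, "stepMonths must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn DemographicParams-class Constructor.  Defaults are the
#'   declared model configuration: alpha = 0.04, sigmaA = 0.6 and
#'   sigma0 * phi = 1.2 (net recruitment), giving an asymptotic growth
#'   rate of about 1.2 per step.
#' @param alpha,sigma0,sigmaA,phi,stepMonths See slot descriptions.
#' @examples
#' DemographicParams()
#' @export
DemographicParams <- function(alpha = 0.04, sigma0 = 1, sigmaA = 0.6,
                              phi = 1.2, stepMonths = 6) {
  new("DemographicParams", alpha = alpha, sigma0 = sigma0,
      sigmaA = sigmaA, phi = phi, stepMonths = stepMonths)
}

#' Population state vector
#'
#' Abundances of the four functional classes as a named numeric vector
#' in class order \code{ZZ} (ZZ males), \code{IS} (intersex WZ males),
#' \code{WZ} (WZ females), \code{WW} (WW females).
#'
#' @param ZZ,IS,WZ,WW Nonnegative abundances.
#' @return Named numeric vector of length 4.
#' @examples
#' populationState(ZZ = 100, WZ = 100)
#' @export
populationState <- function(ZZ = 0, IS = 0, WZ = 0, WW = 0) {
  st <- c(ZZ = as.numeric(ZZ), IS = as.numeric(IS),
          WZ = as.numeric(WZ), WW = as.numeric(WW))
  .checkState(st)
}

.checkState <- function(state) {
  if (is.null(names(state)) || !all(.stateLevels() %in% names(state)))
    stop("state must be named with classes ZZ, IS, WZ, WW", call. = FALSE)
  state <- state[.stateLevels()]
  if (anyNA(state) || any(state < 0))
    stop("class abundances must be nonnegative and non-NA", call. = FALSE)
  state
}

#' Trajectory of the projection model
#'
#' Stores the sequence of population states produced by
#' \code{\link{simulateTrajectory}}: a (steps + 1) x 4 matrix of class
#' abundances (row 0 is the initial state), the per-step finite growth
#' rates \eqn{\lambda_t = N_{t+1}/N_t}, the parameters used, the mode,
#' and whether a stochastic run went extinct (truncating the run).
#'
#' @slot states Numeric matrix, one row per time step.
#' @slot lambda Numeric vector of finite growth rates.
#' @slot params A \code{DemographicParams}.
#' @slot mode \code{"deterministic"} or \code{"stochastic"}.
#' @slot extinct Logical flag.
#' @slot seed Integer seed used (NA for deterministic runs).
#' @export
setClass("Trajectory",
         representation(states = "matrix", lambda = "numeric",
                        params = "DemographicParams", mode = "character",
                        extinct = "logical", seed = "integer"))

setValidity("Trajectory", function(object) {
  if (ncol(object@states) != 4L ||
      !identical(colnames(object@states), .stateLevels()))
    return("states must have columns ZZ, IS, WZ, WW")
  if (any(object@states < 0)) return("abundances must be nonnegative")
  if (length(object@lambda) != nrow(object@states) - 1L)
    return("lambda must have one entry per transition")
  TRUE
})

#' Long-term stable distribution of the four classes
#'
#' The asymptotic class fractions of the projection model, which
#' depend only on the intersex-emergence fraction alpha, together with
#' the asymptotic per-step growth rate and the number of iterations
#' used (0 for the direct fixed-point solve).
#'
#' @slot fractions Named numeric vector over ZZ/IS/WZ/WW, summing to 1.
#' @slot lambda Asymptotic finite growth rate.
#' @slot iterations Integer iteration count.
#' @slot method \code{"iterate"} or \code{"solve"}.
#' @slot alpha The alpha the distribution belongs to.
#' @export
setClass("StableDistribution",
         representation(fractions = "numeric", lambda = "numeric",
                        iterations = "integer", method = "character",
                        alpha = "numeric"))

setValidity("StableDistribution", function(object) {
  f <- object@fractions
  if (!identical(names(f), .stateLevels()))
    return("fractions must be named ZZ, IS, WZ, WW")
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9)
    return("fractions must be nonnegative and sum to 1")
  TRUE
})

#' Goodness-of-fit result for a segregation ratio
#'
#' Observed and expected category counts, the uncorrected chi-square
#' statistic, its degrees of freedom (categories - 1) and the upper
#' tail p-value.
#'
#' @slot observed,expected Numeric count vectors (equal totals).
#' @slot ratio The null ratio weights tested.
#' @slot statistic,df,pValue Test statistic, degrees of freedom and
#'   p-value.
#' @export
setClass("GofResult",
         representation(observed = "numeric", expected = "numeric",
                        ratio = "numeric", statistic = "numeric",
                        df = "integer", pValue = "numeric"))

setValidity("GofResult", function(object) {
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-9)
    return("observed and expected totals must match")
  if (object@statistic < 0) return("chi-square statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("p must be in [0, 1]")
  if (object@df != length(object@observed) - 1L)
    return("df must equal categories - 1")
  TRUE
})

#' Cohort summary
#'
#' Phenotype counts, female:male ratio, and genotype counts among
#' genotyped females (WZ vs WW) for one site or a whole cohort, in the
#' reporting style of field tables: integer-rounded "k:1" ratio labels
#' alongside the exact quotients, and the WW percentage at two
#' decimals.
#'
#' @slot site Site label ("" for all sites pooled).
#' @slot phenotypeCounts Named integer vector (male/female/intersex).
#' @slot fmRatio Exact female:male quotient (NA when no males).
#' @slot fmRatioLabel Display label such as \code{"3:1"} (or
#'   \code{"-"}).
#' @slot genotypeCounts Named integer vector (WZ/WW) among genotyped
#'   females.
#' @slot wzWwRatio,wzWwRatioLabel WZ:WW quotient and label.
#' @slot wwPercent Percent of WW among genotyped females, 2 decimals.
#' @slot nExcluded Number of females without a determined genotype.
#' @export
setClass("CohortSummary",
         representation(site = "character", phenotypeCounts = "integer",
                        fmRatio = "numeric", fmRatioLabel = "character",
                        genotypeCounts = "integer", wzWwRatio = "numeric",
                        wzWwRatioLabel = "character", wwPercent = "numeric",
                        nExcluded = "integer"))

## ---- show methods -------------------------------------------------

setMethod("show", "DemographicParams", function(object) {
  cat("DemographicParams: alpha =", object@alpha,
      "| sigma0 =", object@sigma0, "| sigmaA =", object@sigmaA,
      "| phi =", object@phi, "| step =", object@stepMonths, "months\n")
  cat("  net recruitment sigma0*phi =", object@sigma0 * object@phi,
      "; adult life expectancy =",
      signif(adultLifeExpectancy(object), 4), "steps\n")
})

setMethod("show", "Trajectory", function(object) {
  n <- nrow(object@states) - 1L
  cat("Trajectory:", n, "steps (", object@mode, ")",
      if (object@extinct) "[EXTINCT]" else "", "\n")
  cat("  initial N =", sum(object@states[1L, ]),
      "-> final N =", signif(sum(object@states[nrow(object@states), ]), 6), "\n")
  if (length(object@lambda))
    cat("  last lambda_t =", signif(object@lambda[length(object@lambda)], 6), "\n")
})

setMethod("show", "StableDistribution", function(object) {
  cat("StableDistribution (alpha =", object@alpha, ", method =",
      object@method, ")\n")
  print(round(100 * object@fractions, 2))
  cat("  lambda_inf =", signif(object@lambda, 6),
      "; iterations =", object@iterations, "\n")
})

setMethod("show", "GofResult", function(object) {
  cat("Chi-square goodness of fit (ratio ",
      paste(object@ratio, collapse = ":"), ")\n", sep = "")
  print(rbind(observed = object@observed, expected = object@expected))
  cat("  X-squared =", signif(object@statistic, 5), ", df =", object@df,
      ", p =", signif(object@pValue, 4), "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary",
      if (nzchar(object@site)) paste0("[site ", object@site, "]"), "\n")
  print(object@phenotypeCounts)
  cat("  F:M =", object@fmRatioLabel,
      "(", signif(object@fmRatio, 4), ")\n")
  if (sum(object@genotypeCounts) > 0)
    cat("  genotyped females WZ:WW =", object@wzWwRatioLabel,
        "; WW% =", object@wwPercent,
        "; undetermined excluded =", object@nExcluded, "\n")
})

## ---- accessors ----------------------------------------------------

#' Accessors for model objects
#'
#' @param object A \code{DemographicParams}, \code{StableDistribution},
#'   \code{Trajectory} or \code{GofResult}.
#' @return The requested component.
#' @name accessors
#' @examples
#' alphaOf(DemographicParams())
NULL

#' @rdname accessors
#' @export
setGeneric("alphaOf", function(object) standardGeneric("alphaOf"))
#' @rdname accessors
#' @export
setMethod("alphaOf", "DemographicParams", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("alphaOf", "StableDistribution", function(object) object@alpha)

#' @rdname accessors
#' @export
adultLifeExpectancy <- function(object) {
  stopifnot(is(object, "DemographicParams"))
  if (object@sigmaA == 0) 0 else 1 / (-log(object@sigmaA))
}

#' @rdname accessors
#' @export
setGeneric("classFractions", function(object) standardGeneric("classFractions"))

#' @rdname accessors
#' @export
setMethod("classFractions", "StableDistribution", function(object)
  object@fractions)

#' @rdname accessors
#' @export
setMethod("classFractions", "Trajectory", function(object) {
  tot <- rowSums(object@states)
  sweep(object@states, 1, tot, "/")
})

#' @rdname accessors
#' @export
setGeneric("growthRates", function(object) standardGeneric("growthRates"))
#' @rdname accessors
#' @export
setMethod("growthRates", "Trajectory", function(object) object@lambda)

#' @rdname accessors
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))
#' @rdname accessors
#' @export
setMethod("finalState", "Trajectory", function(object)
  object@states[nrow(object@states), ])

#' @rdname accessors
#' @export
setGeneric("isExtinct", function(object) standardGeneric("isExtinct"))
#' @rdname accessors
#' @export
setMethod("isExtinct", "Trajectory", function(object) object@extinct)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "GofResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("chisqStatistic", function(object) standardGeneric("chisqStatistic"))
#' @rdname accessors
#' @export
setMethod("chisqStatistic", "GofResult", function(object) object@statistic)

#' Tabulate a trajectory
#'
#' @param x A \code{Trajectory}.
#' @param row.names,optional,... Ignored (base generic signature).
#' @return A data.frame with columns step, years, per-class abundances,
#'   total, per-step growth rate \code{lambda_t} (NA on the final row)
#'   and class fractions.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  n <- nrow(x@states)
  tot <- rowSums(x@states)
  fr <- x@states / ifelse(tot > 0, tot, NA_real_)
  df <- data.frame(step = seq_len(n) - 1L,
                   years = (seq_len(n) - 1L) * x@params@stepMonths / 12,
                   N_ZZ = x@states[, "ZZ"], N_IS = x@states[, "IS"],
                   N_WZ = x@states[, "WZ"], N_WW = x@states[, "WW"],
                   N_total = tot,
                   lambda_t = c(x@lambda, NA_real_),
                   frac_ZZ = fr[, "ZZ"], frac_IS = fr[, "IS"],
                   frac_WZ = fr[, "WZ"], frac_WW = fr[, "WW"],
                   row.names = NULL)
  df
}

setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)
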