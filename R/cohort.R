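## Progeny segregation-ratio tests and cohort tallies.

#' Expected counts under a null ratio
#'
#' @param nTotal Total number of individuals (>= 0).
#' @param ratio Positive ratio weights, e.g. \code{c(3, 1)}.
#' @return Numeric vector of expected counts
#'   \code{nTotal * ratio / sum(ratio)}.
#' @examples
#' expectedCounts(83, c(3, 1))
#' @export
expectedCounts <- function(nTotal, ratio) {
  if (length(ratio) == 0 || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio weights must be positive and non-empty", call. = FALSE)
  if (nTotal < 0) stop("nTotal must be >= 0", call. = FALSE)
  nTotal * ratio / sum(ratio)
}

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' The uncorrected Pearson statistic
#' \eqn{\chi^2 = \sum_i (O_i - E_i)^2 / E_i} against expected counts
#' from the null ratio, with \code{length(observed) - 1} degrees of
#' freedom and an upper-tail p-value from the chi-square law (no Yates
#' continuity correction, which is what reproduces the published
#' progeny-table p-values).
#'
#' @param observed Integer counts (>= 2 categories, positive total).
#' @param ratio Null ratio weights, one per category; default 3:1 (the
#'   expected WZ/ZZ : WW split of a WZ-male x WZ-female progeny).
#' @return A \code{\link[=GofResult-class]{GofResult}}.
#' @examples
#' pValue(chiSquareGof(c(66, 17), c(3, 1)))
#' @export
chiSquareGof <- function(observed, ratio = c(3, 1)) {
  if (length(observed) < 2)
    stop("need at least 2 categories", call. = FALSE)
  if (length(ratio) != length(observed))
    stop("ratio must have one weight per observed category",
         call. = FALSE)
  if (any(observed < 0) || sum(observed) <= 0)
    stop("observed counts must be nonnegative with positive total",
         call. = FALSE)
  E <- expectedCounts(sum(observed), ratio)
  if (any(E == 0)) stop("expected count of zero", call. = FALSE)
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  new("GofResult", observed = as.numeric(observed), expected = E,
      ratio = as.numeric(ratio), statistic = stat, df = df,
      pValue = pchisq(stat, df, lower.tail = FALSE))
}

.ratioLabel <- function(num, den) {
  if (den == 0) return(if (num == 0) "-" else "-")
  paste0(round(num / den), ":1")
}

#' Tally a cohort of individual records
#'
#' Counts phenotypes, reports the female:male ratio in the field-table
#' style \code{"k:1"} (nearest integer) alongside the exact quotient,
#' and tallies genotypes among genotyped phenotypic females (WZ vs WW
#' ratio and the WW percentage at two decimals).  Females without a
#' determined genotype are excluded from the genotype tally (their
#' count is reported) but kept in the phenotype tally.  The
#' female:male ratio uses phenotypic males only; intersex animals are
#' counted separately.
#'
#' @param records Data frame of individual records with at least a
#'   \code{phenotype} column (\code{male}/\code{female}/\code{intersex})
#'   and optionally \code{site} and \code{genotype}.
#' @param site Optional site label to filter on.
#' @return A \code{\link[=CohortSummary-class]{CohortSummary}}.
#' @examples
#' rec <- data.frame(phenotype = c("female", "female", "male"),
#'                   genotype = c("WZ", "WW", "ZZ"))
#' tallyCohort(rec)
#' @export
tallyCohort <- function(records, site = NULL) {
  stopifnot(is.data.frame(records), "phenotype" %in% names(records))
  if (!is.null(site)) {
    if (!"site" %in% names(records))
      stop("records have no 'site' column", call. = FALSE)
    records <- records[records$site == site, , drop = FALSE]
  }
  if (nrow(records) == 0)
    stop("empty cohort", if (!is.null(site)) paste0(" for site ", site),
         call. = FALSE)
  ph <- factor(records$phenotype, levels = c("male", "female", "intersex"))
  if (anyNA(ph)) stop("invalid phenotype values", call. = FALSE)
  cnt <- table(ph)
  nM <- cnt[["male"]]; nF <- cnt[["female"]]
  fem <- records[records$phenotype == "female", , drop = FALSE]
  gt <- if ("genotype" %in% names(fem)) fem$genotype else
    rep(NA_character_, nrow(fem))
  known <- !is.na(gt) & gt %in% c("WZ", "WW")
  nWZ <- sum(gt[known] == "WZ"); nWW <- sum(gt[known] == "WW")
  new("CohortSummary",
      site = if (is.null(site)) "" else as.character(site),
      phenotypeCounts = setNames(as.integer(cnt), names(cnt)),
      fmRatio = if (nM > 0 && nF > 0) nF / nM else NA_real_,
      fmRatioLabel = if (nM > 0 && nF > 0) .ratioLabel(nF, nM) else "-",
      genotypeCounts = c(WZ = as.integer(nWZ), WW = as.integer(nWW)),
      wzWwRatio = if (nWW > 0) nWZ / nWW else NA_real_,
      wzWwRatioLabel = if (nWW > 0) .ratioLabel(nWZ, nWW) else "-",
      wwPercent = if (nWZ + nWW > 0)
        round(100 * nWW / (nWZ + nWW), 2) else NA_real_,
      nExcluded = as.integer(sum(!known)))
}

#' Segregation-ratio report over progenies
#'
#' Runs \code{\link{chiSquareGof}} per progeny group on genotyped
#' offspring.  By default WZ and ZZ offspring are pooled into one
#' category against WW (the published two-category 3:1 test, df = 1);
#' \code{categories = "three"} tests ZZ : WZ : WW against 1:2:1.
#' Progenies with no genotyped offspring are skipped with a warning.
#'
#' @param records Data frame with \code{genotype} and a grouping
#'   column.
#' @param groupBy Name of the grouping column (default \code{"site"}).
#' @param nullRatio Null ratio weights (default \code{c(3, 1)} for the
#'   pooled test, \code{c(1, 2, 1)} for the three-category test).
#' @param categories \code{"pooled"} (WZ/ZZ vs WW) or \code{"three"}.
#' @return Data frame with one row per progeny: sample size, observed
#'   counts and percentages, expected counts, chi-square statistic, df
#'   and p-value.
#' @examples
#' rec <- data.frame(site = "p1",
#'                   genotype = c(rep("WZ", 40), rep("ZZ", 26), rep("WW", 17)))
#' progenyRatioReport(rec)
#' @export
progenyRatioReport <- function(records, groupBy = "site",
                               nullRatio = NULL,
                               categories = c("pooled", "three")) {
  categories <- match.arg(categories)
  stopifnot(is.data.frame(records), groupBy %in% names(records),
            "genotype" %in% names(records))
  if (is.null(nullRatio))
    nullRatio <- if (categories == "pooled") c(3, 1) else c(1, 2, 1)
  out <- NULL
  for (g in unique(records[[groupBy]])) {
    gt <- records$genotype[records[[groupBy]] == g]
    gt <- gt[!is.na(gt) & gt %in% genotypeLevels()]
    if (length(gt) == 0) {
      warning("progeny ", g, " has no genotyped offspring; skipped")
      next
    }
    obs <- if (categories == "pooled")
      c(WZ_ZZ = sum(gt %in% c("WZ", "ZZ")), WW = sum(gt == "WW"))
    else c(ZZ = sum(gt == "ZZ"), WZ = sum(gt == "WZ"),
           WW = sum(gt == "WW"))
    res <- chiSquareGof(obs, nullRatio)
    row <- data.frame(progeny = as.character(g), n = length(gt),
                      t(setNames(as.numeric(obs),
                                 paste0("obs_", names(obs)))),
                      t(setNames(round(100 * obs / length(gt)),
                                 paste0("pct_", names(obs)))),
                      t(setNames(res@expected,
                                 paste0("exp_", names(obs)))),
                      chisq = res@statistic, df = res@df,
                      p = res@pValue, row.names = NULL)
    out <- rbind(out, row)
  }
  if (is.null(out)) stop("no progeny with genotyped offspring",
                         call. = FALSE)
  out
}
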