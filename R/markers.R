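## W-linked sex-marker screening from binary tag-presence matrices.

#' TagMatrix: binary tag presence over sexed samples
#'
#' A \code{SummarizedExperiment} with one assay, \code{"presence"}
#' (tags x samples, values 0/1), and a mandatory \code{sex} column
#' (\code{male}/\code{female}) in \code{colData}, optionally a
#' \code{genotype} column.  Count matrices are binarized at
#' \code{binarizeMin} reads; \code{NA} entries are kept and resolved at
#' screening time.
#'
#' @export
setClass("TagMatrix", contains = "SummarizedExperiment")

setValidity("TagMatrix", function(object) {
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'presence' is required")
  m <- SummarizedExperiment::assay(object, "presence")
  if (!all(m %in% c(0, 1, NA)))
    return("presence values must be 0/1 (or NA)")
  cd <- SummarizedExperiment::colData(object)
  if (!"sex" %in% names(cd)) return("colData must contain 'sex'")
  if (!all(cd$sex %in% c("male", "female")))
    return("sample sex labels must be 'male' or 'female'")
  TRUE
})

#' @describeIn TagMatrix-class Constructor.
#' @param presence Numeric matrix (tags x samples) of presence calls or
#'   read counts; rows and columns should be named.
#' @param sex Character vector of sample sex labels, one per column.
#' @param genotype Optional character vector of sample genotypes.
#' @param binarizeMin Minimum count treated as presence (default 1).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("tag1", "tag2"), c("s1", "s2")))
#' TagMatrix(m, sex = c("female", "male"))
#' @export
TagMatrix <- function(presence, sex, genotype = NULL, binarizeMin = 1) {
  presence <- as.matrix(presence)
  if (length(sex) != ncol(presence))
    stop("need one sex label per sample column", call. = FALSE)
  bin <- ifelse(is.na(presence), NA_real_,
                as.numeric(presence >= binarizeMin))
  cd <- S4Vectors::DataFrame(sex = as.character(sex),
                             row.names = colnames(presence))
  if (!is.null(genotype)) cd$genotype <- as.character(genotype)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = bin), colData = cd)
  new("TagMatrix", se)
}

#' @describeIn TagMatrix-class Sample sex labels.
#' @param object A \code{TagMatrix}.
#' @export
setGeneric("sampleSex", function(object) standardGeneric("sampleSex"))

#' @describeIn TagMatrix-class Sample sex labels.
#' @export
setMethod("sampleSex", "TagMatrix", function(object)
  SummarizedExperiment::colData(object)$sex)

.presenceBySex <- function(x, naAction) {
  m <- SummarizedExperiment::assay(x, "presence")
  nMissing <- sum(is.na(m))
  if (naAction == "absent") m[is.na(m)] <- 0
  list(m = m, nMissing = nMissing)
}

.sexFraction <- function(m, cols) {
  if (length(cols) == 0) stop("no samples of required sex", call. = FALSE)
  rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
}

#' Screen for W-linked (or Z-linked) sex markers
#'
#' Implements the presence/absence filter used to nominate W-linked
#' RAD tags: a tag is selected when it is present in strictly more
#' than \code{threshold} of the female samples (default > 60\%) and in
#' none of the male samples.  The symmetric Z-linked mode (requires a
#' \code{genotype} column) selects tags present in more than
#' \code{threshold} of males and of WZ females and absent in all WW
#' females.  Missing calls are treated as absent by default
#' (conservative for the zero-male criterion) or excluded from the
#' denominators with \code{naAction = "exclude"}.
#'
#' @param x A \code{\link[=TagMatrix-class]{TagMatrix}}.
#' @param threshold Female presence fraction that must be exceeded,
#'   in [0, 1).
#' @param mode \code{"W"} (default) or \code{"Z"}.
#' @param naAction \code{"absent"} or \code{"exclude"}.
#' @return A \code{DataFrame} with per-tag presence fractions by sex
#'   and a \code{selected} flag; screening parameters and the number
#'   of missing calls are in \code{metadata()}.
#' @examples
#' tm <- simulateRadMatrix(nTags = 50, nWLinked = 2, seed = 1)
#' sum(screenSexMarkers(tm)$selected)
#' @export
screenSexMarkers <- function(x, threshold = 0.6, mode = c("W", "Z"),
                             naAction = c("absent", "exclude")) {
  mode <- match.arg(mode)
  naAction <- match.arg(naAction)
  stopifnot(is(x, "TagMatrix"))
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  sex <- sampleSex(x)
  if (!any(sex == "male") || !any(sex == "female"))
    stop("need at least one male and one female sample", call. = FALSE)
  pm <- .presenceBySex(x, naAction)
  m <- pm$m
  femaleFrac <- .sexFraction(m, which(sex == "female"))
  maleFrac <- .sexFraction(m, which(sex == "male"))
  if (mode == "W") {
    sel <- femaleFrac > threshold & maleFrac == 0
  } else {
    gt <- SummarizedExperiment::colData(x)$genotype
    if (is.null(gt))
      stop("Z-linked screening requires sample genotypes", call. = FALSE)
    wz <- which(sex == "female" & gt == "WZ")
    ww <- which(sex == "female" & gt == "WW")
    if (length(wz) == 0 || length(ww) == 0)
      stop("Z-linked screening requires WZ and WW female samples",
           call. = FALSE)
    sel <- maleFrac > threshold &
      .sexFraction(m, wz) > threshold &
      .sexFraction(m, ww) == 0
  }
  out <- S4Vectors::DataFrame(
    tag = rownames(m),
    femaleFraction = unname(femaleFrac),
    maleFraction = unname(maleFrac),
    selected = unname(sel))
  S4Vectors::metadata(out) <- list(threshold = threshold, mode = mode,
                                   naAction = naAction,
                                   nMissing = pm$nMissing)
  out
}

#' Per-tag sex association diagnostics
#'
#' The 2x2 presence-by-sex contingency counts for every tag, with an
#' odds-style enrichment summary (odds ratio with a 0.5 Haldane
#' correction) for reporting and plotting around the screen.
#'
#' @param x A \code{\link[=TagMatrix-class]{TagMatrix}}.
#' @return A \code{DataFrame} with columns
#'   \code{presentFemale/absentFemale/presentMale/absentMale},
#'   presence fractions and \code{logOddsRatio}.
#' @examples
#' tm <- simulateRadMatrix(nTags = 20, nWLinked = 1, seed = 1)
#' tagAssociationStats(tm)[1:3, ]
#' @export
tagAssociationStats <- function(x) {
  stopifnot(is(x, "TagMatrix"))
  m <- SummarizedExperiment::assay(x, "presence")
  m[is.na(m)] <- 0
  sex <- sampleSex(x)
  f <- sex == "female"
  pf <- rowSums(m[, f, drop = FALSE])
  pmale <- rowSums(m[, !f, drop = FALSE])
  nf <- sum(f); nm <- sum(!f)
  orr <- ((pf + 0.5) / (nf - pf + 0.5)) /
    ((pmale + 0.5) / (nm - pmale + 0.5))
  S4Vectors::DataFrame(
    tag = rownames(m),
    presentFemale = unname(pf), absentFemale = unname(nf - pf),
    presentMale = unname(pmale), absentMale = unname(nm - pmale),
    femaleFraction = unname(pf / nf), maleFraction = unname(pmale / nm),
    logOddsRatio = unname(log(orr)))
}
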