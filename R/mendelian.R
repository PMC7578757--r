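## Exact genetics of the WZ/ZZ system with intersex (WZ) males.

#' Sex genotypes and phenotype classes
#'
#' The three sex genotypes of a female-heterogametic system
#' (\code{"ZZ"}, \code{"WZ"}, \code{"WW"}) and the four functional
#' classes they map onto: \code{"ZZ_MALE"}, \code{"IS"} (intersex, a
#' functional male with the female WZ genotype), \code{"WZ_FEMALE"}
#' and \code{"WW_FEMALE"}.
#'
#' @return A character vector of level names.
#' @examples
#' genotypeLevels()
#' phenotypeClassLevels()
#' @export
genotypeLevels <- function() c("ZZ", "WZ", "WW")

#' @rdname genotypeLevels
#' @export
phenotypeClassLevels <- function() c("ZZ_MALE", "IS", "WZ_FEMALE", "WW_FEMALE")

## short state labels used for abundance vectors, in class order
.stateLevels <- function() c("ZZ", "IS", "WZ", "WW")

.checkGenotype <- function(g, what = "genotype") {
  bad <- !(g %in% genotypeLevels())
  if (any(bad))
    stop(sprintf("invalid %s: %s (must be one of %s)", what,
                 paste(unique(g[bad]), collapse = ", "),
                 paste(genotypeLevels(), collapse = "/")), call. = FALSE)
  invisible(g)
}

.checkProb <- function(p, what = "alpha") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(sprintf("%s must be a single number in [0, 1]", what), call. = FALSE)
  invisible(p)
}

#' Gamete distribution of a sex genotype
#'
#' Each of a parent's two sex chromosomes is transmitted with
#' probability 1/2, so \code{"WZ"} gives W and Z gametes in equal
#' proportion and the homogametic genotypes give a single gamete type.
#'
#' @param parent A genotype, one of \code{"ZZ"}, \code{"WZ"}, \code{"WW"}.
#' @return Named numeric vector of probabilities over gametes
#'   \code{c(W =, Z =)}, summing to 1.
#' @examples
#' gameteDistribution("WZ")
#' @export
gameteDistribution <- function(parent) {
  .checkGenotype(parent, "parent genotype")
  stopifnot(length(parent) == 1L)
  switch(parent,
         ZZ = c(W = 0, Z = 1),
         WZ = c(W = 0.5, Z = 0.5),
         WW = c(W = 1, Z = 0))
}

#' Offspring genotype distribution of a cross
#'
#' Product of the two parental gamete distributions.  Functional sires
#' are \code{"ZZ"} males or \code{"WZ"} intersex males; dams are
#' \code{"WZ"} or \code{"WW"} females.  WW sires are rejected: WW
#' males have only been produced by artificial manipulation in other
#' species and are outside this model.
#'
#' @param sire Sire genotype, \code{"ZZ"} or \code{"WZ"}.
#' @param dam Dam genotype, \code{"WZ"} or \code{"WW"}.
#' @return Named numeric vector of offspring genotype probabilities
#'   over \code{genotypeLevels()}, summing to 1.
#' @examples
#' ## the intersex x female cross: 25% WW females
#' offspringGenotypeDistribution("WZ", "WZ")
#' @export
offspringGenotypeDistribution <- function(sire, dam) {
  .checkGenotype(sire, "sire genotype")
  .checkGenotype(dam, "dam genotype")
  if (!(sire %in% c("ZZ", "WZ")))
    stop("invalid sire genotype '", sire,
         "': functional sires are ZZ or WZ (intersex)", call. = FALSE)
  if (!(dam %in% c("WZ", "WW")))
    stop("invalid dam genotype '", dam,
         "': functional dams are WZ or WW", call. = FALSE)
  gs <- gameteDistribution(sire)
  gd <- gameteDistribution(dam)
  out <- c(ZZ = unname(gs["Z"] * gd["Z"]),
           WZ = unname(gs["W"] * gd["Z"] + gs["Z"] * gd["W"]),
           WW = unname(gs["W"] * gd["W"]))
  stopifnot(abs(sum(out) - 1) < 1e-12)
  out
}

#' Partition offspring genotypes into phenotype classes
#'
#' ZZ offspring are males and WW offspring are females; a fraction
#' \code{alpha} of WZ offspring emerge as intersex functional males
#' (class \code{"IS"}), the rest as WZ females.
#'
#' @param g Named numeric genotype distribution (names among
#'   \code{genotypeLevels()}; missing genotypes count as 0).
#' @param alpha Fraction of WZ progeny emerging intersex, in [0, 1].
#' @return Named numeric vector over \code{phenotypeClassLevels()},
#'   summing to \code{sum(g)}.
#' @examples
#' phenotypePartition(offspringGenotypeDistribution("WZ", "WZ"), alpha = 0)
#' @export
phenotypePartition <- function(g, alpha) {
  .checkProb(alpha, "alpha")
  if (is.null(names(g)) || !all(names(g) %in% genotypeLevels()))
    stop("g must be named with genotypes ZZ/WZ/WW", call. = FALSE)
  if (any(g < 0)) stop("genotype probabilities must be nonnegative",
                       call. = FALSE)
  full <- setNames(numeric(3), genotypeLevels())
  full[names(g)] <- g
  out <- c(ZZ_MALE   = unname(full["ZZ"]),
           IS        = unname(alpha * full["WZ"]),
           WZ_FEMALE = unname((1 - alpha) * full["WZ"]),
           WW_FEMALE = unname(full["WW"]))
  stopifnot(abs(sum(out) - sum(full)) < 1e-12)
  out
}

#' Call a sex genotype from the W/Z marker bands
#'
#' The two sex-chromosome-specific PCR markers amplify a W band and a
#' Z band; the band pattern determines the genotype directly
#' (W+Z = WZ, Z only = ZZ, W only = WW).  A double-negative call is a
#' genotyping failure, not a genotype, and raises an error.
#'
#' @param wBand,zBand Logical vectors (recycled to common length):
#'   presence of the W and Z band.
#' @return Character vector of genotypes.
#' @examples
#' genotypeFromMarkers(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
genotypeFromMarkers <- function(wBand, zBand) {
  n <- max(length(wBand), length(zBand))
  w <- rep_len(as.logical(wBand), n)
  z <- rep_len(as.logical(zBand), n)
  if (anyNA(w) || anyNA(z))
    stop("band calls must be TRUE/FALSE, not NA", call. = FALSE)
  if (any(!w & !z))
    stop("undetermined call: no band amplified for ",
         sum(!w & !z), " individual(s); (w, z) = (FALSE, FALSE) ",
         "signals genotyping failure, not a genotype", call. = FALSE)
  ifelse(w & z, "WZ", ifelse(z, "ZZ", "WW"))
}

#' Classify an individual into a functional class
#'
#' Combines the genotype with the gonopore phenotype: an intersex
#' animal with the WZ genotype is an \code{"IS"} (functional male); the
#' rare intersex-looking ZZ animal is classed \code{"ZZ_MALE"}.
#' Inadmissible pairs (e.g. a phenotypic male with genotype WW) raise a
#' validation error.
#'
#' @param genotype Character vector of genotypes.
#' @param phenotype Character vector among \code{"male"},
#'   \code{"female"}, \code{"intersex"} (recycled).
#' @return Character vector over \code{phenotypeClassLevels()}.
#' @examples
#' classifyIndividual("WZ", "intersex")
#' @export
classifyIndividual <- function(genotype, phenotype) {
  n <- max(length(genotype), length(phenotype))
  g <- rep_len(genotype, n)
  p <- rep_len(phenotype, n)
  .checkGenotype(g)
  bad <- !(p %in% c("male", "female", "intersex"))
  if (any(bad))
    stop("invalid phenotype: ", paste(unique(p[bad]), collapse = ", "),
         call. = FALSE)
  out <- character(n)
  ok <- logical(n)
  sel <- p == "male" & g == "ZZ";      out[sel] <- "ZZ_MALE";   ok[sel] <- TRUE
  sel <- p == "intersex" & g == "WZ";  out[sel] <- "IS";        ok[sel] <- TRUE
  sel <- p == "intersex" & g == "ZZ";  out[sel] <- "ZZ_MALE";   ok[sel] <- TRUE
  sel <- p == "female" & g == "WZ";    out[sel] <- "WZ_FEMALE"; ok[sel] <- TRUE
  sel <- p == "female" & g == "WW";    out[sel] <- "WW_FEMALE"; ok[sel] <- TRUE
  if (any(!ok))
    stop("inadmissible genotype/phenotype pair(s): ",
         paste(unique(paste0(g[!ok], "+", p[!ok])), collapse = ", "),
         call. = FALSE)
  out
}
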