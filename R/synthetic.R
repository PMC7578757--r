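## Seeded generators for crosses, pond experiments, native cohorts and
## RAD-tag matrices, emitting tables consumable by every other module.

.bandsFromGenotype <- function(genotype, errorRate) {
  w <- genotype %in% c("WZ", "WW")
  z <- genotype %in% c("WZ", "ZZ")
  if (errorRate > 0) {
    n <- length(genotype)
    w <- xor(w, runif(n) < errorRate)
    z <- xor(z, runif(n) < errorRate)
  }
  list(w = w, z = z)
}

.classToPhenotype <- c(ZZ_MALE = "male", IS = "intersex",
                       WZ_FEMALE = "female", WW_FEMALE = "female")
.classToGenotype <- c(ZZ_MALE = "ZZ", IS = "WZ",
                      WZ_FEMALE = "WZ", WW_FEMALE = "WW")

## individual records from per-class counts; genotype column is the
## band-called genotype (NA when no band amplified), true_genotype the
## simulated truth
.recordsFromClassCounts <- function(counts, site, errorRate, idPrefix) {
  cls <- rep(names(counts), counts)
  n <- length(cls)
  trueGt <- unname(.classToGenotype[cls])
  bands <- .bandsFromGenotype(trueGt, errorRate)
  called <- rep(NA_character_, n)
  ok <- bands$w | bands$z
  if (any(ok)) called[ok] <- genotypeFromMarkers(bands$w[ok], bands$z[ok])
  data.frame(id = sprintf("%s%05d", idPrefix, seq_len(n)),
             site = site,
             phenotype = unname(.classToPhenotype[cls]),
             gonopore_config = NA_character_,
             w_band = bands$w, z_band = bands$z,
             genotype = called,
             true_genotype = trueGt,
             stringsAsFactors = FALSE)
}

#' Simulate a Mendelian cross progeny
#'
#' Draws \code{n} offspring multinomially from the phenotype-class
#' distribution of the cross (the genotype cross table partitioned
#' with \code{alpha}) and attaches marker bands derived from the true
#' genotype, each band independently flipped with probability
#' \code{bandErrorRate} (double-negative calls yield an undetermined
#' \code{genotype} of \code{NA}).
#'
#' @param sire,dam Parental genotypes (see
#'   \code{\link{offspringGenotypeDistribution}}).
#' @param n Number of offspring (>= 1).
#' @param alpha Intersex-emergence fraction.
#' @param bandErrorRate Per-band flip probability (default 0).
#' @param seed Optional integer seed.
#' @param progenyId Label written to the \code{site} column.
#' @return Data frame of individual records (one row per offspring)
#'   with columns id, site, phenotype, gonopore_config, w_band,
#'   z_band, genotype (band-called) and true_genotype.
#' @examples
#' table(simulateCross("WZ", "WZ", n = 100, alpha = 0, seed = 1)$genotype)
#' @export
simulateCross <- function(sire, dam, n, alpha = 0.04, bandErrorRate = 0,
                          seed = NULL, progenyId = "cross1") {
  stopifnot(n >= 1)
  .checkProb(bandErrorRate, "bandErrorRate")
  p <- phenotypePartition(offspringGenotypeDistribution(sire, dam), alpha)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- setNames(as.integer(rmultinom(1L, n, p)), names(p))
  .recordsFromClassCounts(counts, progenyId, bandErrorRate, "off")
}

#' Simulate a pond stocking experiment
#'
#' Emulates the cultured-pond design: a pond stocked with chosen
#' counts of the four classes (e.g. WZ females plus intersex males,
#' or females plus ZZ males as a control).  Each stocked female mates
#' with a sire class drawn proportional to the stocked male classes
#' and produces a brood (equal sizes by default, negative-binomially
#' overdispersed when \code{dispersion > 0}); \code{nSampled}
#' offspring are then sampled without replacement from the pooled
#' progeny.
#'
#' @param stocking Named counts of stocked animals, e.g.
#'   \code{c(IS = 30, WZ = 130)}; classes are ZZ/IS/WZ/WW.
#' @param nSampled Number of offspring sampled from the pool.
#' @param alpha Intersex-emergence fraction.
#' @param broodSize Mean offspring per female (default 300).
#' @param dispersion Brood-size overdispersion; 0 = equal broods,
#'   otherwise negative binomial with size \code{1/dispersion}.
#' @param bandErrorRate Per-band flip probability.
#' @param seed Optional integer seed.
#' @param pondId Label written to the \code{site} column.
#' @return Data frame of sampled offspring records (as
#'   \code{\link{simulateCross}}), with the full pooled progeny class
#'   counts in \code{attr(, "poolCounts")}.
#' @examples
#' pond <- simulatePondExperiment(c(IS = 30, WZ = 130), nSampled = 200,
#'                                alpha = 0.04, seed = 1)
#' table(pond$phenotype)
#' @export
simulatePondExperiment <- function(stocking, nSampled, alpha = 0.04,
                                   broodSize = 300, dispersion = 0,
                                   bandErrorRate = 0, seed = NULL,
                                   pondId = "pond1") {
  st <- populationState(
    ZZ = if ("ZZ" %in% names(stocking)) stocking[["ZZ"]] else 0,
    IS = if ("IS" %in% names(stocking)) stocking[["IS"]] else 0,
    WZ = if ("WZ" %in% names(stocking)) stocking[["WZ"]] else 0,
    WW = if ("WW" %in% names(stocking)) stocking[["WW"]] else 0)
  if (st[["ZZ"]] + st[["IS"]] <= 0 || st[["WZ"]] + st[["WW"]] <= 0)
    stop("degenerate stocking: need at least one functional male and ",
         "one female", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  uSire <- st[["IS"]] / (st[["ZZ"]] + st[["IS"]])
  dams <- c(rep("WZ", st[["WZ"]]), rep("WW", st[["WW"]]))
  pool <- setNames(integer(4), phenotypeClassLevels())
  for (damGt in dams) {
    sireGt <- if (runif(1) < uSire) "WZ" else "ZZ"
    brood <- if (dispersion > 0)
      rnbinom(1L, size = 1 / dispersion, mu = broodSize) else broodSize
    if (brood == 0) next
    p <- phenotypePartition(
      offspringGenotypeDistribution(sireGt, damGt), alpha)
    pool <- pool + setNames(as.integer(rmultinom(1L, brood, p)), names(p))
  }
  if (nSampled > sum(pool))
    stop("cannot sample ", nSampled, " offspring from a progeny pool ",
         "of ", sum(pool), call. = FALSE)
  ## sample without replacement from the pooled progeny
  drawn <- sample(rep(names(pool), pool), nSampled)
  counts <- setNames(as.integer(table(
    factor(drawn, levels = phenotypeClassLevels()))),
    phenotypeClassLevels())
  out <- .recordsFromClassCounts(counts, pondId, bandErrorRate, "pond")
  attr(out, "poolCounts") <- pool
  out
}

#' Simulate a native population sample
#'
#' Draws \code{n} individuals multinomially from the long-term stable
#' distribution at \code{alpha} (native samples are interpreted
#' against the long-term structure); a burn-in trajectory mode is
#' available for transient studies via \code{burninSteps}.
#'
#' @param n Sample size (>= 1).
#' @param alpha Intersex-emergence fraction.
#' @param bandErrorRate Per-band flip probability.
#' @param seed Optional integer seed.
#' @param site Label written to the \code{site} column.
#' @param burninSteps If > 0, draw from the class fractions after this
#'   many projection steps from ZZ = WZ = 50\% instead of the LTSD.
#' @return Data frame of individual records.
#' @examples
#' mean(simulateNativePopulation(1000, alpha = 0.04,
#'                               seed = 1)$phenotype == "intersex")
#' @export
simulateNativePopulation <- function(n, alpha = 0.04, bandErrorRate = 0,
                                     seed = NULL, site = "native",
                                     burninSteps = 0) {
  stopifnot(n >= 1)
  frac <- if (burninSteps > 0) {
    tr <- simulateTrajectory(populationState(ZZ = 0.5, WZ = 0.5),
                             DemographicParams(alpha = alpha),
                             nSteps = burninSteps)
    finalState(tr) / sum(finalState(tr))
  } else {
    classFractions(stableDistribution(alpha, method = "solve"))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- setNames(as.integer(rmultinom(1L, n, frac)),
                     phenotypeClassLevels())
  .recordsFromClassCounts(counts, site, bandErrorRate, "ind")
}

#' Simulate a RAD-tag presence/absence matrix
#'
#' Emulates the marker-discovery cohort (by default 12 ZZ males and 12
#' females, 8 WZ + 4 WW).  W-linked tags are present in each W-carrier
#' with probability \code{1 - dropout} and in ZZ samples with
#' probability \code{falsePresence}; background tags are present
#' i.i.d. with a per-tag frequency drawn uniformly on (0, 1).
#'
#' @param nMale,nFemaleWZ,nFemaleWW Sample counts per genotype.
#' @param nTags Total number of tags.
#' @param nWLinked Number of planted W-linked tags (first rows,
#'   flagged in \code{rowData()$wLinked}).
#' @param dropout Per-sample dropout probability of a W-linked tag in
#'   W-carriers.
#' @param falsePresence Probability a W-linked tag appears in a ZZ
#'   male.
#' @param seed Optional integer seed.
#' @return A \code{\link[=TagMatrix-class]{TagMatrix}} with sample sex
#'   and genotype in \code{colData()}.
#' @examples
#' tm <- simulateRadMatrix(nTags = 100, nWLinked = 3, seed = 1)
#' table(screenSexMarkers(tm)$selected)
#' @export
simulateRadMatrix <- function(nMale = 12, nFemaleWZ = 8, nFemaleWW = 4,
                              nTags = 2000, nWLinked = 5, dropout = 0,
                              falsePresence = 0, seed = NULL) {
  stopifnot(nMale >= 1, nFemaleWZ + nFemaleWW >= 1, nWLinked <= nTags)
  .checkProb(dropout, "dropout")
  .checkProb(falsePresence, "falsePresence")
  if (!is.null(seed)) withr::local_seed(seed)
  genotype <- c(rep("ZZ", nMale), rep("WZ", nFemaleWZ),
                rep("WW", nFemaleWW))
  sex <- c(rep("male", nMale), rep("female", nFemaleWZ + nFemaleWW))
  nS <- length(sex)
  sampleIds <- sprintf("%s%02d", ifelse(sex == "male", "M", "F"),
                       seq_len(nS))
  m <- matrix(0, nrow = nTags, ncol = nS,
              dimnames = list(sprintf("tag%05d", seq_len(nTags)),
                              sampleIds))
  wl <- seq_len(nWLinked)
  if (nWLinked > 0) {
    carriers <- genotype %in% c("WZ", "WW")
    m[wl, carriers] <- rbinom(nWLinked * sum(carriers), 1L, 1 - dropout)
    m[wl, !carriers] <- rbinom(nWLinked * sum(!carriers), 1L,
                               falsePresence)
  }
  bg <- setdiff(seq_len(nTags), wl)
  if (length(bg) > 0) {
    freq <- runif(length(bg))
    m[bg, ] <- rbinom(length(bg) * nS, 1L, rep(freq, times = nS))
  }
  tm <- TagMatrix(m, sex = sex, genotype = genotype)
  SummarizedExperiment::rowData(tm)$wLinked <-
    seq_len(nTags) %in% wl
  tm
}
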