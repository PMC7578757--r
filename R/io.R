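## File IO: cohort CSV tables and tag-matrix TSVs.

.cohortColumns <- c("id", "site", "phenotype", "gonopore_config",
                    "w_band", "z_band", "genotype")

#' Read and write cohort CSV tables
#'
#' Cohort tables are comma-separated, UTF-8, header mandatory, with
#' \code{"NA"} for missing values and columns id, site, phenotype,
#' gonopore_config, w_band, z_band, genotype (extra columns such as
#' \code{true_genotype} are preserved).  On reading, the genotype is
#' back-filled from the marker bands where absent (a double-negative
#' band call stays \code{NA} and is counted), and every
#' genotype/phenotype pair is validated; violations are reported with
#' the offending row.
#'
#' @param path File path.
#' @return For \code{readCohortCsv}, a validated data frame of
#'   individual records.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCohortCsv(simulateCross("ZZ", "WZ", 5, seed = 1), f)
#' readCohortCsv(f)
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(c("id", "phenotype"), names(rec))
  if (length(missing))
    stop("cohort file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in setdiff(.cohortColumns, names(rec)))
    rec[[col]] <- NA
  for (col in c("id", "site", "phenotype", "gonopore_config", "genotype"))
    rec[[col]] <- as.character(rec[[col]])
  bad <- !(rec$phenotype %in% c("male", "female", "intersex"))
  if (any(bad))
    stop("invalid phenotype in row(s) ",
         paste(head(which(bad), 5), collapse = ", "),
         " (column 'phenotype')", call. = FALSE)
  rec$w_band <- as.logical(rec$w_band)
  rec$z_band <- as.logical(rec$z_band)
  ## back-fill genotype from bands where absent
  fill <- is.na(rec$genotype) & !is.na(rec$w_band) & !is.na(rec$z_band) &
    (rec$w_band | rec$z_band)
  if (any(fill))
    rec$genotype[fill] <- genotypeFromMarkers(rec$w_band[fill],
                                              rec$z_band[fill])
  known <- !is.na(rec$genotype)
  badGt <- known & !(rec$genotype %in% genotypeLevels())
  if (any(badGt))
    stop("invalid genotype in row(s) ",
         paste(head(which(badGt), 5), collapse = ", "),
         " (column 'genotype')", call. = FALSE)
  ## admissibility of genotype/phenotype pairs
  for (i in which(known)) {
    res <- tryCatch(classifyIndividual(rec$genotype[i], rec$phenotype[i]),
                    error = function(e) e)
    if (inherits(res, "error"))
      stop("row ", i, " (id ", rec$id[i], "): ", conditionMessage(res),
           call. = FALSE)
  }
  rec
}

#' @rdname readCohortCsv
#' @param records Data frame of individual records.
#' @export
writeCohortCsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE, na = "NA",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write tag matrices as TSV
#'
#' The matrix file is tab-separated with tags as rows (first column
#' \code{tag}) and samples as columns, values 0/1 or read counts; the
#' sex map is a two-column TSV (\code{sample}, \code{sex}) with an
#' optional \code{genotype} column.
#'
#' @param path Matrix TSV path.
#' @param sexPath Sample-sex map TSV path.
#' @param binarizeMin Minimum count treated as presence.
#' @return For \code{readTagMatrix}, a
#'   \code{\link[=TagMatrix-class]{TagMatrix}}.
#' @examples
#' tm <- simulateRadMatrix(nTags = 10, nWLinked = 1, seed = 1)
#' fm <- tempfile(); fs <- tempfile()
#' writeTagMatrix(tm, fm, fs)
#' readTagMatrix(fm, fs)
#' @export
readTagMatrix <- function(path, sexPath, binarizeMin = 1) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "tag")
    stop("first column of the matrix TSV must be 'tag'", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$tag
  sexMap <- read.delim(sexPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "sex") %in% names(sexMap)))
    stop("sex map needs columns 'sample' and 'sex'", call. = FALSE)
  missing <- setdiff(colnames(m), sexMap$sample)
  if (length(missing))
    stop("samples without sex label: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  idx <- match(colnames(m), sexMap$sample)
  TagMatrix(m, sex = sexMap$sex[idx],
            genotype = if ("genotype" %in% names(sexMap))
              sexMap$genotype[idx] else NULL,
            binarizeMin = binarizeMin)
}

#' @rdname readTagMatrix
#' @param x A \code{TagMatrix}.
#' @importFrom utils write.table
#' @export
writeTagMatrix <- function(x, path, sexPath) {
  stopifnot(is(x, "TagMatrix"))
  m <- SummarizedExperiment::assay(x, "presence")
  tab <- data.frame(tag = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cd <- SummarizedExperiment::colData(x)
  sexMap <- data.frame(sample = rownames(cd), sex = cd$sex)
  if ("genotype" %in% names(cd)) sexMap$genotype <- cd$genotype
  write.table(sexMap, sexPath, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' One row per step with columns step, years, per-class abundances,
#' total, per-step growth rate and class fractions.
#'
#' @param trajectory A \code{\link[=Trajectory-class]{Trajectory}}.
#' @param path Output path.
#' @export
writeTrajectoryCsv <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE,
            na = "NA")
  invisible(path)
}
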