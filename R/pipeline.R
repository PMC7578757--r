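## Orchestration: configuration, stage wiring and run manifests.

.validateConfig <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (!is.null(config$alpha)) .checkProb(config$alpha, "alpha")
  for (p in c("sigma0", "sigma_a"))
    if (!is.null(config[[p]])) .checkProb(config[[p]], p)
  if (!is.null(config$phi) && config$phi < 0)
    stop("phi must be >= 0", call. = FALSE)
  if (is.null(config$seed)) stop("config must declare a seed",
                                 call. = FALSE)
  invisible(config)
}

.configParams <- function(config) {
  DemographicParams(
    alpha = if (is.null(config$alpha)) 0.04 else config$alpha,
    sigma0 = if (is.null(config$sigma0)) 1 else config$sigma0,
    sigmaA = if (is.null(config$sigma_a)) 0.6 else config$sigma_a,
    phi = if (is.null(config$phi)) 1.2 else config$phi,
    stepMonths = if (is.null(config$step_months)) 6 else
      config$step_months)
}

#' Run a configured analysis pipeline
#'
#' Thin orchestration over the package's stages.  The configuration is
#' an R list or a JSON file with fields \code{seed} (mandatory),
#' \code{alpha}, \code{sigma0}, \code{sigma_a}, \code{phi},
#' \code{step_months} and any of the stage blocks:
#' \describe{
#'   \item{\code{ltsd}}{\code{list(tol =)} — stable-distribution
#'     report (both solver routes).}
#'   \item{\code{project}}{\code{list(initial = c(ZZ=,IS=,WZ=,WW=),
#'     n_steps =, mode =)} — trajectory simulation.}
#'   \item{\code{cross}}{\code{list(sire =, dam =, n =)} — simulated
#'     progeny plus its segregation-ratio report.}
#'   \item{\code{native}}{\code{list(n =)} — simulated native cohort
#'     plus its tally and alpha estimate.}
#'   \item{\code{rad}}{\code{list(n_tags =, n_w_linked =, dropout =,
#'     false_presence =, threshold =)} — simulated tag matrix plus the
#'     marker screen.}
#' }
#' The configuration is validated before any stage runs; all
#' randomness is derived from the declared seed, so a rerun with the
#' same config is identical.  When \code{outDir} is given, stage
#' outputs are written as CSV/TSV and a JSON run manifest
#' (parameters, seed, package version, timestamp, output paths) is
#' saved alongside.
#'
#' @param config List or path to a JSON config file.
#' @param outDir Optional output directory (created if needed).
#' @return List with elements \code{results} (per-stage objects) and
#'   \code{manifest}.
#' @examples
#' out <- runPipeline(list(seed = 1, alpha = 0.04, ltsd = list()))
#' classFractions(out$results$ltsd$iterate)
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  .validateConfig(config)
  params <- .configParams(config)
  seed <- as.integer(config$seed)
  results <- list()
  outputs <- character()
  saveCsv <- function(obj, name, writer) {
    if (is.null(outDir)) return()
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    p <- file.path(outDir, name)
    writer(obj, p)
    outputs[[name]] <<- p
  }

  if (!is.null(config$ltsd)) {
    tol <- if (is.null(config$ltsd$tol)) 1e-10 else config$ltsd$tol
    results$ltsd <- list(
      iterate = stableDistribution(params@alpha, params, tol = tol),
      solve = stableDistribution(params@alpha, params, method = "solve"))
    rep <- data.frame(
      class = .stateLevels(),
      percent = round(100 * classFractions(results$ltsd$iterate), 4))
    saveCsv(rep, "ltsd.csv", function(o, p)
      write.csv(o, p, row.names = FALSE))
  }
  if (!is.null(config$project)) {
    init <- do.call(populationState, as.list(config$project$initial))
    mode <- if (is.null(config$project$mode)) "deterministic" else
      config$project$mode
    results$project <- simulateTrajectory(
      init, params, nSteps = config$project$n_steps, mode = mode,
      seed = seed)
    saveCsv(results$project, "trajectory.csv", writeTrajectoryCsv)
  }
  if (!is.null(config$cross)) {
    rec <- simulateCross(config$cross$sire, config$cross$dam,
                         n = config$cross$n, alpha = params@alpha,
                         seed = seed)
    results$cross <- list(records = rec,
                          gof = progenyRatioReport(rec))
    saveCsv(rec, "cross.csv", writeCohortCsv)
  }
  if (!is.null(config$native)) {
    rec <- simulateNativePopulation(config$native$n,
                                    alpha = params@alpha, seed = seed)
    tal <- tallyCohort(rec)
    results$native <- list(
      records = rec, tally = tal,
      alphaHat = estimateAlphaFromCohort(
        mean(rec$phenotype == "intersex")))
    saveCsv(rec, "native.csv", writeCohortCsv)
  }
  if (!is.null(config$rad)) {
    r <- config$rad
    tm <- simulateRadMatrix(
      nTags = if (is.null(r$n_tags)) 2000 else r$n_tags,
      nWLinked = if (is.null(r$n_w_linked)) 5 else r$n_w_linked,
      dropout = if (is.null(r$dropout)) 0 else r$dropout,
      falsePresence = if (is.null(r$false_presence)) 0 else
        r$false_presence,
      seed = seed)
    scr <- screenSexMarkers(tm, threshold = if (is.null(r$threshold))
      0.6 else r$threshold)
    results$rad <- list(matrix = tm, screen = scr)
    saveCsv(as.data.frame(scr), "screen.csv", function(o, p)
      write.csv(o, p, row.names = FALSE))
  }

  manifest <- list(
    package = "WZdynamics",
    version = as.character(packageVersion("WZdynamics")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameters = list(alpha = params@alpha, sigma0 = params@sigma0,
                      sigma_a = params@sigmaA, phi = params@phi,
                      step_months = params@stepMonths),
    config = config,
    outputs = as.list(outputs))
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  list(results = results, manifest = manifest)
}
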