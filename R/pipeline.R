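## End-to-end orchestration: a validated configuration, a reproducible run
## directory, and serialization of recordings and reports.

#' Build a validated pipeline configuration
#'
#' All analysis constants in one place, preset to the method's defaults:
#' 0.75-4 Hz band (design order 6), 10x10 / 5x5 pooling blocks, the 50 x 35
#' grid, 5 pulse frames, prominence 0.4 (G, NIR) / 0.2 (R, B), a 6-row chin
#' mask, and the boosting hyperparameters. Configurations round-trip
#' through YAML losslessly (\code{\link{readConfig}},
#' \code{\link{writeConfig}}).
#'
#' @param nSubjects,classes,trialsPerClass simulated cohort design.
#' @param seed master seed for simulation, undersampling and training.
#' @param bandLo,bandHi,filterOrder band-pass parameters, Hz.
#' @param chinRows rows in the chin mask.
#' @param prominence named per-channel prominence thresholds.
#' @param nrounds,maxDepth,eta boosting hyperparameters.
#' @param templateStrength class-template modulation strength.
#' @return A named list of class \code{"tstmsConfig"}.
#' @export
tstmsConfig <- function(nSubjects = 6L, classes = CLASS_LEVELS,
                        trialsPerClass = 4L, seed = 1L, bandLo = 0.75,
                        bandHi = 4, filterOrder = 6L, chinRows = 6L,
                        prominence = defaultProminence(), nrounds = 60L,
                        maxDepth = 3L, eta = 0.3, templateStrength = 1) {
  cfg <- list(
    nSubjects = as.integer(nSubjects), classes = classes,
    trialsPerClass = as.integer(trialsPerClass), seed = as.integer(seed),
    bandLo = bandLo, bandHi = bandHi, filterOrder = as.integer(filterOrder),
    chinRows = as.integer(chinRows), prominence = as.list(prominence),
    nrounds = as.integer(nrounds), maxDepth = as.integer(maxDepth),
    eta = eta, templateStrength = templateStrength
  )
  validateConfig(cfg)
  class(cfg) <- c("tstmsConfig", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list.
#' @return Invisibly \code{TRUE}; errors describe the offending field.
#' @export
validateConfig <- function(cfg) {
  if (cfg$nSubjects < 2) stop("config: nSubjects must be at least 2")
  if (!(cfg$bandLo > 0 && cfg$bandLo < cfg$bandHi)) {
    stop("config: need 0 < bandLo < bandHi")
  }
  if (cfg$trialsPerClass < 1) stop("config: trialsPerClass must be >= 1")
  if (!all(unlist(cfg$prominence) > 0 & unlist(cfg$prominence) < 1)) {
    stop("config: prominence thresholds must lie in (0, 1)")
  }
  if (cfg$chinRows < 0 || cfg$chinRows > 15) {
    stop("config: chinRows out of range")
  }
  invisible(TRUE)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return \code{readConfig} returns the configuration.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$classes <- as.character(cfg$classes)
  validateConfig(cfg)
  class(cfg) <- c("tstmsConfig", "list")
  cfg
}

#' @rdname readConfig
#' @param cfg configuration from \code{\link{tstmsConfig}}.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulates a cohort from the configuration, extracts the TSTMS feature
#' matrix, evaluates the class-weighted one-vs-one classifier under
#' leave-one-subject-out cross-validation, computes the multiclass
#' importance tensor, and writes all artifacts into \code{outDir}: the
#' config and cohort manifest, the feature matrix container plus its index
#' map, metrics as JSON and per-class CSV, the confusion matrix as CSV and
#' heatmap, the spatial importance summary as CSV and heatmap, and a run
#' log.
#'
#' @param cfg from \code{\link{tstmsConfig}}.
#' @param outDir output directory, created if needed.
#' @param verbose report progress.
#' @return Invisibly, a list with \code{features}, \code{metrics} and
#'   \code{importance}.
#' @export
runPipeline <- function(cfg, outDir, verbose = FALSE) {
  validateConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  cat(sprintf("run started %s\nseed %d\n", format(Sys.time()), cfg$seed),
      file = log)
  writeConfig(cfg, file.path(outDir, "config.yaml"))

  cohort <- makeCohort(
    cfg$nSubjects, cfg$classes, cfg$trialsPerClass, seed = cfg$seed,
    templates = defaultClassTemplates(strength = cfg$templateStrength)
  )
  write.csv(cohortManifest(cohort), file.path(outDir, "manifest.csv"),
            row.names = FALSE)
  fm <- cohortFeatureMatrix(
    cohort, verbose = verbose, chinMask = defaultChinMask(cfg$chinRows),
    prominence = unlist(cfg$prominence), lo = cfg$bandLo, hi = cfg$bandHi,
    order = cfg$filterOrder
  )
  params <- boostParams(cfg$nrounds, cfg$maxDepth, cfg$eta)
  metrics <- evaluateLoocv(fm$x, fm$meta, params = params, seed = cfg$seed)
  model <- trainOvo(fm$x, fm$meta$classLabel, params = params,
                    seed = cfg$seed)
  it <- lfcImportance(model, method = "native")
  sm <- spatialMaps(it)

  saveRDS(fm, file.path(outDir, "features.rds"))
  jsonlite::write_json(featureIndexMap(),
                       file.path(outDir, "feature_index_map.json"))
  jsonlite::write_json(
    list(aucPerClass = as.list(metrics@aucPerClass),
         balancedAccPerClass = as.list(metrics@balancedAccPerClass),
         subsetAccuracy = metrics@subsetAccuracy,
         macroAuc = mean(metrics@aucPerClass),
         f8Percent = sm$f8Percent, seed = cfg$seed),
    file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  write.csv(data.frame(class = names(metrics@aucPerClass),
                       rocAuc = metrics@aucPerClass,
                       balancedAcc = metrics@balancedAccPerClass,
                       row.names = NULL),
            file.path(outDir, "metrics_per_class.csv"), row.names = FALSE)
  write.csv(metrics@confusion, file.path(outDir, "confusion.csv"))
  plotImportanceMap(metrics@confusion, file.path(outDir, "confusion.png"),
                    main = "median row-normalized confusion (%)")
  write.csv(sm$summary, file.path(outDir, "importance_summary.csv"),
            row.names = FALSE)
  plotImportanceMap(sm$summary,
                    file.path(outDir, "importance_summary.png"))
  cat("run completed\n", file = log, append = TRUE)
  invisible(list(features = fm, metrics = metrics, importance = it))
}

#' Render an importance map as a PNG heatmap
#'
#' @param map 50 x 35 numeric matrix.
#' @param path output PNG path.
#' @param main plot title.
#' @return Invisibly, \code{path}.
#' @export
plotImportanceMap <- function(map, path, main = "spatial importance") {
  grDevices::png(path, width = 420, height = 600)
  op <- graphics::par(mar = c(2, 2, 3, 1))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  # image() draws x along rows; transpose and flip so row 1 is at the top
  graphics::image(t(map[rev(seq_len(nrow(map))), ]),
                  col = grDevices::hcl.colors(64, "inferno"), main = main,
                  axes = FALSE)
  invisible(path)
}

#' Write / read a recording container
#'
#' One self-describing file per trial holding the five channel stacks and
#' the trial metadata (RDS serialization of the S4 object).
#'
#' @param rec a \code{\linkS4class{MultispectralRecording}}.
#' @param path file path.
#' @return \code{readRecording} returns the recording.
#' @export
writeRecording <- function(rec, path) {
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  rec <- readRDS(path)
  if (!is(rec, "MultispectralRecording")) {
    stop("not a recording container: ", path)
  }
  rec
}
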