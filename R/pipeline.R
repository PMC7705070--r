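.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[floravision] %-12s ok (%.2fs)", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Default pipeline run configuration
#'
#' @param input either `list(type = "synthetic", study = <study config>)`
#'   (see [defaultStudyConfig()]) or
#'   `list(type = "files", spectra = <csv>, metadata = <csv>)`.
#' @param viewers viewer labels for [buildViewer()].
#' @param thresholds optional named overrides of viewer thresholds.
#' @param scheme grouping scheme for [regroupMixedSystems()].
#' @param outDir output directory.
#' @param seed integer seed (propagated to a synthetic study config).
#' @return Configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(input = list(type = "synthetic",
                                        study = defaultStudyConfig()),
                           viewers = c("bee", "bird_VS"),
                           thresholds = NULL,
                           scheme = "main",
                           outDir = tempfile("floravision_run_"),
                           seed = 1) {
  list(input = input, viewers = viewers, thresholds = thresholds,
       scheme = scheme, outDir = outDir, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest/simulate, cleaning, colour-space modeling, pairwise
#' distances, fraction-discriminable tabulation, the mixed-model analysis and
#' the cross-space regression as one configured run. All outputs (cleaned
#' spectra, colour points, long-format distances, fraction tables, model
#' report, manifest) are written as CSV/JSON under `config$outDir`. The run
#' is a pure function of configuration and seed: rerunning with the same
#' configuration reproduces the outputs byte for byte.
#'
#' @param config a [pipelineConfig()] list, or the path to a YAML file
#'   holding one.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @examples
#' cfg <- pipelineConfig(
#'   input = list(type = "synthetic",
#'                study = defaultStudyConfig(nSpecies = c(Bee = 3, Bird = 3),
#'                                           flowersPerPopulation = 5)))
#' \donttest{man <- runPipeline(cfg)}
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(length(config$viewers) >= 1L)
  if (!is.null(config$thresholds) && any(unlist(config$thresholds) <= 0))
    stop("thresholds must be positive")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outDir, ...)

  ds <- .stage("ingest", {
    inp <- config$input
    if (identical(inp$type, "synthetic")) {
      study <- inp$study %||% defaultStudyConfig()
      if (!is.null(config$seed)) study$seed <- config$seed
      simulateStudy(study)
    } else if (identical(inp$type, "files")) {
      readSpectra(inp$spectra, inp$metadata)
    } else stop("unknown input type: ", inp$type)
  })

  ds <- .stage("clean", cleanSpectra(ds))
  writeSpectra(ds, out("cleaned_spectra.csv"), out("metadata.csv"))

  viewers <- .stage("viewers", lapply(config$viewers, function(lbl) {
    v <- buildViewer(lbl, grid = wavelengths(ds))
    thr <- config$thresholds[[lbl]]
    if (!is.null(thr)) v@threshold <- thr
    v
  }))

  .stage("colorpoints", for (v in viewers)
    write.csv(colorPoints(ds, v),
              out(sprintf("color_points_%s.csv", v@label)),
              row.names = FALSE))

  summ <- .stage("fractions", summarizeStudy(ds, viewers))
  write.csv(populationFractions(summ), out("fractions_populations.csv"),
            row.names = FALSE)
  write.csv(speciesFractions(summ), out("fractions_species.csv"),
            row.names = FALSE)
  write.csv(studyMeans(summ), out("fractions_study.csv"), row.names = FALSE)

  .stage("distances", {
    long <- list()
    for (v in viewers) for (p in populationIds(ds)) {
      d <- pairwiseDistances(populationSubset(ds, p), v)
      ut <- which(upper.tri(d@distances), arr.ind = TRUE)
      long[[length(long) + 1L]] <- data.frame(
        population_id = p, viewer_label = v@label,
        flower_a = d@flower_ids[ut[, 1L]], flower_b = d@flower_ids[ut[, 2L]],
        distance = d@distances[ut])
    }
    write.csv(do.call(rbind, long), out("pairwise_distances.csv"),
              row.names = FALSE)
  })

  report <- .stage("models", {
    # the mixed model contrasts one bee viewer against one bird viewer;
    # additional bird phenotypes (e.g. UVS robustness runs) are tabulated in
    # the fraction tables but the primary model uses the first bird viewer
    firstBird <- config$viewers[config$viewers != "bee"][1L]
    keep <- c("bee", firstBird)
    vt <- regroupMixedSystems(variationTable(summ), config$scheme %||% "main")
    vt <- vt[vt$viewer_label %in% keep, , drop = FALSE]
    fit <- fitVariationModel(vt)
    reg <- regressAcrossSpaces(vt)
    sat <- saturationTable(ds, viewers[vapply(viewers, function(v)
      v@label %in% keep, logical(1L))])
    satFit <- fitSaturationModel(
      regroupMixedSystems(sat, config$scheme %||% "main"))
    list(
      variation = list(lrt = lrtTable(fit), contrasts = contrastTable(fit),
                       cell_means = cellMeans(fit),
                       fixed_effects = fit@fixedEffects),
      regression = reg,
      saturation = list(lrt = lrtTable(satFit),
                        contrasts = contrastTable(satFit)))
  })
  jsonlite::write_json(report, out("model_report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  manifest <- .stage("manifest", {
    cfgPath <- out("config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    m <- list(
      package_version = as.character(utils::packageVersion("floravision")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfgPath)),
      n_flowers = ncol(ds),
      n_populations = length(populationIds(ds)),
      viewers = vapply(viewers, function(v) v@label, character(1L)),
      outputs = list.files(config$outDir))
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    m
  })
  invisible(manifest)
}
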