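#' @include AllClasses.R
NULL

#' Build a pipeline run configuration
#'
#' A declarative description of one pipeline run: which stages execute,
#' the simulated conditions (one offspring-concentration level per named
#' condition, the first being the control used for normalization), the
#' stage parameters, and the master seed. Every stage parameter has a
#' default matching the standard protocol; the whole configuration
#' round-trips through JSON serialization.
#'
#' @param stages character subset of `"simulate"`, `"clusterIndex"`,
#'   `"clusterAreas"`, `"coverage"`, `"emSpacing"`.
#' @param seed master integer seed; per-scene seeds are derived from it.
#' @param nNuclei nuclei simulated per condition.
#' @param conditions named numeric vector of offspring concentrations;
#'   the first name is the control condition.
#' @param coverageFraction generated granule coverage for the coverage
#'   stage.
#' @param binEdges cluster-area histogram bin edges (square micron).
#' @param projectionDepth clustering-index projection depth (micron).
#' @param emLength,emRate EM-profile contour length (micron) and pore
#'   rate (per micron).
#' @param emBinEdges spacing-histogram bin edges (micron).
#' @return a `list` of class `poreQuantConfig`.
#' @export
runConfig <- function(stages = c("simulate", "clusterIndex",
                                 "clusterAreas", "coverage", "emSpacing"),
                      seed = 1L, nNuclei = 5L,
                      conditions = c(control = 20, uniform = 0),
                      coverageFraction = 1, binEdges = c(0, 0.5, 1, 1.5, 2, 4),
                      projectionDepth = NULL, emLength = 100, emRate = 2,
                      emBinEdges = seq(0, 2, by = 0.25)) {
  known <- c("simulate", "clusterIndex", "clusterAreas", "coverage",
             "emSpacing")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named vector")
  cfg <- list(stages = stages, seed = as.integer(seed),
              nNuclei = as.integer(nNuclei),
              conditions = lapply(as.list(conditions), as.numeric),
              coverageFraction = coverageFraction, binEdges = binEdges,
              projectionDepth = projectionDepth,
              emLength = emLength, emRate = emRate,
              emBinEdges = emBinEdges)
  class(cfg) <- "poreQuantConfig"
  cfg
}

#' Serialize / deserialize a run configuration
#'
#' @param config a `poreQuantConfig`.
#' @param path JSON file path.
#' @return `readRunConfig` returns the configuration; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, raw[!vapply(raw, is.null, TRUE) |
                           names(raw) == "projectionDepth"])
}

#' Hash of a run configuration
#'
#' MD5 over the canonical JSON serialization; stamped on every output row
#' so each measurement is traceable to the exact configuration that
#' produced it.
#'
#' @param config a `poreQuantConfig`.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeRunConfig(config, tf)
  unname(tools::md5sum(tf))
}

#' Execute a configured pipeline run
#'
#' Simulates the configured conditions, runs the requested measurement
#' stages, and returns one tidy measurement table (one row per metric per
#' entity, stamped with the config hash). When `outputDir` is given, the
#' table and per-stage histograms are also written as CSV, plus the
#' configuration itself. Identical configuration implies identical
#' outputs.
#'
#' @param config a `poreQuantConfig` from [runConfig()].
#' @param outputDir optional output directory (created if missing).
#' @return data.frame with columns `id`, `group`, `stage`, `metric`,
#'   `value`, `unit`, `configHash`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  stopifnot(inherits(config, "poreQuantConfig"))
  hash <- configHash(config)
  rows <- list()
  addRow <- function(id, group, stage, metric, value, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, group = group, stage = stage, metric = metric,
      value = value, unit = unit, configHash = hash)
  }
  histTables <- list()
  conds <- config$conditions
  needsScenes <- any(c("clusterIndex", "clusterAreas", "coverage") %in%
                       config$stages)
  if (needsScenes && !"simulate" %in% config$stages)
    stop("measurement stages require the 'simulate' stage")
  if (needsScenes) {
    raw <- list()
    allAreas <- list()
    sceneIdx <- 0L
    for (ci in seq_along(conds)) {
      cname <- names(conds)[ci]
      kappa <- conds[[ci]]
      for (i in seq_len(config$nNuclei)) {
        sceneIdx <- sceneIdx + 1L
        sc <- simulateScene(
          clusterParams = ClusterProcessParams(
            offspringConcentration = kappa),
          granuleParams = GranuleParams(
            coverageFraction = config$coverageFraction),
          seed = config$seed + 1000L * sceneIdx)
        id <- sprintf("%s_%02d", cname, i)
        vz <- sc@truth$optics$voxelSizeZ
        proj <- maxProject(sc@stack[, , , 1L],
                           depth = config$projectionDepth, voxelSizeZ = vz)
        if ("clusterIndex" %in% config$stages)
          raw[[length(raw) + 1L]] <- data.frame(
            id = id, group = cname, raw = clusteringIndex(proj))
        if ("clusterAreas" %in% config$stages) {
          cs <- segmentClusters(proj,
                                pixelSizeXY = sc@truth$optics$voxelSizeXY)
          allAreas[[length(allAreas) + 1L]] <-
            data.frame(group = cname, area = clusterAreas(cs))
          addRow(id, cname, "clusterAreas", "nClusters",
                 length(clusterAreas(cs)), "count")
        }
        if ("coverage" %in% config$stages) {
          cov <- measureSceneCoverage(sc)
          addRow(id, cname, "coverage", "largeClusterCoverage",
                 cov$fraction, "fraction")
        }
      }
    }
    if ("clusterIndex" %in% config$stages) {
      rawTab <- do.call(rbind, raw)
      norm <- normalizeToControl(rawTab$raw, rawTab$group,
                                 control = names(conds)[1])
      for (j in seq_len(nrow(rawTab))) {
        addRow(rawTab$id[j], rawTab$group[j], "clusterIndex", "raw",
               rawTab$raw[j], "intensity")
        addRow(rawTab$id[j], rawTab$group[j], "clusterIndex", "normalized",
               norm$normalized[j], "dimensionless")
      }
    }
    if ("clusterAreas" %in% config$stages && length(allAreas)) {
      areaTab <- do.call(rbind, allAreas)
      hists <- lapply(split(areaTab$area, areaTab$group), function(a)
        clusterAreaHistogram(a, config$binEdges))
      for (g in names(hists)) hists[[g]]$group <- g
      histTables$cluster_area_hist <- do.call(rbind, hists)
    }
  }
  if ("emSpacing" %in% config$stages) {
    prof <- sampleEmPositions(config$emLength, config$emRate,
                              seed = config$seed + 7L)
    gaps <- adjacentDistances(prof)
    addRow("em_profile", "em", "emSpacing", "meanGap", mean(gaps), "um")
    addRow("em_profile", "em", "emSpacing", "nPores",
           length(porePositions(prof)), "count")
    histTables$em_spacing_hist <- spacingHistogram(gaps, config$emBinEdges)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outputDir, "measurements.csv"),
                     row.names = FALSE)
    for (nm in names(histTables))
      utils::write.csv(histTables[[nm]],
                       file.path(outputDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    writeRunConfig(config, file.path(outputDir, "config.json"))
  }
  attr(tab, "histograms") <- histTables
  tab
}
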