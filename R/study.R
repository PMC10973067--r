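## The four-case study workflow: complex/trimmed x physiological/pathological.

#' Construct a study configuration
#'
#' Defaults reproduce the study design: a 60-outlet complex model trimmed to
#' its 10 most prominent outlets, one aneurysm on the right MCA (IA-A) and
#' one on the left MCA (IA-B), 0.32 mm imaging, 2\% region growing,
#' Newtonian blood (4 mPa s, 1055 kg/m^3), 1 ms time steps over three
#' cycles with the last evaluated and Murray n = 2 outlet splitting.
#'
#' @param nOutlets,keep complex and trimmed outlet counts.
#' @param seed global seed; all stages derive their randomness from it.
#' @param spacing voxel spacing (mm) for the imaging stage.
#' @param noiseSd additive image noise (a.u.; lumen-background contrast is
#'   100).
#' @param lumenIntensity,backgroundIntensity phantom contrast (a.u.).
#' @param tolerance region-growing band (fraction of seed intensity).
#' @param skipImaging run the simulations on the template network directly.
#' @param period,pulsatility,nSamples inlet waveform parameters.
#' @param fluid a [FluidProperties-class].
#' @param solver a [SolverConfig-class].
#' @param aneurysms list of lists with fields label, trunk, arc, sacVolume,
#'   compliance, neckRatio, neckLength.
#' @return A [StudyConfig-class].
#' @export
studyConfig <- function(nOutlets = 60, keep = 10, seed = 1, spacing = 0.32,
                        noiseSd = 0, lumenIntensity = 100,
                        backgroundIntensity = 0, tolerance = 0.02,
                        skipImaging = FALSE, period = 1.0, pulsatility = 0.5,
                        nSamples = 201, fluid = fluidProperties(),
                        solver = solverConfig(),
                        aneurysms = list(
                          list(label = "IA-A", trunk = "MCA.r", arc = 0.5,
                               sacVolume = 100, compliance = 1e-12,
                               neckRatio = 1.0, neckLength = 1.0),
                          list(label = "IA-B", trunk = "MCA.l", arc = 0.5,
                               sacVolume = 100, compliance = 1e-12,
                               neckRatio = 1.0, neckLength = 1.0))) {
  new("StudyConfig", nOutlets = nOutlets, keep = keep, seed = seed,
      spacing = spacing, noiseSd = noiseSd,
      lumenIntensity = lumenIntensity,
      backgroundIntensity = backgroundIntensity, tolerance = tolerance,
      skipImaging = skipImaging, period = period, pulsatility = pulsatility,
      nSamples = nSamples, fluid = fluid, solver = solver,
      aneurysms = aneurysms)
}

# serialize a StudyConfig to a plain list (for the resolved-config JSON)
.config_to_list <- function(config) {
  list(nOutlets = config@nOutlets, keep = config@keep, seed = config@seed,
       spacing = config@spacing, noiseSd = config@noiseSd,
       lumenIntensity = config@lumenIntensity,
       backgroundIntensity = config@backgroundIntensity,
       tolerance = config@tolerance, skipImaging = config@skipImaging,
       period = config@period, pulsatility = config@pulsatility,
       nSamples = config@nSamples,
       fluid = list(mu_Pa_s = config@fluid@mu, rho_kg_m3 = config@fluid@rho),
       solver = list(dt_s = config@solver@dt, cycles = config@solver@cycles,
                     murray_n = config@solver@murrayN,
                     split_mode = config@solver@splitMode),
       aneurysms = config@aneurysms)
}

# world midpoint of a labelled trunk in the template
.trunk_midpoint <- function(template, trunk) {
  ed <- template@edges
  hit <- which(!is.na(ed$label) & ed$label == trunk)
  if (length(hit) == 0) stop(sprintf("no trunk labelled '%s'", trunk))
  segs <- .edge_segments(template)[hit, , drop = FALSE]
  pts <- rbind(segs[, 1:3], segs[, 4:6])
  colMeans(pts)
}

# attach the configured aneurysms to a network, locating each parent edge
# as the edge nearest the template trunk midpoint
.attach_study_aneurysms <- function(network, template, aneurysms) {
  for (a in aneurysms) {
    p <- .trunk_midpoint(template, a$trunk)
    ne <- nearestEdge(network, p)
    spec <- makeAneurysmSpec(network, ne$id,
                             arcPosition = if (is.null(a$arc)) ne$arcPosition else a$arc,
                             sacVolume = a$sacVolume,
                             compliance = a$compliance,
                             neckRatio = if (is.null(a$neckRatio)) 1.0 else a$neckRatio,
                             neckLength = if (is.null(a$neckLength)) 1.0 else a$neckLength,
                             label = a$label)
    network <- suppressWarnings(attachAneurysm(network, spec))
  }
  network
}

#' Run the full four-case study
#'
#' Executes phantom generation, (optionally) rasterization and the
#' segmentation-to-network chain, model trimming, aneurysm attachment,
#' the four pulsatile simulations (complex/trimmed x physiological/
#' pathological), metric evaluation and the two paired comparisons, and
#' writes every artifact plus a resolved config, a structured log and a
#' content-hash manifest to \code{outDir}. Re-running with the same config
#' reproduces all numeric outputs bit for bit.
#'
#' @param config a [StudyConfig-class].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the four [SimulationResult-class]s, the
#'   four [HemodynamicMetrics-class]s, the two [ComparisonReport-class]s
#'   and the output paths.
#' @export
runStudy <- function(config = studyConfig(), outDir = tempfile("cowstudy")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  stamp <- function(stage, t0) {
    line <- sprintf("%s: %.2f s", stage, as.numeric(Sys.time()) - t0)
    logLines <<- c(logLines, line)
    message("[runStudy] ", line)
  }

  t0 <- as.numeric(Sys.time())
  template <- generateCowTemplate(nOutlets = config@nOutlets,
                                  seed = config@seed)
  stamp("phantom", t0)

  if (config@skipImaging) {
    complexNet <- template
  } else {
    t0 <- as.numeric(Sys.time())
    ras <- rasterizeNetwork(template, spacing = config@spacing,
                            lumenIntensity = config@lumenIntensity,
                            backgroundIntensity = config@backgroundIntensity,
                            noiseSd = config@noiseSd, seed = config@seed)
    stamp("rasterize", t0)
    t0 <- as.numeric(Sys.time())
    inl <- inletNodes(template)
    seeds <- round(worldToVoxel(ras$volume,
                                as.matrix(inl[, c("x", "y", "z")])))
    presmooth <- if (config@noiseSd > 0) 1.0 else 0
    seg <- segmentVolume(ras$volume, seeds, tolerance = config@tolerance,
                         presmoothSigma = presmooth)
    stamp("segment", t0)
    t0 <- as.numeric(Sys.time())
    complexNet <- skeletonizeNetwork(seg,
                                     openings = openingsFromNetwork(template))
    stamp("network", t0)
  }

  trimmedNet <- trimNetwork(complexNet, config@keep)
  compPatho <- .attach_study_aneurysms(complexNet, template, config@aneurysms)
  trimPatho <- .attach_study_aneurysms(trimmedNet, template, config@aneurysms)

  inflows <- cowInflows(period = config@period,
                        pulsatility = config@pulsatility,
                        nSamples = config@nSamples)

  cases <- list(complex_physiological = complexNet,
                trimmed_physiological = trimmedNet,
                complex_pathological = compPatho,
                trimmed_pathological = trimPatho)
  results <- list()
  metrics <- list()
  for (nm in names(cases)) {
    t0 <- as.numeric(Sys.time())
    res <- solveUnsteady(cases[[nm]], inflows, config@fluid, config@solver)
    results[[nm]] <- res
    metrics[[nm]] <- computeMetrics(res, caseId = nm)
    stamp(paste0("simulate+metrics:", nm), t0)
  }

  repPhys <- compareModels(metrics$complex_physiological,
                           metrics$trimmed_physiological)
  repPath <- compareModels(metrics$complex_pathological,
                           metrics$trimmed_pathological)

  t0 <- as.numeric(Sys.time())
  paths <- character(0)
  save1 <- function(p) { paths <<- c(paths, p); p }
  writeNetworkJSON(complexNet, save1(file.path(outDir, "network_complex.json")))
  writeNetworkJSON(trimmedNet, save1(file.path(outDir, "network_trimmed.json")))
  writeNetworkJSON(compPatho, save1(file.path(outDir, "network_complex_pathological.json")))
  writeNetworkJSON(trimPatho, save1(file.path(outDir, "network_trimmed_pathological.json")))
  for (lab in names(inflows))
    writeWaveformCSV(inflows[[lab]],
                     save1(file.path(outDir, sprintf("inflow_%s.csv", lab))))
  for (nm in names(results)) {
    writeSimulationCSV(results[[nm]],
                       save1(file.path(outDir, sprintf("result_%s.csv", nm))))
    writeMetricsCSV(metrics[[nm]],
                    save1(file.path(outDir, sprintf("metrics_%s.csv", nm))))
  }
  writeComparisonJSON(repPhys,
                      save1(file.path(outDir, "comparison_physiological.json")))
  writeComparisonJSON(repPath,
                      save1(file.path(outDir, "comparison_pathological.json")))
  write.csv(branchSummary(complexNet, trimmedNet),
            save1(file.path(outDir, "branch_summary.csv")), row.names = FALSE)
  jsonlite::write_json(.config_to_list(config),
                       save1(file.path(outDir, "config.json")),
                       auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  writeLines(c(sprintf("cowflow %s, R %s",
                       as.character(utils::packageVersion("cowflow")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("seed: %d", as.integer(config@seed)), logLines),
             file.path(outDir, "run.log"))
  stamp("write-artifacts", t0)

  invisible(list(results = results, metrics = metrics,
                 reports = list(physiological = repPhys,
                                pathological = repPath),
                 networks = cases, outDir = outDir,
                 manifest = manifest))
}
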