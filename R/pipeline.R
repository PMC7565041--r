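#' Assemble and validate a pipeline run configuration
#'
#' Builds the fully resolved configuration driving
#' \code{\link{runPipeline}}. Every analysis output embeds this resolved
#' configuration (and the package version) in its run log. All validation
#' problems are reported in one aggregated error.
#'
#' @param seed integer master seed; every stochastic stage derives its
#'   seed from it.
#' @param outDir output directory.
#' @param genotypes genotype presets to simulate and compare (when no
#'   external inputs are given).
#' @param nGonads simulated gonad fields per genotype.
#' @param nDonorGonads donor-only fields for the tauD reference.
#' @param imageShape per-gonad field size in pixels.
#' @param totalPhotonBudget photons per field; the default keeps the
#'   standard acquisition's photon density (5e6 over 256 x 256) at any
#'   field size.
#' @param backgroundFraction,irfSigmaNs,irfCenterNs acquisition options,
#'   see \code{\link{acquisitionSpec}}.
#' @param donorLifetimeNs true/expected donor lifetime in ns.
#' @param nNuclei nuclei per simulated field.
#' @param fitModel,fitMethod,binRadius,minPhotons,background decay-fit
#'   options, see \code{\link{fitMap}}.
#' @param maskSource "truth" (simulator ground-truth nuclei) or
#'   "segmented" (automated segmentation of the intensity image).
#' @param classNames,classBoundaries FRET class scheme, see
#'   \code{\link{fretClassScheme}}.
#' @param tTestMode "student" or "welch".
#' @param writeMaps write per-gonad lifetime/FRET TIFF maps.
#' @return a validated list of class "flimfretConfig".
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("flimfret-run-"),
                      genotypes = c("wildtype-like",
                                    "compass-mutant-like"),
                      nGonads = 5L, nDonorGonads = 3L,
                      imageShape = c(128L, 128L),
                      totalPhotonBudget = NULL,
                      backgroundFraction = 0, irfSigmaNs = 0,
                      irfCenterNs = 0, donorLifetimeNs = 2.5,
                      nNuclei = 8L,
                      fitModel = "mono", fitMethod = "mle",
                      binRadius = 1L, minPhotons = 500,
                      background = "tail", maskSource = "truth",
                      classNames = c("sub-low", "low", "intermediate",
                                     "high"),
                      classBoundaries = c(0.05, 0.125, 0.25),
                      tTestMode = "student", writeMaps = FALSE) {
    if (is.null(totalPhotonBudget))
        totalPhotonBudget <- 5e6 * prod(imageShape) / (256 * 256)
    cfg <- list(seed = as.integer(seed), outDir = outDir,
                genotypes = genotypes, nGonads = as.integer(nGonads),
                nDonorGonads = as.integer(nDonorGonads),
                imageShape = as.integer(imageShape),
                totalPhotonBudget = totalPhotonBudget,
                backgroundFraction = backgroundFraction,
                irfSigmaNs = irfSigmaNs, irfCenterNs = irfCenterNs,
                donorLifetimeNs = donorLifetimeNs,
                nNuclei = as.integer(nNuclei),
                fitModel = fitModel, fitMethod = fitMethod,
                binRadius = as.integer(binRadius),
                minPhotons = minPhotons, background = background,
                maskSource = maskSource, classNames = classNames,
                classBoundaries = classBoundaries,
                tTestMode = tTestMode, writeMaps = isTRUE(writeMaps))
    problems <- character()
    chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
    chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed must be one integer")
    chk(cfg$nGonads >= 1L, "nGonads must be >= 1")
    chk(cfg$nDonorGonads >= 1L, "nDonorGonads must be >= 1")
    chk(length(cfg$imageShape) == 2L && all(cfg$imageShape >= 16L),
        "imageShape must be two integers >= 16")
    chk(cfg$totalPhotonBudget > 0, "totalPhotonBudget must be > 0")
    chk(cfg$backgroundFraction >= 0 && cfg$backgroundFraction < 1,
        "backgroundFraction must be in [0, 1)")
    chk(cfg$donorLifetimeNs > 0, "donorLifetimeNs must be > 0")
    chk(cfg$fitModel %in% c("mono", "bi"), "fitModel must be mono or bi")
    chk(cfg$fitMethod %in% c("mle", "ls"), "fitMethod must be mle or ls")
    chk(cfg$binRadius >= 0L, "binRadius must be >= 0")
    chk(cfg$background %in% c("tail", "fit", "none"),
        "background must be tail, fit or none")
    chk(cfg$maskSource %in% c("truth", "segmented"),
        "maskSource must be truth or segmented")
    chk(length(cfg$classBoundaries) == length(cfg$classNames) - 1L,
        "need one fewer class boundary than class names")
    chk(!is.unsorted(cfg$classBoundaries, strictly = TRUE),
        "class boundaries must be strictly increasing")
    chk(cfg$tTestMode %in% c("student", "welch"),
        "tTestMode must be student or welch")
    if (length(problems))
        stop("invalid run configuration:\n  - ",
             paste(problems, collapse = "\n  - "))
    class(cfg) <- "flimfretConfig"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields missing from the file take the \code{\link{runConfig}}
#' defaults; unknown fields are rejected.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file.
#' @return a validated configuration.
#' @export
readRunConfig <- function(path, ...) {
    y <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    bad <- setdiff(names(y), known)
    if (length(bad))
        stop("unknown config fields: ", paste(bad, collapse = ", "))
    args <- utils::modifyList(y, list(...))
    do.call(runConfig, args)
}

## deterministic sub-seed from the master seed, kept below 2^31
.subSeed <- function(seed, stream, i) {
    (as.numeric(seed) * 131071 + stream * 8191 + i) %% 2147483647
}

## simulate + analyze one gonad field; returns maps, profile, tables
.analyzeGonad <- function(cube, gonadId, cfg, ref = NULL) {
    mask <- if (cfg$maskSource == "truth") truthMask(cube, gonadId)
            else segmentNuclei(intensityImage(cube), gonadId = gonadId)
    ltm <- fitMap(cube, mask, model = cfg$fitModel,
                  method = cfg$fitMethod, binRadius = cfg$binRadius,
                  minPhotons = cfg$minPhotons,
                  background = cfg$background)
    out <- list(mask = mask, lifetimeMap = ltm)
    if (!is.null(ref)) {
        fm <- fretMap(ltm, ref)
        prof <- classifyFret(fm, fretClassScheme(cfg$classNames,
                                                 cfg$classBoundaries))
        out$fretMap <- fm
        out$profile <- prof
    }
    out
}

#' Genotype comparison table
#'
#' Two-tailed unpaired t tests between two genotypes on the per-gonad
#' mean FRET efficiency and on each per-gonad FRET class fraction.
#'
#' @param gonadTable data.frame with columns genotype, meanE and one
#'   column per class fraction (as produced by \code{\link{runPipeline}}).
#' @param classNames class fraction columns to test.
#' @param mode "student" or "welch".
#' @return data.frame: metric, group1, group2, mean1, mean2, statistic,
#'   p.value.
#' @export
compareGenotypes <- function(gonadTable,
                             classNames = c("sub-low", "low",
                                            "intermediate", "high"),
                             mode = "student") {
    gt <- unique(gonadTable$genotype)
    if (length(gt) != 2L) stop("need exactly 2 genotypes")
    metrics <- c("meanE", intersect(classNames, names(gonadTable)))
    do.call(rbind, lapply(metrics, function(mt) {
        g1 <- gonadTable[[mt]][gonadTable$genotype == gt[1]]
        g2 <- gonadTable[[mt]][gonadTable$genotype == gt[2]]
        tt <- tTestGroups(stats::setNames(list(g1, g2), gt), mode = mode)
        data.frame(metric = mt, group1 = gt[1], group2 = gt[2],
                   mean1 = mean(g1), mean2 = mean(g2),
                   statistic = tt$statistic, p.value = tt$p.value)
    }))
}

#' Run the full simulate-fit-FRET-classify-compare pipeline
#'
#' Orchestrates the whole analysis on synthetic genotype presets (or on
#' supplied photon cubes + masks): donor-only fields establish the tauD
#' reference by mono-exponential fitting; each gonad field is fitted
#' per pixel, converted to a FRET efficiency map, and decomposed into
#' FRET population fractions; genotypes are compared by two-tailed
#' unpaired t tests on per-gonad mean E and class fractions.
#'
#' Outputs written under \code{config$outDir}: \code{roi_table.csv} (one
#' row per nucleus ROI), \code{gonad_table.csv} (one row per gonad),
#' \code{stats_table.csv} (the genotype comparison), \code{run_log.txt}
#' (resolved configuration + package version), and when
#' \code{writeMaps} is set, per-gonad lifetime and FRET TIFF maps under
#' \code{maps/}. Re-running with the same configuration reproduces the
#' CSVs bit for bit.
#'
#' @param config a configuration from \code{\link{runConfig}}.
#' @param inputs optional named list of lists with elements \code{cube}
#'   (\linkS4class{PhotonCube}), \code{mask} (\linkS4class{RoiMask}),
#'   \code{genotype}, \code{gonadId}, plus \code{donor = TRUE} entries
#'   for donor-only fields; when NULL everything is simulated from the
#'   presets in \code{config}.
#' @return invisibly, a list with donorReference, roiTable, gonadTable,
#'   statsTable, and the output paths.
#' @export
runPipeline <- function(config, inputs = NULL) {
    if (!inherits(config, "flimfretConfig"))
        stop("config must come from runConfig()/readRunConfig()")
    cfg <- config
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    mkAcq <- function() acquisitionSpec(
        imageShape = cfg$imageShape,
        totalPhotonBudget = cfg$totalPhotonBudget,
        backgroundFraction = cfg$backgroundFraction,
        irfSigmaNs = cfg$irfSigmaNs, irfCenterNs = cfg$irfCenterNs)

    if (is.null(inputs)) {
        donorCubes <- lapply(seq_len(cfg$nDonorGonads), function(i)
            simulateScene(genotypePreset(
                "donor-only", seed = .subSeed(cfg$seed, 1L, i),
                acquisition = mkAcq(), nNuclei = cfg$nNuclei,
                donorLifetimeNs = cfg$donorLifetimeNs)))
        names(donorCubes) <- paste0("donor", seq_along(donorCubes))
        sampleCubes <- list()
        for (g in seq_along(cfg$genotypes))
            for (i in seq_len(cfg$nGonads)) {
                id <- paste0(cfg$genotypes[g], "-gonad", i)
                sampleCubes[[id]] <- list(
                    cube = simulateScene(genotypePreset(
                        cfg$genotypes[g],
                        seed = .subSeed(cfg$seed, 10L + g, i),
                        acquisition = mkAcq(), nNuclei = cfg$nNuclei,
                        donorLifetimeNs = cfg$donorLifetimeNs)),
                    genotype = cfg$genotypes[g], gonadId = id)
            }
    } else {
        donor <- vapply(inputs, function(x) isTRUE(x$donor), logical(1))
        donorCubes <- lapply(inputs[donor], `[[`, "cube")
        names(donorCubes) <- vapply(inputs[donor], function(x)
            x$gonadId, character(1))
        sampleCubes <- inputs[!donor]
    }

    ## donor reference from mono-exponential fits of donor-only fields
    donorMaps <- lapply(names(donorCubes), function(id)
        .analyzeGonad(donorCubes[[id]], id, cfg)$lifetimeMap)
    ref <- donorReference(donorMaps)

    roiRows <- list(); gonadRows <- list()
    mapsDir <- file.path(cfg$outDir, "maps")
    if (cfg$writeMaps) dir.create(mapsDir, showWarnings = FALSE)
    for (id in names(sampleCubes)) {
        s <- sampleCubes[[id]]
        res <- .analyzeGonad(s$cube, s$gonadId, cfg, ref = ref)
        ts <- roiSummary(res$lifetimeMap)
        es <- roiSummary(res$fretMap)
        fr <- classFractions(res$profile)
        prof <- res$profile
        m <- merge(ts, es[, c("roi", "meanE", "medianE")], by = "roi")
        m$genotype <- s$genotype
        frDf <- as.data.frame(fr)
        frDf$roi <- prof@roiInfo$roi
        m <- merge(m, frDf, by = "roi", all.x = TRUE)
        roiRows[[id]] <- m

        gfr <- gonadClassFractions(prof)
        g <- data.frame(gonadId = s$gonadId, genotype = s$genotype,
                        pixelCount = sum(es$pixelCount),
                        meanTauNs = stats::weighted.mean(
                            ts$meanTauNs, ts$pixelCount, na.rm = TRUE),
                        meanE = stats::weighted.mean(
                            es$meanE, es$pixelCount, na.rm = TRUE))
        gonadRows[[id]] <- cbind(g, gfr[, cfg$classNames, drop = FALSE])

        if (cfg$writeMaps) {
            writeMapTiff(res$lifetimeMap,
                         file.path(mapsDir, paste0(id, "_tau.tif")))
            writeMapTiff(res$fretMap,
                         file.path(mapsDir, paste0(id, "_E.tif")))
        }
    }
    roiTable <- do.call(rbind, roiRows)
    rownames(roiTable) <- NULL
    gonadTable <- do.call(rbind, gonadRows)
    rownames(gonadTable) <- NULL

    statsTable <- if (length(unique(gonadTable$genotype)) == 2L)
        compareGenotypes(gonadTable, classNames = cfg$classNames,
                         mode = cfg$tTestMode)
    else NULL

    paths <- list(roi = file.path(cfg$outDir, "roi_table.csv"),
                  gonad = file.path(cfg$outDir, "gonad_table.csv"),
                  stats = file.path(cfg$outDir, "stats_table.csv"),
                  log = file.path(cfg$outDir, "run_log.txt"))
    utils::write.csv(roiTable, paths$roi, row.names = FALSE)
    utils::write.csv(gonadTable, paths$gonad, row.names = FALSE)
    if (!is.null(statsTable))
        utils::write.csv(statsTable, paths$stats, row.names = FALSE)
    writeLines(c(
        paste0("flimfret ",
               as.character(utils::packageVersion("flimfret"))),
        sprintf("tauD reference: %.6f ns (dispersion %.6g ns, %d ROIs)",
                tauD(ref), ref@dispersionNs, nrow(ref@source)),
        "resolved configuration:",
        yaml::as.yaml(unclass(cfg))), paths$log)

    invisible(list(donorReference = ref, roiTable = roiTable,
                   gonadTable = gonadTable, statsTable = statsTable,
                   paths = paths, config = cfg))
}
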