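#' Write / read a photon cube container
#'
#' Serializes a \linkS4class{PhotonCube} as a directory: \code{counts.tif}
#' (multi-page 16-bit grey TIFF, one page per time bin, row-major (y, x)
#' pixel convention), \code{meta.json} (acquisition settings, seed, class
#' table), and when ground truth is present \code{truth_labels.tif},
#' \code{truth_nuclei.tif} (16-bit label images) and \code{truth_E.tif}
#' (efficiency scaled by the factor recorded in \code{meta.json}).
#'
#' @param cube a \linkS4class{PhotonCube}.
#' @param path directory to create/overwrite.
#' @return \code{writePhotonCube}: invisibly the path;
#'   \code{readPhotonCube}: the restored cube.
#' @export
writePhotonCube <- function(cube, path) {
    stopifnot(is(cube, "PhotonCube"))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    cnt <- photonCounts(cube)
    if (max(cnt) > 65535)
        stop("per-bin counts exceed 16-bit storage")
    pages <- lapply(seq_len(dim(cnt)[3]), function(b) cnt[, , b] / 65535)
    tiff::writeTIFF(pages, file.path(path, "counts.tif"),
                    bits.per.sample = 16L, compression = "none")
    acq <- acquisition(cube)
    meta <- list(
        format = "flimfret-photon-cube-v1",
        nTimeBins = acq@nTimeBins, periodNs = acq@periodNs,
        binWidthNs = acq@periodNs / acq@nTimeBins,
        imageShape = acq@imageShape,
        totalPhotonBudget = acq@totalPhotonBudget,
        backgroundFraction = acq@backgroundFraction,
        irfSigmaNs = acq@irfSigmaNs, irfCenterNs = acq@irfCenterNs,
        seed = cube@seed, eScale = 4)
    tr <- groundTruth(cube)
    if (length(tr)) {
        meta$classNames <- tr$classNames
        meta$classE <- tr$classE
        meta$donorLifetimeNs <- tr$donorLifetimeNs
        meta$genotypePreset <- tr$genotypePreset
        tiff::writeTIFF(tr$classLabels / 65535,
                        file.path(path, "truth_labels.tif"),
                        bits.per.sample = 16L, compression = "none")
        tiff::writeTIFF(tr$nucleusLabels / 65535,
                        file.path(path, "truth_nuclei.tif"),
                        bits.per.sample = 16L, compression = "none")
        ## E in (-1, 1): store (E + 1)/eScale in [0, 1); NA -> 0 page 2
        eimg <- tr$trueE
        na <- is.na(eimg)
        eimg[na] <- 0
        tiff::writeTIFF(list((eimg + 1) / meta$eScale, 1 - na * 1),
                        file.path(path, "truth_E.tif"),
                        bits.per.sample = 32L, compression = "none")
    }
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePhotonCube
#' @export
readPhotonCube <- function(path) {
    metaPath <- file.path(path, "meta.json")
    if (!file.exists(metaPath))
        stop("not a photon-cube container: missing meta.json in ", path)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    cntPath <- file.path(path, "counts.tif")
    if (!file.exists(cntPath))
        stop("corrupt photon-cube container: missing counts.tif")
    pages <- tiff::readTIFF(cntPath, all = TRUE, as.is = TRUE)
    if (length(pages) != meta$nTimeBins)
        stop("corrupt photon-cube container: expected ", meta$nTimeBins,
             " pages in counts.tif, found ", length(pages))
    d <- c(dim(pages[[1]]), length(pages))
    cnt <- array(0L, dim = d)
    for (b in seq_along(pages)) cnt[, , b] <- as.integer(pages[[b]])
    acq <- acquisitionSpec(nTimeBins = meta$nTimeBins,
                           periodNs = meta$periodNs,
                           imageShape = d[1:2],
                           totalPhotonBudget = meta$totalPhotonBudget,
                           backgroundFraction = meta$backgroundFraction,
                           irfSigmaNs = meta$irfSigmaNs,
                           irfCenterNs = meta$irfCenterNs)
    truth <- list()
    labPath <- file.path(path, "truth_labels.tif")
    if (file.exists(labPath)) {
        clsLab <- tiff::readTIFF(labPath, as.is = TRUE)
        nucLab <- tiff::readTIFF(file.path(path, "truth_nuclei.tif"),
                                 as.is = TRUE)
        ep <- tiff::readTIFF(file.path(path, "truth_E.tif"), all = TRUE)
        eimg <- ep[[1]] * meta$eScale - 1
        eimg[ep[[2]] < 0.5] <- NA_real_
        truth <- list(classLabels = matrix(as.integer(clsLab), d[1], d[2]),
                      classNames = meta$classNames,
                      trueE = eimg,
                      nucleusLabels = matrix(as.integer(nucLab),
                                             d[1], d[2]),
                      classE = meta$classE,
                      donorLifetimeNs = meta$donorLifetimeNs,
                      genotypePreset = meta$genotypePreset)
    }
    new("PhotonCube", counts = cnt, acquisition = acq, truth = truth,
        seed = if (is.null(meta$seed)) NA_integer_
               else as.integer(meta$seed))
}

#' Export a per-pixel map as 32-bit TIFF
#'
#' Writes a lifetime or efficiency map as a two-page float TIFF: page 1
#' holds the values mapped linearly from [lo, hi] to [0, 1] (the range is
#' recorded in a JSON sidecar next to the image), page 2 a defined-pixel
#' mask. NA pixels are 0 in both pages.
#'
#' @param map a \linkS4class{PixelLifetimeMap} or
#'   \linkS4class{FretEfficiencyMap} (or a plain numeric matrix).
#' @param path output .tif path; the sidecar is \code{<path>.json}.
#' @param range optional c(lo, hi); default spans the finite values.
#' @return invisibly the path.
#' @export
writeMapTiff <- function(map, path, range = NULL) {
    m <- if (is(map, "PixelLifetimeMap")) lifetimeValues(map)
         else if (is(map, "FretEfficiencyMap")) efficiencyValues(map)
         else map
    fin <- is.finite(m)
    if (is.null(range)) {
        range <- if (any(fin)) grDevices::extendrange(m[fin], f = 0.001)
                 else c(0, 1)
        if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
    }
    v <- (m - range[1]) / (range[2] - range[1])
    v[!fin] <- 0
    tiff::writeTIFF(list(pmin(pmax(v, 0), 1), fin * 1), path,
                    bits.per.sample = 32L, compression = "none")
    jsonlite::write_json(list(lo = range[1], hi = range[2]),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeMapTiff
#' @return \code{readMapTiff}: numeric matrix with NA at undefined pixels.
#' @export
readMapTiff <- function(path) {
    pg <- tiff::readTIFF(path, all = TRUE)
    sc <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
    m <- pg[[1]] * (sc$hi - sc$lo) + sc$lo
    m[pg[[2]] < 0.5] <- NA_real_
    m
}
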