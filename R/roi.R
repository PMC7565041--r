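#' Construct an ROI label mask
#'
#' @param labels integer matrix; 0 = background, k = nucleus k. Labels
#'   need not be contiguous: non-contiguous labels are remapped to 1..n
#'   and the mapping is reported in a message.
#' @param gonadId gonad identifier (recycled over labels).
#' @param stageTag stage annotation, e.g. "pachytene".
#' @param source "manual", "segmented", or "truth". Manual masks are the
#'   first-class input (the assay segments nuclei by hand to exclude
#'   autofluorescent surroundings); automated masks are flagged.
#' @return a \linkS4class{RoiMask}.
#' @export
roiMask <- function(labels, gonadId = "gonad1", stageTag = "pachytene",
                    source = "manual") {
    labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
    u <- sort(unique(labels[labels > 0L]))
    if (length(u) && !identical(u, seq_along(u))) {
        remap <- integer(max(u))
        remap[u] <- seq_along(u)
        labels[labels > 0L] <- remap[labels[labels > 0L]]
        message("relabeled ROIs to contiguous 1..", length(u), ": ",
                paste(u, "->", seq_along(u), collapse = ", "))
        u <- seq_along(u)
    }
    md <- data.frame(label = u,
                     gonadId = rep_len(gonadId, length(u)),
                     stageTag = rep_len(stageTag, length(u)))
    new("RoiMask", labels = labels, metadata = md, source = source)
}

#' Read / write ROI masks as label images
#'
#' Round-trip serialization of label masks as 16-bit grey TIFF or PNG.
#' Pixel convention: 0-based coordinates, row-major (y, x); image row 1 is
#' mask row 1.
#'
#' @param path file path ending in .tif/.tiff or .png.
#' @param mask a \linkS4class{RoiMask}.
#' @param ... passed to \code{\link{roiMask}} when loading (gonadId,
#'   stageTag, source).
#' @return \code{loadMask}: a \linkS4class{RoiMask}; \code{saveMask}:
#'   invisibly, the path.
#' @export
saveMask <- function(mask, path) {
    stopifnot(is(mask, "RoiMask"))
    lab <- roiLabels(mask)
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        if (max(lab) > 255L) stop("PNG masks support at most 255 labels")
        png::writePNG(lab / 255, path)           # 8-bit grey PNG
    } else {
        if (max(lab) > 65535L)
            stop("more labels than a 16-bit image can hold")
        tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L,
                        compression = "none")
    }
    invisible(path)
}

#' @rdname saveMask
#' @export
loadMask <- function(path, ...) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        img <- png::readPNG(path)                # values are label/255
        if (length(dim(img)) == 3L) img <- img[, , 1]
        img <- round(img * 255)
    } else {
        img <- tiff::readTIFF(path, as.is = TRUE)
        if (length(dim(img)) == 3L) img <- img[, , 1]
    }
    roiMask(img, ...)
}

#' Automated nucleus segmentation
#'
#' Convenience substitute for manual nucleus outlining: Otsu threshold on
#' the (smoothed) intensity image, connected components, a
#' distance-map/watershed split of touching nuclei, and removal of
#' objects below \code{minArea}. Deterministic for fixed inputs and
#' parameters. The resulting mask is flagged \code{source = "segmented"}
#' so downstream tables can distinguish it from manual ROIs.
#'
#' @param intensity 2-D numeric intensity image (e.g.
#'   \code{intensityImage(cube)}).
#' @param minArea minimum object area in pixels (default 30).
#' @param thresholdMethod currently "otsu".
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @param watershedSplit split touching objects via the distance-map
#'   watershed (default TRUE).
#' @param ... passed to \code{\link{roiMask}}.
#' @return a \linkS4class{RoiMask}; empty (all-zero, with a warning) when
#'   nothing is found.
#' @export
segmentNuclei <- function(intensity, minArea = 30,
                          thresholdMethod = c("otsu"),
                          smoothSigma = 1, watershedSplit = TRUE, ...) {
    thresholdMethod <- match.arg(thresholdMethod)
    stopifnot(length(dim(intensity)) == 2L)
    img <- intensity / max(intensity, 1e-12)
    if (max(intensity) <= 0) {
        warning("blank image: empty mask")
        return(roiMask(matrix(0L, nrow(img), ncol(img)),
                       source = "segmented", ...))
    }
    eimg <- EBImage::Image(img)
    if (smoothSigma > 0)
        eimg <- EBImage::gblur(eimg, sigma = smoothSigma)
    thr <- EBImage::otsu(eimg, range = c(0, 1))
    bin <- eimg > thr
    lab <- if (watershedSplit)
        EBImage::watershed(EBImage::distmap(bin), tolerance = 1)
    else EBImage::bwlabel(bin)
    lab <- EBImage::imageData(lab)
    ## drop small objects
    sz <- tabulate(lab[lab > 0])
    drop <- which(sz < minArea)
    if (length(drop)) lab[lab %in% drop] <- 0L
    if (!any(lab > 0)) {
        warning("no object above minArea: empty mask")
        return(roiMask(matrix(0L, nrow(lab), ncol(lab)),
                       source = "segmented", ...))
    }
    suppressMessages(roiMask(lab, source = "segmented", ...))
}
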