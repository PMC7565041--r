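#' @name flimfret-accessors
#' @title Accessors for flimfret objects
#' @description Slot accessors for the core classes. Use these rather than
#'   \code{@} access; the slot layout is not part of the API.
#' @param object a flimfret S4 object.
NULL

#' @rdname flimfret-accessors
#' @export
setGeneric("photonCounts", function(object) standardGeneric("photonCounts"))

#' @rdname flimfret-accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' @rdname flimfret-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname flimfret-accessors
#' @export
setGeneric("intensityImage", function(object)
    standardGeneric("intensityImage"))

#' @rdname flimfret-accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname flimfret-accessors
#' @export
setGeneric("roiMetadata", function(object) standardGeneric("roiMetadata"))

#' @rdname flimfret-accessors
#' @export
setGeneric("lifetimeValues", function(object)
    standardGeneric("lifetimeValues"))

#' @rdname flimfret-accessors
#' @export
setGeneric("meanLifetime", function(object) standardGeneric("meanLifetime"))

#' @rdname flimfret-accessors
#' @export
setGeneric("efficiencyValues", function(object)
    standardGeneric("efficiencyValues"))

#' @rdname flimfret-accessors
#' @export
setGeneric("tauD", function(object) standardGeneric("tauD"))

#' @rdname flimfret-accessors
#' @export
setGeneric("roiSummary", function(object) standardGeneric("roiSummary"))

#' @rdname flimfret-accessors
#' @export
setGeneric("classFractions", function(object)
    standardGeneric("classFractions"))

#' @rdname flimfret-accessors
#' @export
setGeneric("fretClasses", function(object) standardGeneric("fretClasses"))

setMethod("photonCounts", "PhotonCube", function(object) object@counts)
setMethod("acquisition", "PhotonCube", function(object) object@acquisition)
setMethod("acquisition", "SceneSpec", function(object) object@acquisition)
setMethod("groundTruth", "PhotonCube", function(object) object@truth)
setMethod("intensityImage", "PhotonCube", function(object)
    rowSums(object@counts, dims = 2L))
setMethod("roiLabels", "RoiMask", function(object) object@labels)
setMethod("roiMetadata", "RoiMask", function(object) object@metadata)
setMethod("lifetimeValues", "PixelLifetimeMap", function(object) object@tau)
setMethod("meanLifetime", "FitResult", function(object)
    object@meanLifetimeNs)
setMethod("efficiencyValues", "FretEfficiencyMap", function(object)
    object@E)
setMethod("tauD", "DonorReference", function(object) object@tauDNs)
setMethod("tauD", "FretEfficiencyMap", function(object)
    object@donorReference@tauDNs)
setMethod("roiSummary", "PixelLifetimeMap", function(object)
    object@roiSummary)
setMethod("roiSummary", "FretEfficiencyMap", function(object)
    object@roiSummary)
setMethod("classFractions", "FretClassProfile", function(object)
    object@fractions)
setMethod("fretClasses", "FretClassScheme", function(object)
    object@classNames)
setMethod("fretClasses", "FretClassProfile", function(object)
    object@scheme@classNames)

setMethod("show", "AcquisitionSpec", function(object) {
    cat("AcquisitionSpec:", object@nTimeBins, "bins over",
        object@periodNs, "ns;",
        paste(object@imageShape, collapse = " x "), "pixels;",
        format(object@totalPhotonBudget, big.mark = ","), "photons/field\n")
    if (object@irfSigmaNs > 0)
        cat("  Gaussian IRF sigma =", object@irfSigmaNs, "ns at",
            object@irfCenterNs, "ns\n")
    if (object@backgroundFraction > 0)
        cat("  background fraction =", object@backgroundFraction, "\n")
})

setMethod("show", "PhotonCube", function(object) {
    d <- dim(object@counts)
    cat("PhotonCube:", d[1], "x", d[2], "pixels,", d[3], "time bins,",
        format(sum(object@counts), big.mark = ","), "photons\n")
    if (length(object@truth))
        cat("  ground truth present (classes:",
            paste(object@truth$classNames, collapse = ", "), ")\n")
    if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("%s-exponential fit: tau_m = %.4f ns", object@model,
                object@meanLifetimeNs))
    if (object@model == "bi")
        cat(sprintf(" [tau = %s ns, a = %s]",
                    paste(sprintf("%.3f", object@lifetimes), collapse = "/"),
                    paste(sprintf("%.2f", object@amplitudes),
                          collapse = "/")))
    cat(sprintf("\n  %d photons, red. chi^2 = %.2f, converged: %s%s\n",
                round(object@photonsUsed), object@reducedChiSq,
                object@converged,
                if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "RoiMask", function(object) {
    cat("RoiMask (", object@source, "): ",
        paste(dim(object@labels), collapse = " x "), " pixels, ",
        nrow(object@metadata), " ROIs\n", sep = "")
})

setMethod("show", "SceneSpec", function(object) {
    cat("SceneSpec [", object@genotypePreset, "]: ",
        nrow(object@nuclei), " nuclei, tauD = ",
        object@donorLifetimeNs, " ns, seed ", object@seed, "\n", sep = "")
    cat("  classes:", paste(sprintf("%s (E=%.3g)", object@classNames,
                                    object@classE), collapse = ", "), "\n")
})

setMethod("show", "PixelLifetimeMap", function(object) {
    cat("PixelLifetimeMap:", sum(!is.na(object@tau)), "fitted pixels over",
        nrow(object@roiSummary), "ROIs; model", object@model, "\n")
})

setMethod("show", "DonorReference", function(object) {
    cat(sprintf("DonorReference: tauD = %.4f ns (sd %.4g, n = %d ROIs)\n",
                object@tauDNs, object@dispersionNs, nrow(object@source)))
})

setMethod("show", "FretEfficiencyMap", function(object) {
    cat(sprintf(
        "FretEfficiencyMap: %d pixels, tauD = %.4f ns, mean E = %.4f\n",
        sum(!is.na(object@E)), object@donorReference@tauDNs,
        mean(object@E, na.rm = TRUE)))
})

setMethod("show", "FretClassScheme", function(object) {
    lo <- c(-Inf, object@boundaries)
    hi <- c(object@boundaries, 1)
    cat("FretClassScheme:\n")
    for (i in seq_along(object@classNames))
        cat(sprintf("  %-12s [%g, %g)\n", object@classNames[i],
                    lo[i], hi[i]))
})

setMethod("show", "FretClassProfile", function(object) {
    cat("FretClassProfile over", nrow(object@fractions), "ROIs\n")
    if (nrow(object@fractions)) {
        m <- colMeans(object@fractions)
        cat("  mean fractions:",
            paste(sprintf("%s %.3f", colnames(object@fractions), m),
                  collapse = ", "), "\n")
    }
})
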