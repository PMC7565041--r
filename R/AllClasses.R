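#' @import methods
NULL

#' TCSPC acquisition settings
#'
#' Describes one FLIM acquisition: the TCSPC time axis (number of bins over
#' one laser period), the image raster, the photon budget for a whole field,
#' the uniform (temporal) background fraction, and an optional Gaussian
#' instrument response function (IRF).
#'
#' Defaults follow a typical two-photon TCSPC setup for germline imaging:
#' an 80 MHz pulsed laser (12.5 ns period), 256 time bins, a 256 x 256 pixel
#' raster, and a field photon budget of 5e6 photons (about 8.5e4 detected
#' photons per second over a 60 s acquisition).
#'
#' @slot nTimeBins integer, number of TCSPC time bins (>= 8).
#' @slot periodNs laser repetition period in ns (> 0).
#' @slot imageShape integer(2), image height and width in pixels.
#' @slot totalPhotonBudget expected total photons per field (> 0).
#' @slot backgroundFraction fraction of photons that are uniform-in-time
#'   background, in [0, 1).
#' @slot irfSigmaNs Gaussian IRF standard deviation in ns; 0 means an ideal
#'   delta-function response.
#' @slot irfCenterNs position of the IRF peak on the time axis in ns.
#' @exportClass AcquisitionSpec
setClass("AcquisitionSpec",
    representation(
        nTimeBins = "integer",
        periodNs = "numeric",
        imageShape = "integer",
        totalPhotonBudget = "numeric",
        backgroundFraction = "numeric",
        irfSigmaNs = "numeric",
        irfCenterNs = "numeric"
    )
)

setValidity("AcquisitionSpec", function(object) {
    msg <- character()
    if (length(object@nTimeBins) != 1L || object@nTimeBins < 8L)
        msg <- c(msg, "nTimeBins must be a single integer >= 8")
    if (length(object@periodNs) != 1L || !is.finite(object@periodNs) ||
        object@periodNs <= 0)
        msg <- c(msg, "periodNs must be > 0")
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
        msg <- c(msg, "imageShape must be two positive integers")
    if (length(object@totalPhotonBudget) != 1L ||
        object@totalPhotonBudget <= 0)
        msg <- c(msg, "totalPhotonBudget must be > 0")
    if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
        msg <- c(msg, "backgroundFraction must lie in [0, 1)")
    if (object@irfSigmaNs < 0)
        msg <- c(msg, "irfSigmaNs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' A single FRET state (compaction class)
#'
#' One discrete FRET population: a class label, its true FRET efficiency E,
#' and the implied quenched donor lifetime tauDA = tauD * (1 - E).
#'
#' @slot label class name, e.g. "sub-low".
#' @slot trueE FRET efficiency in [0, 1).
#' @slot donorLifetimeNs unquenched donor lifetime tauD in ns.
#' @exportClass FretStateSpec
setClass("FretStateSpec",
    representation(
        label = "character",
        trueE = "numeric",
        donorLifetimeNs = "numeric"
    )
)

setValidity("FretStateSpec", function(object) {
    msg <- character()
    if (object@trueE < 0 || object@trueE >= 1)
        msg <- c(msg, "trueE must lie in [0, 1)")
    if (object@donorLifetimeNs <= 0)
        msg <- c(msg, "donorLifetimeNs must be > 0")
    if (length(msg)) msg else TRUE
})

#' Ground-truth description of a synthetic germline field
#'
#' Full recipe for one simulated gonad field: acquisition settings, the
#' unquenched donor lifetime, the class scheme (names and true E values),
#' the nuclei (disk centres, radii and per-class pixel mixing fractions),
#' a genotype preset tag and the RNG seed. Scene generation is a pure
#' function of this object.
#'
#' @slot acquisition an \linkS4class{AcquisitionSpec}.
#' @slot donorLifetimeNs unquenched donor lifetime tauD in ns.
#' @slot classNames ordered FRET class names.
#' @slot classE true FRET efficiency per class, same order.
#' @slot nuclei data.frame with columns cx, cy (0-based pixel centres),
#'   radius, and one mixing-fraction column per class (named after
#'   classNames).
#' @slot genotypePreset preset tag, e.g. "wildtype-like".
#' @slot outsideIntensity relative photon weight of non-nuclear pixels
#'   (ambient background light), in units of the nuclear plateau intensity.
#' @slot classField "domains" (default): classes form spatially contiguous
#'   patches inside each nucleus, with per-nucleus fractions matching the
#'   mixing fractions exactly (quantile cut of a smoothed noise field), the
#'   pattern seen as discrete compaction regions in real nuclei; "iid":
#'   classes drawn independently per pixel.
#' @slot domainSigmaPx smoothing length (pixels) of the domain field;
#'   larger values give larger compaction domains.
#' @slot seed integer RNG seed recorded in the output cube.
#' @exportClass SceneSpec
setClass("SceneSpec",
    representation(
        acquisition = "AcquisitionSpec",
        donorLifetimeNs = "numeric",
        classNames = "character",
        classE = "numeric",
        nuclei = "data.frame",
        genotypePreset = "character",
        outsideIntensity = "numeric",
        classField = "character",
        domainSigmaPx = "numeric",
        seed = "integer"
    )
)

setValidity("SceneSpec", function(object) {
    msg <- character()
    if (object@donorLifetimeNs <= 0)
        msg <- c(msg, "donorLifetimeNs must be > 0")
    if (length(object@classE) != length(object@classNames))
        msg <- c(msg, "classE must have one value per class name")
    if (any(object@classE < 0 | object@classE >= 1))
        msg <- c(msg, "class E values must lie in [0, 1)")
    nuc <- object@nuclei
    need <- c("cx", "cy", "radius", object@classNames)
    if (!all(need %in% names(nuc))) {
        msg <- c(msg, paste("nuclei must have columns:",
                            paste(need, collapse = ", ")))
    } else if (nrow(nuc)) {
        fr <- as.matrix(nuc[, object@classNames, drop = FALSE])
        if (any(fr < 0))
            msg <- c(msg, "mixing fractions must be >= 0")
        if (any(abs(rowSums(fr) - 1) > 1e-8))
            msg <- c(msg, "mixing fractions must sum to 1 per nucleus")
        sh <- object@acquisition@imageShape
        # 0-based (y, x); nucleus disk must lie fully inside the raster
        if (any(nuc$cx - nuc$radius < 0 | nuc$cy - nuc$radius < 0 |
                nuc$cx + nuc$radius > sh[2] - 1 |
                nuc$cy + nuc$radius > sh[1] - 1))
            msg <- c(msg, "nuclei must lie fully inside the image")
    }
    if (object@outsideIntensity < 0)
        msg <- c(msg, "outsideIntensity must be >= 0")
    if (!object@classField %in% c("domains", "iid"))
        msg <- c(msg, "classField must be 'domains' or 'iid'")
    if (object@domainSigmaPx <= 0)
        msg <- c(msg, "domainSigmaPx must be > 0")
    if (length(msg)) msg else TRUE
})

#' TCSPC photon-count data cube
#'
#' Photon counts per pixel and time bin for one field, with the acquisition
#' settings and, for synthetic scenes, the per-pixel ground truth (class
#' label image and true-E image).
#'
#' @slot counts integer array (height, width, nTimeBins), all >= 0.
#' @slot acquisition the \linkS4class{AcquisitionSpec} used.
#' @slot truth list; empty for real data, else classLabels (integer matrix,
#'   0 = background, k = class k), classNames, trueE (numeric matrix,
#'   NA outside nuclei), nucleusLabels (integer matrix, 0 = background).
#' @slot seed integer seed used for simulation (NA for real data).
#' @exportClass PhotonCube
setClass("PhotonCube",
    representation(
        counts = "array",
        acquisition = "AcquisitionSpec",
        truth = "list",
        seed = "integer"
    )
)

setValidity("PhotonCube", function(object) {
    msg <- character()
    d <- dim(object@counts)
    acq <- object@acquisition
    if (length(d) != 3L)
        msg <- c(msg, "counts must be a 3-d array (height, width, time)")
    else {
        if (!all(d == c(acq@imageShape, acq@nTimeBins)))
            msg <- c(msg, "counts dimensions must match acquisition")
        if (any(object@counts < 0))
            msg <- c(msg, "counts must be >= 0")
    }
    tr <- object@truth
    if (length(tr)) {
        for (f in c("classLabels", "trueE"))
            if (!is.null(tr[[f]]) && !all(dim(tr[[f]]) == d[1:2]))
                msg <- c(msg, paste("truth$", f, " shape mismatch", sep = ""))
    }
    if (length(msg)) msg else TRUE
})

#' One TCSPC decay histogram
#'
#' Time-binned photon counts for a single pixel or ROI.
#'
#' @slot counts non-negative integer counts per time bin.
#' @slot binWidthNs bin width in ns.
#' @slot periodNs laser period in ns.
#' @slot originBin 1-based index of the decay start (histogram peak);
#'   NA means "determine from the data at fit time".
#' @exportClass DecayHistogram
setClass("DecayHistogram",
    representation(
        counts = "numeric",
        binWidthNs = "numeric",
        periodNs = "numeric",
        originBin = "integer"
    )
)

setValidity("DecayHistogram", function(object) {
    msg <- character()
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be >= 0")
    if (object@binWidthNs <= 0 || object@periodNs <= 0)
        msg <- c(msg, "binWidthNs and periodNs must be > 0")
    if (object@binWidthNs * length(object@counts) >
        object@periodNs * (1 + 1e-6))
        msg <- c(msg, "bin span exceeds the laser period")
    if (length(msg)) msg else TRUE
})

#' Exponential decay fit result
#'
#' Lifetimes and amplitudes from a mono- or bi-exponential fit of a decay
#' histogram, with the amplitude-weighted mean lifetime
#' tau_m = sum(a_i tau_i) / sum(a_i).
#'
#' @slot model "mono" or "bi".
#' @slot lifetimes fitted lifetimes in ns, increasing order for "bi".
#' @slot amplitudes non-negative amplitude weights, summing to 1.
#' @slot background fitted/fixed uniform background, counts per bin.
#' @slot meanLifetimeNs amplitude-weighted mean lifetime in ns.
#' @slot reducedChiSq Pearson reduced chi-square of the fit.
#' @slot photonsUsed photons inside the fit window.
#' @slot converged logical convergence flag.
#' @slot degenerate logical; TRUE when a bi-exponential fit collapsed to a
#'   single component.
#' @exportClass FitResult
setClass("FitResult",
    representation(
        model = "character",
        lifetimes = "numeric",
        amplitudes = "numeric",
        background = "numeric",
        meanLifetimeNs = "numeric",
        reducedChiSq = "numeric",
        photonsUsed = "numeric",
        converged = "logical",
        degenerate = "logical"
    )
)

setValidity("FitResult", function(object) {
    msg <- character()
    if (!object@model %in% c("mono", "bi"))
        msg <- c(msg, "model must be 'mono' or 'bi'")
    if (any(object@lifetimes <= 0))
        msg <- c(msg, "lifetimes must be > 0")
    if (any(object@amplitudes < 0))
        msg <- c(msg, "amplitudes must be >= 0")
    if (object@reducedChiSq < 0)
        msg <- c(msg, "reducedChiSq must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Nucleus ROI label mask
#'
#' Label image marking nucleus ROIs: 0 is background, k marks nucleus k.
#' Labels are positive contiguous integers 1..n; constructors relabel
#' non-contiguous input and report the mapping.
#'
#' @slot labels integer matrix of labels.
#' @slot metadata data.frame with one row per label: label, gonadId,
#'   stageTag.
#' @slot source "manual", "segmented", or "truth"; automated masks are
#'   flagged so downstream tables can distinguish them from manual
#'   outlining.
#' @exportClass RoiMask
setClass("RoiMask",
    representation(
        labels = "matrix",
        metadata = "data.frame",
        source = "character"
    )
)

setValidity("RoiMask", function(object) {
    msg <- character()
    lab <- object@labels
    if (any(lab < 0) || any(lab != round(lab)))
        msg <- c(msg, "labels must be non-negative integers")
    u <- sort(unique(as.integer(lab[lab > 0])))
    if (length(u) && !identical(u, seq_along(u)))
        msg <- c(msg, "positive labels must be contiguous 1..n")
    if (length(msg)) msg else TRUE
})

#' Per-pixel lifetime map
#'
#' Amplitude-weighted mean lifetime per masked pixel (NA where the pixel
#' was unmasked, photon-poor, or failed to converge), with a per-ROI
#' summary table.
#'
#' @slot tau numeric matrix of mean lifetimes in ns; NA = undefined.
#' @slot mask the \linkS4class{RoiMask} used.
#' @slot roiSummary data.frame: roi, gonadId, pixelCount, meanTauNs,
#'   medianTauNs.
#' @slot model fit model used ("mono" or "bi").
#' @slot settings list of fit settings (method, binRadius, minPhotons).
#' @exportClass PixelLifetimeMap
setClass("PixelLifetimeMap",
    representation(
        tau = "matrix",
        mask = "RoiMask",
        roiSummary = "data.frame",
        model = "character",
        settings = "list"
    )
)

#' Donor-only lifetime reference
#'
#' The unquenched donor lifetime tauD, computed as the mean of per-ROI mean
#' lifetimes from mono-exponential fits of donor-only samples, with their
#' dispersion.
#'
#' @slot tauDNs reference donor lifetime in ns.
#' @slot dispersionNs standard deviation of the per-ROI means (NA for a
#'   single ROI).
#' @slot source data.frame of the per-ROI means entering the average.
#' @exportClass DonorReference
setClass("DonorReference",
    representation(
        tauDNs = "numeric",
        dispersionNs = "numeric",
        source = "data.frame"
    )
)

setValidity("DonorReference", function(object) {
    if (object@tauDNs <= 0) "tauDNs must be > 0" else TRUE
})

#' Per-pixel FRET efficiency map
#'
#' E = 1 - tau_m / tauD per pixel. Values may be negative (fit noise around
#' E = 0); they are never clamped, since clamping would bias per-ROI mean E.
#'
#' @slot E numeric matrix of efficiencies; NA where the lifetime map is
#'   undefined.
#' @slot donorReference the \linkS4class{DonorReference} used.
#' @slot mask ROI provenance.
#' @slot roiSummary data.frame: roi, gonadId, pixelCount, meanE, medianE.
#' @exportClass FretEfficiencyMap
setClass("FretEfficiencyMap",
    representation(
        E = "matrix",
        donorReference = "DonorReference",
        mask = "RoiMask",
        roiSummary = "data.frame"
    )
)

#' FRET population class scheme
#'
#' Ordered class names and the E boundaries between them. Classes partition
#' (-Inf, 1): intervals are left-closed, right-open, and the lowest class is
#' unbounded below so that negative-E pixels fall in it.
#'
#' @slot classNames ordered class names, lowest E first.
#' @slot boundaries strictly increasing boundaries, length
#'   length(classNames) - 1.
#' @exportClass FretClassScheme
setClass("FretClassScheme",
    representation(
        classNames = "character",
        boundaries = "numeric"
    )
)

setValidity("FretClassScheme", function(object) {
    msg <- character()
    if (length(object@boundaries) != length(object@classNames) - 1L)
        msg <- c(msg, "need one fewer boundary than class names")
    if (is.unsorted(object@boundaries, strictly = TRUE))
        msg <- c(msg, "boundaries must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Per-ROI FRET population profile
#'
#' Fraction of defined pixels in each FRET class, per ROI.
#'
#' @slot fractions numeric matrix, one row per ROI, one column per class;
#'   rows sum to 1.
#' @slot pixelCounts defined-pixel count per ROI.
#' @slot roiInfo data.frame: roi, gonadId.
#' @slot scheme the \linkS4class{FretClassScheme} used.
#' @exportClass FretClassProfile
setClass("FretClassProfile",
    representation(
        fractions = "matrix",
        pixelCounts = "numeric",
        roiInfo = "data.frame",
        scheme = "FretClassScheme"
    )
)

setValidity("FretClassProfile", function(object) {
    msg <- character()
    if (any(object@fractions < 0))
        msg <- c(msg, "fractions must be >= 0")
    if (nrow(object@fractions) &&
        any(abs(rowSums(object@fractions) - 1) > 1e-8))
        msg <- c(msg, "fractions must sum to 1 per ROI")
    if (length(msg)) msg else TRUE
})
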