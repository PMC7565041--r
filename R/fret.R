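#' Donor-only lifetime reference
#'
#' Builds the unquenched donor reference tauD as the arithmetic mean of
#' per-ROI mean lifetimes across donor-only samples. Only mono-exponential
#' maps are accepted: the donor-alone decay is a single-lifetime decay by
#' construction, and a bi-exponential input indicates the wrong sample (or
#' model) was supplied.
#'
#' @param donorOnlyMaps a \linkS4class{PixelLifetimeMap} or list of them,
#'   fitted with \code{model = "mono"} on donor-only scenes.
#' @return a \linkS4class{DonorReference}.
#' @export
donorReference <- function(donorOnlyMaps) {
    if (is(donorOnlyMaps, "PixelLifetimeMap"))
        donorOnlyMaps <- list(donorOnlyMaps)
    if (!length(donorOnlyMaps)) stop("need at least one donor-only map")
    for (m in donorOnlyMaps) {
        stopifnot(is(m, "PixelLifetimeMap"))
        if (m@model != "mono")
            stop("donor reference requires mono-exponential fits, got '",
                 m@model, "'")
    }
    src <- do.call(rbind, lapply(seq_along(donorOnlyMaps), function(i) {
        s <- roiSummary(donorOnlyMaps[[i]])
        s$mapIndex <- i
        s
    }))
    src <- src[!is.na(src$meanTauNs), , drop = FALSE]
    if (!nrow(src)) stop("no ROI with a defined mean lifetime")
    tauD <- mean(src$meanTauNs)
    disp <- if (nrow(src) > 1L) stats::sd(src$meanTauNs) else NA_real_
    new("DonorReference", tauDNs = tauD, dispersionNs = disp,
        source = src)
}

#' FRET efficiency from lifetimes
#'
#' E = 1 - tauDA / tauD, the donor-quenching definition of FRET
#' efficiency. Values are not clamped: noise in tauDA can push E below 0,
#' and clamping would bias ROI mean efficiencies.
#'
#' @param tauDA donor lifetime in presence of the acceptor, ns
#'   (vectorized).
#' @param tauD unquenched donor lifetime, ns.
#' @return efficiency, same length as \code{tauDA}; always < 1.
#' @examples
#' fretEfficiency(1.25, 2.5)   # 0.5
#' fretEfficiency(2.6, 2.5)    # -0.04, noise around E = 0
#' @export
fretEfficiency <- function(tauDA, tauD) {
    if (any(!is.na(tauDA) & tauDA <= 0) || tauD <= 0)
        stop("lifetimes must be > 0")
    1 - tauDA / tauD
}

#' Per-pixel FRET efficiency map
#'
#' Applies \code{\link{fretEfficiency}} pixelwise to a lifetime map under
#' a donor reference; NA (unfitted) pixels propagate. The attached per-ROI
#' summary (mean E per nucleus/gonad) is the statistic used for genotype
#' comparisons.
#'
#' @param lifetimeMap a \linkS4class{PixelLifetimeMap}.
#' @param ref a \linkS4class{DonorReference}.
#' @return a \linkS4class{FretEfficiencyMap}.
#' @export
fretMap <- function(lifetimeMap, ref) {
    stopifnot(is(lifetimeMap, "PixelLifetimeMap"),
              is(ref, "DonorReference"))
    E <- fretEfficiency(lifetimeValues(lifetimeMap), tauD(ref))
    lab <- roiLabels(lifetimeMap@mask)
    md <- roiMetadata(lifetimeMap@mask)
    roiSumm <- do.call(rbind, lapply(md$label, function(k) {
        v <- E[lab == k]
        v <- v[!is.na(v)]
        data.frame(roi = k, gonadId = md$gonadId[md$label == k][1],
                   pixelCount = length(v),
                   meanE = if (length(v)) mean(v) else NA_real_,
                   medianE = if (length(v)) stats::median(v) else NA_real_)
    }))
    new("FretEfficiencyMap", E = E, donorReference = ref,
        mask = lifetimeMap@mask, roiSummary = roiSumm)
}

#' FRET population class scheme
#'
#' @param classNames ordered class names, lowest efficiency first.
#' @param boundaries strictly increasing E boundaries between consecutive
#'   classes. Intervals are left-closed, right-open; the lowest class is
#'   unbounded below (negative-E pixels land there). Defaults: sub-low
#'   below 0.05, low in [0.05, 0.125), intermediate in [0.125, 0.25),
#'   high at and above 0.25. The class cut-offs are operational
#'   configuration, not measured constants.
#' @return a \linkS4class{FretClassScheme}.
#' @export
fretClassScheme <- function(classNames = c("sub-low", "low",
                                           "intermediate", "high"),
                            boundaries = c(0.05, 0.125, 0.25)) {
    new("FretClassScheme", classNames = as.character(classNames),
        boundaries = as.numeric(boundaries))
}

#' Classify pixels into FRET populations
#'
#' Assigns every defined pixel of an efficiency map to exactly one FRET
#' class and returns the per-ROI class fractions (computed over defined
#' pixels only). ROIs with no defined pixel are dropped with a warning.
#'
#' @param map a \linkS4class{FretEfficiencyMap}.
#' @param scheme a \linkS4class{FretClassScheme}.
#' @return a \linkS4class{FretClassProfile}.
#' @export
classifyFret <- function(map, scheme = fretClassScheme()) {
    stopifnot(is(map, "FretEfficiencyMap"), is(scheme, "FretClassScheme"))
    validObject(scheme)
    E <- efficiencyValues(map)
    lab <- roiLabels(map@mask)
    md <- roiMetadata(map@mask)
    ncls <- length(scheme@classNames)

    rows <- list(); counts <- numeric(0); info <- list()
    for (k in md$label) {
        v <- E[lab == k]
        v <- v[!is.na(v)]
        if (!length(v)) {
            warning("ROI ", k, " has no defined pixel; dropped")
            next
        }
        ## left-closed, right-open bins; lowest class unbounded below
        cls <- findInterval(v, scheme@boundaries,
                            left.open = FALSE, rightmost.closed = FALSE) + 1L
        fr <- tabulate(cls, nbins = ncls) / length(v)
        rows[[length(rows) + 1L]] <- fr
        counts <- c(counts, length(v))
        info[[length(info) + 1L]] <-
            data.frame(roi = k, gonadId = md$gonadId[md$label == k][1])
    }
    fractions <- do.call(rbind, rows)
    if (is.null(fractions))
        fractions <- matrix(numeric(0), 0, ncls)
    colnames(fractions) <- scheme@classNames
    new("FretClassProfile", fractions = fractions, pixelCounts = counts,
        roiInfo = if (length(info)) do.call(rbind, info)
                  else data.frame(roi = integer(0),
                                  gonadId = character(0)),
        scheme = scheme)
}

#' Pool a class profile to one row per gonad
#'
#' Pixel-count-weighted pooling of per-ROI fractions into per-gonad
#' fractions — the per-gonad values are the sampling unit for genotype
#' comparisons.
#'
#' @param profile a \linkS4class{FretClassProfile}.
#' @return data.frame with gonadId, pixelCount and one column per class.
#' @export
gonadClassFractions <- function(profile) {
    stopifnot(is(profile, "FretClassProfile"))
    info <- profile@roiInfo
    if (!nrow(info))
        return(data.frame(gonadId = character(0), pixelCount = numeric(0)))
    out <- lapply(split(seq_len(nrow(info)), info$gonadId), function(idx) {
        w <- profile@pixelCounts[idx]
        fr <- colSums(profile@fractions[idx, , drop = FALSE] * w) / sum(w)
        cbind(data.frame(gonadId = info$gonadId[idx[1]],
                         pixelCount = sum(w)), as.data.frame(t(fr)))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
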