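#' Construct TCSPC acquisition settings
#'
#' @param nTimeBins number of TCSPC time bins (default 256).
#' @param periodNs laser period in ns (default 12.5, i.e. 80 MHz).
#' @param imageShape image height and width in pixels (default 256 x 256).
#' @param totalPhotonBudget expected photons per field (default 5e6,
#'   i.e. roughly 8.5e4 photons/s over a 60 s acquisition).
#' @param backgroundFraction uniform-in-time background fraction in [0, 1).
#' @param irfSigmaNs Gaussian IRF sigma in ns; 0 disables the IRF.
#' @param irfCenterNs IRF peak position in ns.
#' @return an \linkS4class{AcquisitionSpec}.
#' @examples
#' acquisitionSpec(imageShape = c(64, 64), totalPhotonBudget = 3e5)
#' @export
acquisitionSpec <- function(nTimeBins = 256L, periodNs = 12.5,
                            imageShape = c(256L, 256L),
                            totalPhotonBudget = 5e6,
                            backgroundFraction = 0,
                            irfSigmaNs = 0, irfCenterNs = 0) {
    new("AcquisitionSpec",
        nTimeBins = as.integer(nTimeBins), periodNs = as.numeric(periodNs),
        imageShape = as.integer(imageShape),
        totalPhotonBudget = as.numeric(totalPhotonBudget),
        backgroundFraction = as.numeric(backgroundFraction),
        irfSigmaNs = as.numeric(irfSigmaNs),
        irfCenterNs = as.numeric(irfCenterNs))
}

#' Construct a FRET state
#'
#' @param label class name.
#' @param trueE FRET efficiency in [0, 1).
#' @param donorLifetimeNs unquenched donor lifetime tauD in ns.
#' @return a \linkS4class{FretStateSpec}. The quenched lifetime is
#'   \code{quenchedLifetime(state)} = tauD * (1 - E).
#' @export
fretState <- function(label, trueE, donorLifetimeNs = 2.5) {
    new("FretStateSpec", label = as.character(label),
        trueE = as.numeric(trueE),
        donorLifetimeNs = as.numeric(donorLifetimeNs))
}

#' @rdname fretState
#' @param state a \linkS4class{FretStateSpec}.
#' @export
quenchedLifetime <- function(state) {
    stopifnot(is(state, "FretStateSpec"))
    state@donorLifetimeNs * (1 - state@trueE)
}

## time-bin centres in ns
.binCenters <- function(acq) {
    dt <- acq@periodNs / acq@nTimeBins
    (seq_len(acq@nTimeBins) - 0.5) * dt
}

#' Expected TCSPC decay profile
#'
#' Per-bin photon probabilities for a (multi-)exponential decay sampled at
#' bin centres, optionally convolved with a Gaussian IRF and mixed with a
#' uniform temporal background. This is the forward model behind both the
#' simulator and the Poisson maximum-likelihood fitter.
#'
#' With no IRF the probability of bin i is proportional to
#' sum_k a_k exp(-t_i / tau_k). With \code{irfSigmaNs > 0} the pure decay is
#' convolved with a Gaussian kernel centred at \code{irfCenterNs} (linear
#' convolution; circular when \code{wrap = TRUE} to emulate incomplete-decay
#' wrap-around of the periodic excitation). A \code{backgroundFraction}
#' portion of the probability mass is uniform over bins.
#'
#' @param lifetimeNs one or more decay lifetimes in ns (> 0).
#' @param acquisition an \linkS4class{AcquisitionSpec}.
#' @param amplitudeFractions optional weights for multi-component decays;
#'   must be non-negative and sum to 1. Default: single component.
#' @param wrap logical; wrap the decay (and IRF tail) around the laser
#'   period instead of truncating. Default FALSE (tau << period makes the
#'   truncation error negligible).
#' @return numeric vector of length \code{nTimeBins} summing to 1.
#' @examples
#' acq <- acquisitionSpec(imageShape = c(1L, 1L), totalPhotonBudget = 1)
#' p <- expectedDecay(2.5, acq)
#' sum(p)  # 1
#' @export
expectedDecay <- function(lifetimeNs, acquisition,
                          amplitudeFractions = NULL, wrap = FALSE) {
    acq <- acquisition
    stopifnot(is(acq, "AcquisitionSpec"))
    if (any(!is.finite(lifetimeNs)) || any(lifetimeNs <= 0))
        stop("lifetimeNs must be positive and finite")
    if (is.null(amplitudeFractions))
        amplitudeFractions <- rep(1 / length(lifetimeNs),
                                  length(lifetimeNs))
    if (length(amplitudeFractions) != length(lifetimeNs))
        stop("amplitudeFractions must match lifetimeNs in length")
    if (any(amplitudeFractions < 0))
        stop("amplitudeFractions must be >= 0")
    if (abs(sum(amplitudeFractions) - 1) > 1e-8)
        stop("amplitudeFractions must sum to 1")

    tc <- .binCenters(acq)
    if (wrap) {
        ## geometric sum over preceding periods: adds a constant factor
        ## 1/(1 - exp(-T/tau)) per component
        comp <- vapply(seq_along(lifetimeNs), function(k) {
            ek <- exp(-tc / lifetimeNs[k]) /
                (1 - exp(-acq@periodNs / lifetimeNs[k]))
            amplitudeFractions[k] * ek
        }, numeric(length(tc)))
    } else {
        comp <- vapply(seq_along(lifetimeNs), function(k)
            amplitudeFractions[k] * exp(-tc / lifetimeNs[k]),
            numeric(length(tc)))
    }
    p <- rowSums(comp)
    p <- p / sum(p)

    if (acq@irfSigmaNs > 0)
        p <- .convolveIrf(p, acq, wrap = wrap)

    bg <- acq@backgroundFraction
    (1 - bg) * p + bg / acq@nTimeBins
}

## discrete convolution of a bin-probability vector with a sampled
## Gaussian kernel centred at irfCenterNs; renormalized
.convolveIrf <- function(p, acq, wrap = FALSE) {
    n <- acq@nTimeBins
    dt <- acq@periodNs / n
    ## kernel sampled on the bin grid, offsets in [-n+1, n-1]
    off <- seq(-(n - 1L), n - 1L)
    kern <- exp(-((off * dt - acq@irfCenterNs)^2) /
                    (2 * acq@irfSigmaNs^2))
    kern <- kern / sum(kern)
    out <- numeric(n)
    for (j in seq_len(n)) {
        idx <- j - off                      # source bin for each offset
        if (wrap) {
            idx <- ((idx - 1L) %% n) + 1L
            out[j] <- sum(kern * p[idx])
        } else {
            keep <- idx >= 1L & idx <= n
            out[j] <- sum(kern[keep] * p[idx[keep]])
        }
    }
    out / sum(out)
}

## run expr with a private RNG stream; global .Random.seed untouched
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulate one pixel's TCSPC histogram
#'
#' Draws \code{nPhotons} photon arrival bins for a pixel in a given FRET
#' state. By default the counts are a multinomial sample over the expected
#' decay profile (fixed per-pixel total, matching a fixed acquisition time);
#' \code{poissonBins = TRUE} instead draws independent Poisson counts per
#' bin with the same expectations.
#'
#' @param state a \linkS4class{FretStateSpec}.
#' @param nPhotons number of photons (>= 0).
#' @param acquisition an \linkS4class{AcquisitionSpec}.
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param poissonBins logical; use independent Poisson bins instead of the
#'   multinomial (total then no longer exact).
#' @return a \linkS4class{DecayHistogram}.
#' @export
simulatePixel <- function(state, nPhotons, acquisition, seed = NULL,
                          poissonBins = FALSE) {
    stopifnot(is(state, "FretStateSpec"))
    if (nPhotons < 0) stop("nPhotons must be >= 0")
    acq <- acquisition
    p <- expectedDecay(quenchedLifetime(state), acq)
    draw <- function() {
        if (poissonBins) stats::rpois(length(p), nPhotons * p)
        else as.integer(stats::rmultinom(1L, size = nPhotons, prob = p))
    }
    cnt <- if (is.null(seed)) draw() else .withSeed(seed, draw())
    new("DecayHistogram", counts = as.numeric(cnt),
        binWidthNs = acq@periodNs / acq@nTimeBins,
        periodNs = acq@periodNs, originBin = NA_integer_)
}

#' Construct a synthetic-scene specification
#'
#' @param acquisition an \linkS4class{AcquisitionSpec}.
#' @param donorLifetimeNs unquenched donor lifetime tauD in ns
#'   (default 2.5, typical for GFP).
#' @param classNames ordered FRET class names.
#' @param classE true efficiency per class. The defaults place each class
#'   midway between the default scheme boundaries (0.05/0.125/0.25), so
#'   every boundary is equidistant from its two neighbouring class
#'   efficiencies: threshold classification under symmetric fit noise is
#'   then flow-balanced and class fractions are recovered without
#'   systematic drift between classes.
#' @param nuclei data.frame with columns cx, cy, radius and one
#'   mixing-fraction column per class. 0-based pixel coordinates,
#'   row-major (y, x) raster convention.
#' @param genotypePreset free-text preset tag.
#' @param outsideIntensity relative photon weight of non-nuclear pixels
#'   (default 0.02 of the nuclear plateau); these pixels receive pure
#'   uniform-in-time background photons.
#' @param classField "domains" (default; spatially contiguous compaction
#'   patches, exact per-nucleus fractions) or "iid" (independent per-pixel
#'   class draws).
#' @param domainSigmaPx smoothing length of the domain field in pixels.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(acquisition = acquisitionSpec(),
                      donorLifetimeNs = 2.5,
                      classNames = c("sub-low", "low", "intermediate",
                                     "high"),
                      classE = c(0.0125, 0.0875, 0.1625, 0.3375),
                      nuclei, genotypePreset = "custom",
                      outsideIntensity = 0.02,
                      classField = c("domains", "iid"),
                      domainSigmaPx = 6, seed = 1L) {
    classField <- match.arg(classField)
    names(classE) <- classNames
    new("SceneSpec", acquisition = acquisition,
        donorLifetimeNs = as.numeric(donorLifetimeNs),
        classNames = classNames, classE = as.numeric(classE),
        nuclei = as.data.frame(nuclei),
        genotypePreset = as.character(genotypePreset),
        outsideIntensity = as.numeric(outsideIntensity),
        classField = classField,
        domainSigmaPx = as.numeric(domainSigmaPx),
        seed = as.integer(seed))
}

## Gaussian-smoothed white-noise field on an h x w grid: separable blur
## by banded kernel matrices (box sizes here are tens of pixels)
.smoothNoise <- function(h, w, sigma) {
    z <- matrix(stats::rnorm(h * w), h, w)
    kr <- outer(seq_len(h), seq_len(h),
                function(i, j) stats::dnorm(i - j, sd = sigma))
    kc <- outer(seq_len(w), seq_len(w),
                function(i, j) stats::dnorm(i - j, sd = sigma))
    kr %*% z %*% kc
}

## default pachytene-like nucleus layout: a grid of disks jittered inside
## the field; deterministic given the seed
.defaultNuclei <- function(imageShape, fractions, nNuclei = 12L,
                           radius = NULL, seed = 1L) {
    h <- imageShape[1]; w <- imageShape[2]
    if (is.null(radius)) radius <- round(min(h, w) / 14)
    .withSeed(seed + 77003L, {
        ncol <- ceiling(sqrt(nNuclei))
        nrow <- ceiling(nNuclei / ncol)
        gx <- (seq_len(ncol) - 0.5) * w / ncol
        gy <- (seq_len(nrow) - 0.5) * h / nrow
        pos <- expand.grid(cx = gx, cy = gy)[seq_len(nNuclei), ]
        jit <- radius * 0.6
        pos$cx <- pos$cx + stats::runif(nNuclei, -jit, jit)
        pos$cy <- pos$cy + stats::runif(nNuclei, -jit, jit)
        pos$cx <- pmin(pmax(pos$cx, radius + 1), w - radius - 2)
        pos$cy <- pmin(pmax(pos$cy, radius + 1), h - radius - 2)
        pos$radius <- radius
        for (cl in names(fractions)) pos[[cl]] <- fractions[[cl]]
        pos
    })
}

#' Genotype presets for synthetic germline fields
#'
#' Ready-made \linkS4class{SceneSpec}s realizing the qualitative genotype
#' contrast of the assay: relative to \code{"wildtype-like"}, the
#' \code{"compass-mutant-like"} preset (loss of H3K4 methyltransferase
#' COMPASS activity) has a larger sub-low fraction and smaller
#' intermediate and high fractions, i.e. reduced nanoscale compaction and
#' a lower mean FRET efficiency. The \code{"donor-only"} preset has every
#' pixel at E = 0 (no acceptor), for building the donor lifetime
#' reference. Exact fractions are package configuration, not measured
#' values.
#'
#' @param preset one of "wildtype-like", "compass-mutant-like",
#'   "donor-only".
#' @param seed integer RNG seed (also jitters nucleus placement).
#' @param acquisition acquisition settings; default full-size field.
#' @param nNuclei number of pachytene nuclei in the field.
#' @param donorLifetimeNs donor lifetime tauD in ns.
#' @param ... passed to \code{\link{sceneSpec}}.
#' @return a \linkS4class{SceneSpec}.
#' @examples
#' sp <- genotypePreset("wildtype-like", seed = 7,
#'                      acquisition = acquisitionSpec(
#'                          imageShape = c(64L, 64L),
#'                          totalPhotonBudget = 3e5))
#' @export
genotypePreset <- function(preset = c("wildtype-like",
                                      "compass-mutant-like",
                                      "donor-only"),
                           seed = 1L,
                           acquisition = acquisitionSpec(),
                           nNuclei = 12L, donorLifetimeNs = 2.5, ...) {
    preset <- match.arg(preset)
    fr <- switch(preset,
        "wildtype-like" = c("sub-low" = 0.25, "low" = 0.35,
                            "intermediate" = 0.25, "high" = 0.15),
        "compass-mutant-like" = c("sub-low" = 0.42, "low" = 0.36,
                                  "intermediate" = 0.15, "high" = 0.07),
        "donor-only" = c("sub-low" = 1, "low" = 0, "intermediate" = 0,
                         "high" = 0))
    nuc <- .defaultNuclei(acquisition@imageShape, as.list(fr),
                          nNuclei = nNuclei, seed = seed)
    args <- list(acquisition = acquisition,
                 donorLifetimeNs = donorLifetimeNs, nuclei = nuc,
                 genotypePreset = preset, seed = seed, ...)
    ## donor-only: every pixel is the unquenched donor, E = 0 exactly
    if (preset == "donor-only" && is.null(args$classE))
        args$classE <- c(0, 0, 0, 0)
    do.call(sceneSpec, args)
}

#' Simulate a full TCSPC field
#'
#' Renders a \linkS4class{SceneSpec} into a photon-count cube. Each nuclear
#' pixel is assigned a FRET class drawn from its nucleus's mixing
#' fractions; the field photon budget is allocated over pixels by a single
#' multinomial draw with weights proportional to the intensity profile
#' (nuclear plateau = 1, outside pixels = \code{outsideIntensity}); each
#' pixel's photons are then spread over time bins by a multinomial draw
#' from that pixel's expected decay (outside pixels: uniform background
#' spectrum). Total photons therefore equal the realized budget exactly.
#' Overlapping nuclei: the later nucleus in the table wins.
#'
#' The returned cube carries the full ground truth: per-pixel class labels,
#' true E, and the nucleus label image (usable as a ground-truth ROI mask).
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return a \linkS4class{PhotonCube}.
#' @export
simulateScene <- function(spec) {
    stopifnot(is(spec, "SceneSpec"))
    validObject(spec)
    acq <- spec@acquisition
    h <- acq@imageShape[1]; w <- acq@imageShape[2]
    nb <- acq@nTimeBins
    nuc <- spec@nuclei
    ncls <- length(spec@classNames)

    ## nucleus label image; later nucleus wins on overlap
    nucLab <- matrix(0L, h, w)
    xs <- matrix(rep(0:(w - 1L), each = h), h, w)
    ys <- matrix(rep(0:(h - 1L), times = w), h, w)
    for (k in seq_len(nrow(nuc))) {
        inside <- (xs - nuc$cx[k])^2 + (ys - nuc$cy[k])^2 <=
            nuc$radius[k]^2
        nucLab[inside] <- k
    }

    frMat <- as.matrix(nuc[, spec@classNames, drop = FALSE])

    .withSeed(spec@seed, {
        ## per-pixel class labels: contiguous domains (quantile cut of a
        ## smoothed noise field; exact per-nucleus fractions) or iid draws
        clsLab <- matrix(0L, h, w)
        for (k in seq_len(nrow(nuc))) {
            idx <- which(nucLab == k)
            if (!length(idx)) next
            if (spec@classField == "iid") {
                clsLab[idx] <- sample.int(ncls, length(idx),
                                          replace = TRUE,
                                          prob = frMat[k, ])
            } else {
                fld <- .smoothNoise(h, w, spec@domainSigmaPx)[idx]
                r <- rank(fld, ties.method = "first")
                cuts <- round(cumsum(frMat[k, ]) * length(idx))
                clsLab[idx] <- 1L +
                    findInterval(r, cuts[-ncls], left.open = TRUE)
            }
        }
        trueE <- matrix(NA_real_, h, w)
        inN <- clsLab > 0L
        trueE[inN] <- spec@classE[clsLab[inN]]

        ## photon budget over pixels
        wgt <- ifelse(inN, 1, spec@outsideIntensity)
        nPix <- as.integer(stats::rmultinom(
            1L, size = round(acq@totalPhotonBudget), prob = as.vector(wgt)))

        ## per-class decay templates
        templ <- vapply(seq_len(ncls), function(j)
            expectedDecay(spec@donorLifetimeNs * (1 - spec@classE[j]), acq),
            numeric(nb))
        uniform <- rep(1 / nb, nb)

        counts <- array(0L, dim = c(h, w, nb))
        cls <- as.vector(clsLab)
        ## vectorized-ish: loop classes, draw all pixels of a class at once
        for (j in 0:ncls) {
            idx <- which(cls == j & nPix > 0L)
            if (!length(idx)) next
            p <- if (j == 0L) uniform else templ[, j]
            ## rmultinom over pixels of this class
            for (i in idx) {
                ij <- arrayInd(i, c(h, w))
                counts[ij[1], ij[2], ] <-
                    as.integer(stats::rmultinom(1L, nPix[i], p))
            }
        }

        new("PhotonCube", counts = counts, acquisition = acq,
            truth = list(classLabels = clsLab,
                         classNames = spec@classNames,
                         trueE = trueE, nucleusLabels = nucLab,
                         classE = spec@classE,
                         donorLifetimeNs = spec@donorLifetimeNs,
                         genotypePreset = spec@genotypePreset),
            seed = spec@seed)
    })
}

#' Ground-truth ROI mask of a synthetic cube
#'
#' @param cube a \linkS4class{PhotonCube} with ground truth.
#' @param gonadId gonad identifier recorded in the mask metadata.
#' @return a \linkS4class{RoiMask} built from the simulated nucleus labels.
#' @export
truthMask <- function(cube, gonadId = "gonad1") {
    tr <- groundTruth(cube)
    if (!length(tr) || is.null(tr$nucleusLabels))
        stop("cube carries no ground truth")
    roiMask(tr$nucleusLabels, gonadId = gonadId, source = "truth")
}
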