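# shared builders for small synthetic inputs; everything generated in code

# single-pixel acquisition for histogram-level tests
acq1 <- function(nTimeBins = 256L, periodNs = 12.5, ...) {
    acquisitionSpec(nTimeBins = nTimeBins, periodNs = periodNs,
                    imageShape = c(1L, 1L), totalPhotonBudget = 1, ...)
}

# small field keeping the default photon density (5e6 over 256 x 256)
smallAcq <- function(side = 96L, ...) {
    acquisitionSpec(imageShape = c(side, side),
                    totalPhotonBudget = 5e6 * side^2 / 256^2, ...)
}

# donor reference built from nDonor donor-only fields
buildDonorRef <- function(acq, nDonor = 2L, nNuclei = 5L, seedBase = 900L,
                          ...) {
    maps <- lapply(seq_len(nDonor), function(i) {
        cube <- simulateScene(genotypePreset("donor-only",
                                             seed = seedBase + i,
                                             acquisition = acq,
                                             nNuclei = nNuclei))
        fitMap(cube, truthMask(cube, paste0("donor", i)), ...)
    })
    donorReference(maps)
}

# Poisson/multinomial log-likelihood of a tail-window histogram under a
# mono-exponential with no background -- used by grid-search oracles;
# written independently of the package internals
oracleLogLik <- function(counts, binWidthNs, tau) {
    o <- which.max(counts)
    cnt <- counts[o:length(counts)]
    t <- (seq_along(cnt) - 0.5) * binWidthNs
    p <- exp(-t / tau)
    p <- p / sum(p)
    sum(cnt[cnt > 0] * log(p[cnt > 0]))
}

oracleGridTau <- function(counts, binWidthNs, grid) {
    ll <- vapply(grid, function(tau)
        oracleLogLik(counts, binWidthNs, tau), numeric(1))
    grid[which.max(ll)]
}
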