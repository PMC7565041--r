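test_that("expected decay matches the normalized exponential at bin centers", {
    acq <- acq1()
    p <- expectedDecay(2.5, acq)
    tc <- (seq_len(256) - 0.5) * 12.5 / 256
    ref <- exp(-tc / 2.5)
    expect_equal(p, ref / sum(ref), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)

    # two components = amplitude-weighted mixture
    p2 <- expectedDecay(c(1, 2.5), acq, amplitudeFractions = c(0.3, 0.7))
    ref2 <- 0.3 * exp(-tc / 1) + 0.7 * exp(-tc / 2.5)
    expect_equal(p2, ref2 / sum(ref2), tolerance = 1e-12)
})

test_that("expected decay rejects invalid parameters", {
    acq <- acq1()
    expect_error(expectedDecay(-1, acq), "positive")
    expect_error(expectedDecay(0, acq), "positive")
    expect_error(expectedDecay(c(1, 2), acq,
                               amplitudeFractions = c(-0.1, 1.1)), ">= 0")
    expect_error(expectedDecay(c(1, 2), acq,
                               amplitudeFractions = c(0.3, 0.3)), "sum to 1")
    expect_error(acquisitionSpec(backgroundFraction = 1), "\\[0, 1\\)")
})

test_that("Gaussian IRF convolution agrees with oversampled quadrature", {
    acq <- acq1(irfSigmaNs = 0.1, irfCenterNs = 0.5)
    p <- expectedDecay(2.5, acq)
    expect_equal(sum(p), 1, tolerance = 1e-12)

    # oracle: direct numerical integration of the convolution integral on
    # a 10x-oversampled grid, then rebinned to the acquisition bins
    n <- 256L; ov <- 10L
    dtf <- 12.5 / (n * ov)
    tf <- (seq_len(n * ov) - 0.5) * dtf
    decay <- exp(-tf / 2.5)
    conv <- vapply(tf, function(tt) {
        # integral over s of decay(s) * gauss(tt - s)
        sum(decay * exp(-((tt - tf) - 0.5)^2 / (2 * 0.1^2))) * dtf
    }, numeric(1))
    ref <- colSums(matrix(conv, ov, n))
    ref <- ref / sum(ref)
    expect_equal(p, ref, tolerance = 5e-3)
})

test_that("background fraction adds a uniform floor to the decay", {
    acq <- acq1(backgroundFraction = 0.2)
    p <- expectedDecay(2.5, acq)
    p0 <- expectedDecay(2.5, acq1())
    expect_equal(p, 0.8 * p0 + 0.2 / 256, tolerance = 1e-12)
})

test_that("pixel simulation is multinomial over the expected decay", {
    acq <- acq1()
    st <- fretState("sub-low", 0, 2.5)
    expect_equal(sum(simulatePixel(st, 0, acq, seed = 1)@counts), 0)

    h1 <- simulatePixel(st, 1000, acq, seed = 7)
    h2 <- simulatePixel(st, 1000, acq, seed = 7)
    expect_identical(h1@counts, h2@counts)
    expect_equal(sum(h1@counts), 1000)

    # goodness of fit of the average of 100 draws of 1e5 photons against
    # the analytic expectation
    p <- expectedDecay(2.5, acq)
    tot <- Reduce(`+`, lapply(1:100, function(s)
        simulatePixel(st, 1e5, acq, seed = s)@counts))
    expected <- 100 * 1e5 * p
    chi <- sum((tot - expected)^2 / expected)
    expect_gt(stats::pchisq(chi, df = 255, lower.tail = FALSE), 0.01)
})

test_that("quenched lifetime follows tauDA = tauD (1 - E)", {
    expect_equal(quenchedLifetime(fretState("high", 0.4, 2.5)), 1.5)
    expect_equal(quenchedLifetime(fretState("sub-low", 0, 2.5)), 2.5)
    expect_error(fretState("bad", 1.0, 2.5), "\\[0, 1\\)")
})

test_that("scene simulation conserves the photon budget exactly", {
    acq <- smallAcq(64L)
    sp <- genotypePreset("wildtype-like", seed = 5, acquisition = acq,
                         nNuclei = 4L)
    cube <- simulateScene(sp)
    expect_equal(sum(photonCounts(cube)),
                 round(acq@totalPhotonBudget))
    expect_equal(dim(photonCounts(cube)), c(64L, 64L, 256L))
})

test_that("single-class nucleus yields pure ground truth", {
    acq <- smallAcq(48L)
    nuc <- data.frame(cx = 23, cy = 23, radius = 10,
                      "sub-low" = 1, low = 0, intermediate = 0, high = 0,
                      check.names = FALSE)
    sp <- sceneSpec(acquisition = acq, nuclei = nuc,
                    classE = c(0, 0.0875, 0.1625, 0.3375), seed = 2)
    cube <- simulateScene(sp)
    tr <- groundTruth(cube)
    inside <- tr$nucleusLabels > 0
    expect_true(all(tr$classLabels[inside] == 1L))
    expect_true(all(tr$trueE[inside] == 0))
    expect_true(all(is.na(tr$trueE[!inside])))
})

test_that("mutant preset has strictly lower ground-truth mean E", {
    acq <- smallAcq(64L)
    wt <- simulateScene(genotypePreset("wildtype-like", seed = 9,
                                       acquisition = acq, nNuclei = 4L))
    mut <- simulateScene(genotypePreset("compass-mutant-like", seed = 9,
                                        acquisition = acq, nNuclei = 4L))
    eWt <- mean(groundTruth(wt)$trueE, na.rm = TRUE)
    eMut <- mean(groundTruth(mut)$trueE, na.rm = TRUE)
    expect_lt(eMut, eWt)
})

test_that("nuclei must lie inside the field; later nucleus wins overlap", {
    acq <- smallAcq(48L)
    bad <- data.frame(cx = 2, cy = 24, radius = 10,
                      "sub-low" = 1, low = 0, intermediate = 0, high = 0,
                      check.names = FALSE)
    expect_error(sceneSpec(acquisition = acq, nuclei = bad, seed = 1),
                 "inside the image")

    two <- data.frame(cx = c(20, 26), cy = c(24, 24), radius = 8,
                      "sub-low" = c(1, 0), low = c(0, 1),
                      intermediate = 0, high = 0, check.names = FALSE)
    cube <- simulateScene(sceneSpec(acquisition = acq, nuclei = two,
                                    seed = 1))
    tr <- groundTruth(cube)
    # overlap region carries the second nucleus's label
    expect_equal(tr$nucleusLabels[25, 24], 2L)
})

test_that("ground-truth class fractions match the mixing fractions", {
    acq <- smallAcq(96L)
    fr <- c(0.4, 0.3, 0.2, 0.1)
    nuc <- data.frame(cx = 47, cy = 47, radius = 30,
                      "sub-low" = fr[1], low = fr[2],
                      intermediate = fr[3], high = fr[4],
                      check.names = FALSE)
    # domains: exact up to integer rounding of the quantile cut
    cube <- simulateScene(sceneSpec(acquisition = acq, nuclei = nuc,
                                    seed = 3))
    tr <- groundTruth(cube)
    n <- sum(tr$nucleusLabels > 0)
    got <- tabulate(tr$classLabels[tr$nucleusLabels > 0], 4) / n
    expect_equal(got, fr, tolerance = 2 / n)

    # iid: within 4 binomial SE at n >= 1e3 pixels
    cube2 <- simulateScene(sceneSpec(acquisition = acq, nuclei = nuc,
                                     classField = "iid", seed = 3))
    tr2 <- groundTruth(cube2)
    got2 <- tabulate(tr2$classLabels[tr2$nucleusLabels > 0], 4) / n
    expect_true(all(abs(got2 - fr) < 4 * sqrt(fr * (1 - fr) / n)))
})

test_that("scene generation is a pure function of its spec", {
    acq <- smallAcq(48L)
    sp <- genotypePreset("wildtype-like", seed = 21, acquisition = acq,
                         nNuclei = 3L)
    c1 <- simulateScene(sp)
    c2 <- simulateScene(sp)
    expect_identical(photonCounts(c1), photonCounts(c2))
    expect_identical(groundTruth(c1)$classLabels,
                     groundTruth(c2)$classLabels)
})
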