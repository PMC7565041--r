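test_that("t test: identical groups give statistic 0, p = 1", {
    r <- tTestGroups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
    expect_equal(r$statistic, 0)
    expect_equal(r$p.value, 1)
})

test_that("t test on a clear shift is significant and matches the exact
           permutation distribution", {
    a <- c(1, 2, 3); b <- c(11, 12, 13)
    r <- tTestGroups(list(a = a, b = b), mode = "student")
    expect_lt(r$p.value, 1e-3)

    # oracle: Student t over all choose(6,3) = 20 label assignments;
    # the observed split must be the most extreme
    pool <- c(a, b)
    tOf <- function(x, y) {
        sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                       (length(x) + length(y) - 2))
        (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
    }
    idx <- utils::combn(6, 3)
    tPerm <- apply(idx, 2, function(i) tOf(pool[i], pool[-i]))
    expect_equal(max(abs(tPerm)), abs(r$statistic), tolerance = 1e-12)
    pPerm <- mean(abs(tPerm) >= abs(r$statistic) - 1e-12)
    expect_equal(pPerm, 2 / 20)       # the two extreme assignments
    expect_lt(r$p.value, pPerm)       # parametric p refines the ranking
})

test_that("t test contracts: short groups and degenerate variance", {
    expect_error(tTestGroups(list(a = 1, b = c(1, 2))), "at least 2")
    expect_error(tTestGroups(list(a = c(1, 1), b = c(2, 2))), "welch")
})

test_that("welch mode is recorded and differs under unequal variance", {
    a <- c(1, 2, 3, 4); b <- c(10, 30, 50, 70)
    rs <- tTestGroups(list(a = a, b = b), mode = "student")
    rw <- tTestGroups(list(a = a, b = b), mode = "welch")
    expect_equal(rw$mode, "welch")
    expect_gt(abs(rs$df - rw$df), 0.5)
})

test_that("t test holds its nominal type-I error on null data", {
    set.seed(123)
    reps <- 4000
    hits <- sum(vapply(seq_len(reps), function(i) {
        r <- tTestGroups(list(a = rnorm(6), b = rnorm(6)))
        r$p.value < 0.05
    }, logical(1)))
    ci <- qbinom(c(0.0005, 0.9995), reps, 0.05)
    expect_gte(hits, ci[1])
    expect_lte(hits, ci[2])
})

test_that("Bonferroni multiplies and clips", {
    expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
    expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
    expect_equal(bonferroni(0.3), 0.3)
})

test_that("Kruskal-Wallis gate controls the pairwise rank-sum tests", {
    same <- list(a = 1:6, b = 1:6 + 0.5, c = 1:6 + 0.25)
    r <- kruskalThenWilcoxon(same)
    expect_true(r$gated)
    expect_null(r$pairwise)

    sep <- list(a = 1:10, b = 1:10 + 0.5, c = 11:20)
    r2 <- kruskalThenWilcoxon(sep)
    expect_false(r2$gated)
    expect_lt(r2$omnibus.p, 0.05)
    pc <- r2$pairwise[r2$pairwise$group1 == "a" &
                      r2$pairwise$group2 == "c", ]
    # oracle: exact rank-sum tail by full enumeration at n = 10 + 10
    pool <- rank(c(1:10, 11:20))
    idx <- utils::combn(20, 10)
    W <- colSums(matrix(pool[idx], nrow = 10)) - 10 * 11 / 2
    wObs <- sum(pool[1:10]) - 55
    pExact <- mean(W <= wObs | W >= (100 - wObs))  # two-sided, symmetric
    expect_equal(pc$p.value, pExact, tolerance = 1e-12)
})

test_that("two groups skip the omnibus with a warning", {
    expect_warning(r <- kruskalThenWilcoxon(list(a = 1:5, b = 6:10)),
                   "omnibus step skipped")
    expect_equal(nrow(r$pairwise), 1L)
})

test_that("chi-square: null table gives statistic 0, p 1", {
    r <- chisqFdr(rbind(a = c(50, 50), b = c(50, 50)))
    expect_equal(r$statistic, 0)
    expect_equal(r$p.value, 1)
})

test_that("chi-square statistic matches the direct formula", {
    tab <- rbind(wt = c(90, 10), mut = c(50, 50))
    r <- chisqFdr(tab)
    # oracle: hand expansion of sum (O - E)^2 / E
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(r$statistic, stat, tolerance = 1e-12)
    expect_equal(r$p.value, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("BH arithmetic and monotonicity", {
    r <- chisqFdr(rbind(a = c(30, 70), b = c(50, 50), c = c(45, 55)))
    expect_true(all(r$q.value >= r$p.value - 1e-15))
    expect_equal(stats::p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
    set.seed(4)
    for (i in 1:20) {
        p <- runif(7)
        q <- stats::p.adjust(p, "BH")
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-15))
        expect_true(all(q >= 0 & q <= 1))
    }
})

test_that("small expected counts trigger an exact-test recommendation", {
    expect_warning(chisqFdr(rbind(a = c(1, 60), b = c(0, 70))),
                   "exact test")
})

test_that("qPCR fold change: reference behaviour on constructed cases", {
    d <- expand.grid(gene = c("tgt", "pmp-3", "cdc-42"),
                     condition = c("ctrl", "rnai"),
                     replicate = 1:3, stringsAsFactors = FALSE)
    d$ct <- 20
    r <- qpcrFoldChange(d, "ctrl")
    expect_equal(r$foldChanges$foldChange, c(1, 1))

    d2 <- d
    d2$ct[d2$gene == "tgt" & d2$condition == "rnai"] <- 21
    r2 <- qpcrFoldChange(d2, "ctrl")
    expect_equal(
        r2$foldChanges$foldChange[r2$foldChanges$condition == "rnai"],
        0.5)
    expect_error(qpcrFoldChange(d[d$gene != "pmp-3", ], "ctrl"),
                 "reference gene")
})

test_that("qPCR matches an independent two-reference ddCt oracle", {
    set.seed(77)
    d <- expand.grid(gene = c("kle-2", "capg-1", "pmp-3", "cdc-42"),
                     condition = c("empty", "rnai"),
                     replicate = 1:3, stringsAsFactors = FALSE)
    d$ct <- runif(nrow(d), 18, 28)
    r <- qpcrFoldChange(d, "empty")

    # independent implementation: quantities 2^-Ct, geometric-mean
    # normalizer, mean-over-replicates ratio
    oracle <- function(g, cond) {
        q <- function(gene, cnd) {
            vapply(1:3, function(rep)
                2^(-d$ct[d$gene == gene & d$condition == cnd &
                             d$replicate == rep]), numeric(1))
        }
        nrm <- function(cnd) sqrt(q("pmp-3", cnd) * q("cdc-42", cnd))
        mean(q(g, cond) / nrm(cond)) / mean(q(g, "empty") / nrm("empty"))
    }
    for (g in c("kle-2", "capg-1")) for (cond in c("empty", "rnai")) {
        got <- r$foldChanges$foldChange[r$foldChanges$gene == g &
                                        r$foldChanges$condition == cond]
        expect_equal(got, oracle(g, cond), tolerance = 1e-12)
    }
})

test_that("qPCR fold change is invariant to a global Ct shift", {
    set.seed(78)
    d <- expand.grid(gene = c("tgt", "pmp-3", "cdc-42"),
                     condition = c("ctrl", "rnai"),
                     replicate = 1:3, stringsAsFactors = FALSE)
    d$ct <- runif(nrow(d), 15, 30)
    d2 <- d; d2$ct <- d2$ct + 3.7
    r1 <- qpcrFoldChange(d, "ctrl")
    r2 <- qpcrFoldChange(d2, "ctrl")
    expect_equal(r1$foldChanges$foldChange, r2$foldChanges$foldChange,
                 tolerance = 1e-12)
})
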