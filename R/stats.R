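#' Two-sample t test on group samples
#'
#' Two-tailed unpaired t test between two groups of per-unit values
#' (per-gonad mean E, per-class fractions, brood sizes, ...). The default
#' is Student's equal-variance test; Welch's unequal-variance test is
#' available and generally preferable when group variances differ.
#'
#' @param samples named list of two numeric vectors (group label ->
#'   values), or a \code{groupSamples()} object.
#' @param mode "student" (equal variances, default) or "welch".
#' @param tails 1 or 2 (default 2).
#' @param paired logical, default FALSE.
#' @return list with statistic, df, p.value, mode, groups, means.
#' @examples
#' tTestGroups(list(wt = c(0.21, 0.24, 0.22), mut = c(0.15, 0.13, 0.16)))
#' @export
tTestGroups <- function(samples, mode = c("student", "welch"), tails = 2,
                        paired = FALSE) {
    mode <- match.arg(mode)
    samples <- .asGroupSamples(samples, nGroups = 2L)
    x <- samples[[1]]; y <- samples[[2]]
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 values")
    if (mode == "student" && stats::var(x) == 0 && stats::var(y) == 0 &&
        !paired)
        stop("both groups have zero variance; use mode = 'welch' ",
             "or inspect the data")
    alt <- "two.sided"
    tt <- stats::t.test(x, y, var.equal = (mode == "student"),
                        paired = paired, alternative = alt)
    p <- tt$p.value
    if (tails == 1) p <- p / 2
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = p, mode = mode, tails = tails, paired = paired,
         groups = names(samples),
         means = c(mean(x), mean(y)))
}

.asGroupSamples <- function(samples, nGroups = NULL) {
    if (!is.list(samples) || is.null(names(samples)))
        stop("samples must be a named list of numeric vectors")
    if (!is.null(nGroups) && length(samples) != nGroups)
        stop("expected ", nGroups, " groups, got ", length(samples))
    lapply(samples, as.numeric)
}

#' Bonferroni adjustment
#'
#' p_i * m, clipped at 1.
#'
#' @param p numeric vector of p values.
#' @return adjusted p values, same order.
#' @examples
#' bonferroni(c(0.01, 0.02))  # 0.02 0.04
#' @export
bonferroni <- function(p) {
    stats::p.adjust(p, method = "bonferroni")
}

#' Kruskal-Wallis omnibus gated pairwise Wilcoxon tests
#'
#' The two-stage rank procedure for >= 3 groups: pairwise two-sided
#' Wilcoxon rank-sum tests are reported only when the Kruskal-Wallis
#' omnibus test is significant at \code{alpha}. Ties are handled by
#' midranks (the standard rank-test treatment). With exactly two groups
#' the omnibus step is skipped with a warning and the direct rank-sum
#' test is returned.
#'
#' @param samples named list of numeric vectors.
#' @param alpha omnibus significance gate (default 0.05).
#' @param exact passed to \code{wilcox.test}; NULL (default) lets it pick.
#' @return list with omnibus.p, omnibus.statistic, gated (logical),
#'   pairwise (data.frame group1, group2, statistic, p.value; NULL when
#'   gated out).
#' @export
kruskalThenWilcoxon <- function(samples, alpha = 0.05, exact = NULL) {
    samples <- .asGroupSamples(samples)
    ng <- length(samples)
    if (ng < 2L) stop("need at least 2 groups")
    pairTests <- function() {
        prs <- utils::combn(names(samples), 2L)
        do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
            a <- prs[1, j]; b <- prs[2, j]
            wt <- suppressWarnings(
                stats::wilcox.test(samples[[a]], samples[[b]],
                                   exact = exact))
            data.frame(group1 = a, group2 = b,
                       statistic = unname(wt$statistic),
                       p.value = wt$p.value)
        }))
    }
    if (ng == 2L) {
        warning("only 2 groups: omnibus step skipped, direct rank-sum")
        return(list(omnibus.p = NA_real_, omnibus.statistic = NA_real_,
                    gated = FALSE, alpha = alpha, pairwise = pairTests()))
    }
    kw <- stats::kruskal.test(samples)
    if (kw$p.value < alpha) {
        list(omnibus.p = kw$p.value,
             omnibus.statistic = unname(kw$statistic), gated = FALSE,
             alpha = alpha, pairwise = pairTests())
    } else {
        list(omnibus.p = kw$p.value,
             omnibus.statistic = unname(kw$statistic), gated = TRUE,
             alpha = alpha, pairwise = NULL)
    }
}

#' Chi-square tests with Benjamini-Hochberg FDR over a comparison family
#'
#' Pearson chi-square tests (no continuity correction) on 2 x k phenotype
#' count tables, with BH adjustment across the family of comparisons.
#' Typical use: each mutant background against the wildtype row of a
#' phenotype-category count table.
#'
#' @param counts integer matrix: one row per genotype/treatment, one
#'   column per phenotype category.
#' @param comparisons list of length-2 vectors of row names/indices;
#'   default compares every other row against the first row.
#' @return data.frame: group1, group2, statistic, df, p.value, q.value
#'   (BH). A warning recommends an exact test when any expected cell
#'   drops below 1.
#' @export
chisqFdr <- function(counts, comparisons = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("group", seq_len(nrow(counts)))
    if (is.null(comparisons))
        comparisons <- lapply(rownames(counts)[-1],
                              function(g) c(rownames(counts)[1], g))
    res <- do.call(rbind, lapply(comparisons, function(cmp) {
        tab <- counts[cmp, , drop = FALSE]
        exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(exp < 1))
            warning("expected cell count < 1 for ",
                    paste(cmp, collapse = " vs "),
                    "; consider an exact test")
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(group1 = as.character(cmp[1]),
                   group2 = as.character(cmp[2]),
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p.value = ct$p.value)
    }))
    res$q.value <- stats::p.adjust(res$p.value, method = "BH")
    res
}

#' qPCR relative quantification with two reference genes
#'
#' Delta-delta-Ct style relative fold change with amplification
#' efficiency \code{efficiency} (default 2): each well's relative
#' quantity is efficiency^(-Ct); per replicate, target quantities are
#' normalized by the geometric mean of the two reference genes'
#' quantities; the fold change of a condition is the mean normalized
#' quantity over replicates divided by the same mean in the control
#' condition. Replicate-level relative quantities are retained for
#' downstream t tests. A global shift of all Ct values cancels exactly.
#'
#' @param data data.frame with columns gene, condition, replicate, ct.
#' @param controlCondition the reference condition (e.g. empty-vector
#'   RNAi).
#' @param referenceGenes the two normalization genes (default pmp-3 and
#'   cdc-42 as in C. elegans germline qPCR practice).
#' @param efficiency amplification efficiency per cycle (> 1; default 2).
#' @param combine "geometric" (default) or "arithmetic" mean of the
#'   reference-gene quantities.
#' @return list with foldChanges (data.frame gene, condition, foldChange)
#'   and replicates (data.frame gene, condition, replicate,
#'   normalizedQuantity, relativeToControl).
#' @examples
#' d <- expand.grid(gene = c("tgt", "pmp-3", "cdc-42"),
#'                  condition = c("ctrl", "rnai"), replicate = 1:3)
#' d$ct <- 20 + (d$gene == "tgt") * (d$condition == "rnai") * 1
#' qpcrFoldChange(d, "ctrl")$foldChanges   # tgt rnai: 0.5
#' @export
qpcrFoldChange <- function(data, controlCondition,
                           referenceGenes = c("pmp-3", "cdc-42"),
                           efficiency = 2,
                           combine = c("geometric", "arithmetic")) {
    combine <- match.arg(combine)
    need <- c("gene", "condition", "replicate", "ct")
    if (!all(need %in% names(data)))
        stop("data must have columns: ", paste(need, collapse = ", "))
    if (efficiency <= 1) stop("efficiency must be > 1")
    if (any(data$ct <= 0)) stop("Ct values must be > 0")
    data$gene <- as.character(data$gene)
    data$condition <- as.character(data$condition)
    if (!controlCondition %in% data$condition)
        stop("control condition '", controlCondition, "' not present")
    conds <- unique(data$condition)
    for (cond in conds)
        for (rg in referenceGenes)
            if (!any(data$condition == cond & data$gene == rg))
                stop("reference gene '", rg, "' missing in condition '",
                     cond, "'")

    data$quantity <- efficiency^(-data$ct)
    key <- interaction(data$condition, data$replicate, drop = TRUE)
    normFac <- vapply(split(data, key), function(d) {
        q <- vapply(referenceGenes,
                    function(rg) mean(d$quantity[d$gene == rg]),
                    numeric(1))
        if (combine == "geometric") exp(mean(log(q))) else mean(q)
    }, numeric(1))
    data$normalizedQuantity <- data$quantity / normFac[as.character(key)]

    targets <- setdiff(unique(data$gene), referenceGenes)
    reps <- data[data$gene %in% targets,
                 c("gene", "condition", "replicate", "normalizedQuantity")]
    ctrlMean <- vapply(targets, function(g)
        mean(reps$normalizedQuantity[reps$gene == g &
                                     reps$condition == controlCondition]),
        numeric(1))
    reps$relativeToControl <- reps$normalizedQuantity / ctrlMean[reps$gene]

    fc <- do.call(rbind, lapply(targets, function(g) {
        do.call(rbind, lapply(conds, function(cond) {
            m <- mean(reps$normalizedQuantity[reps$gene == g &
                                              reps$condition == cond])
            data.frame(gene = g, condition = cond,
                       foldChange = m / ctrlMean[[g]])
        }))
    }))
    rownames(fc) <- NULL
    list(foldChanges = fc, replicates = reps,
         efficiency = efficiency, referenceGenes = referenceGenes,
         controlCondition = controlCondition, combine = combine)
}
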