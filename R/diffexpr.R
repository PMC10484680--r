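#' Median-of-ratios size factors
#'
#' Sequencing-depth normalization factors: for each sample, the median
#' over genes (restricted to genes with non-zero counts in every sample)
#' of the ratio of its count to the gene's geometric mean across samples.
#' When no gene is expressed in all samples, total-count ratios are used
#' with a warning.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
computeSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    stopifnot(all(counts >= 0), ncol(counts) >= 1L)
    logGeo <- rowMeans(log(counts))
    usable <- is.finite(logGeo)
    if (!any(usable)) {
        warning("no gene with non-zero counts in all samples; ",
                "falling back to total-count ratios")
        tot <- colSums(counts)
        return(tot / exp(mean(log(tot))))
    }
    apply(counts, 2L, function(cnt)
        exp(stats::median((log(cnt) - logGeo)[usable])))
}

#' Negative-binomial two-condition test
#'
#' A compact NB differential test: counts are scaled by size factors
#' (median-of-ratios unless supplied), per-gene dispersions are estimated
#' by the method of moments and shrunk in log space toward a fitted
#' mean-dispersion trend, and a Wald statistic on the log2 ratio of
#' normalized condition means (pseudocount 0.5) is referred to a
#' moderated t distribution whose degrees of freedom credit the trend's
#' contribution to the dispersion estimate. This stage is a
#' deliberate simplification of full NB differential frameworks (no
#' Cox-Reid adjustment, no fold-change shrinkage) — the analysis
#' contract here is the comparison design and downstream filtering, not
#' the estimator.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param conditions factor (or coercible) with exactly 2 levels; the
#'   log2 fold change is second level over first level.
#' @param sizeFactors optional per-sample factors; computed from
#'   \code{counts} when \code{NULL}.
#' @param pseudocount added to normalized condition means for finite
#'   fold changes.
#' @param shrink weight (0..1) of the trend in the log-space dispersion
#'   blend.
#' @return data.frame with columns \code{gene}, \code{baseMean},
#'   \code{log2FoldChange}, \code{pvalue}, \code{dispersion} and
#'   \code{allZero}. All-zero genes get p = 1 and log2FC = 0.
#' @export
nbTest <- function(counts, conditions, sizeFactors = NULL,
                   pseudocount = 0.5, shrink = 0.5) {
    counts <- as.matrix(counts)
    conditions <- factor(conditions)
    if (nlevels(conditions) != 2L)
        stop("exactly two conditions are required")
    if (length(conditions) != ncol(counts))
        stop("one condition label per sample is required")
    if (any(table(conditions) < 2L))
        stop("at least 2 samples per condition are required")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    stopifnot(all(sizeFactors > 0),
              length(sizeFactors) == ncol(counts))

    q <- sweep(counts, 2L, sizeFactors, "/")
    grpA <- conditions == levels(conditions)[1L]
    grpB <- conditions == levels(conditions)[2L]
    nA <- sum(grpA); nB <- sum(grpB)
    muA <- rowMeans(q[, grpA, drop = FALSE])
    muB <- rowMeans(q[, grpB, drop = FALSE])
    baseMean <- rowMeans(q)

    # method-of-moments dispersion from pooled within-group variance:
    # Var(K/s) = mu/s + alpha mu^2, so alpha = (v - xim*mu) / mu^2
    vA <- apply(q[, grpA, drop = FALSE], 1L, stats::var)
    vB <- apply(q[, grpB, drop = FALSE], 1L, stats::var)
    vPooled <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    xim <- mean(1 / sizeFactors)
    muBar <- (muA * nA + muB * nB) / (nA + nB)
    dispMoM <- (vPooled - xim * muBar) / muBar^2
    dispMoM[!is.finite(dispMoM)] <- NA_real_
    floorDisp <- 1e-8
    rawDisp <- pmax(dispMoM, floorDisp)

    # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted on genes with
    # informative moment estimates
    use <- !is.na(dispMoM) & dispMoM > 0 & muBar > 0
    trend <- rep(NA_real_, nrow(counts))
    if (sum(use) >= 10L) {
        fit <- stats::lm(dispMoM[use] ~ I(1 / muBar[use]))
        a0 <- max(unname(stats::coef(fit)[1L]), floorDisp)
        a1 <- max(unname(stats::coef(fit)[2L]), 0)
        trend <- a0 + a1 / pmax(muBar, 1e-8)
    } else {
        trend <- rep(max(mean(dispMoM[use], na.rm = TRUE), floorDisp,
                         na.rm = TRUE), nrow(counts))
    }
    trend[!is.finite(trend)] <- floorDisp
    disp <- exp((1 - shrink) * log(pmax(rawDisp, floorDisp, na.rm = TRUE)) +
                shrink * log(pmax(trend, floorDisp)))
    disp[is.na(rawDisp)] <- trend[is.na(rawDisp)]
    disp <- pmin(pmax(disp, floorDisp), 20)

    log2FC <- log2((muB + pseudocount) / (muA + pseudocount))
    # delta method on the log2 of condition means
    varMeanA <- (xim * muA + disp * muA^2) / nA
    varMeanB <- (xim * muB + disp * muB^2) / nB
    se2 <- varMeanA / ((muA + pseudocount)^2 * log(2)^2) +
           varMeanB / ((muB + pseudocount)^2 * log(2)^2)
    # moderated reference: the blended dispersion is part genewise
    # (nA + nB - 2 df) and part trend (fitted across all genes, effectively
    # infinite df), so the residual df is inflated by 1 / (1 - shrink)
    df <- (nA + nB - 2L) / max(1 - shrink, 0.25)
    stat <- log2FC / sqrt(se2)
    pvalue <- 2 * stats::pt(-abs(stat), df = df)

    allZero <- rowSums(counts) == 0L
    log2FC[allZero] <- 0
    pvalue[allZero | !is.finite(pvalue)] <- 1
    genes <- if (is.null(rownames(counts)))
        sprintf("gene%05d", seq_len(nrow(counts))) else rownames(counts)
    data.frame(gene = genes, baseMean = baseMean,
               log2FoldChange = log2FC, pvalue = pvalue,
               dispersion = disp, allZero = allZero,
               row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Hand-written BH step-up with monotonicity enforcement: p-values are
#' ranked, scaled by n/rank, and a running minimum from the largest rank
#' down guarantees monotone adjusted values capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1]; NA/NaN are rejected.
#' @return adjusted FDR values in input order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L)
        return(numeric(0))
    if (anyNA(p))
        stop("NA/NaN p-values are not allowed")
    stopifnot(all(p >= 0 & p <= 1))
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Fold-change / FDR filter for differentially expressed genes
#'
#' DEGs are genes with linear fold change >= \code{fcLinear} (up) or
#' <= 1/\code{fcLinear} (down) — inclusive comparators — and adjusted
#' p-value strictly below \code{fdr}.
#'
#' @param results data.frame with \code{gene}, \code{log2FoldChange} and
#'   either \code{padj} or \code{pvalue} (adjusted with [bhAdjust()] when
#'   \code{padj} is absent).
#' @param fcLinear linear fold-change threshold (>= 1).
#' @param fdr FDR threshold (strict \code{<}).
#' @return list with \code{up}, \code{down} (character vectors) and
#'   \code{table}, the input with \code{padj} and \code{isDEG} columns.
#' @export
degFilter <- function(results, fcLinear = 2, fdr = 0.05) {
    stopifnot(is.data.frame(results), fcLinear >= 1,
              all(c("gene", "log2FoldChange") %in% colnames(results)))
    if (!"padj" %in% colnames(results)) {
        if (!"pvalue" %in% colnames(results))
            stop("results need a 'padj' or 'pvalue' column")
        results$padj <- bhAdjust(results$pvalue)
    }
    lfcCut <- log2(fcLinear)
    up <- results$log2FoldChange >= lfcCut & results$padj < fdr
    down <- results$log2FoldChange <= -lfcCut & results$padj < fdr
    results$isDEG <- up | down
    list(up = sort(results$gene[up]),
         down = sort(results$gene[down]),
         table = results)
}
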