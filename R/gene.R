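# Gene-level aggregation: positional SNP-to-gene annotation and the SNP-wise
# mean chi-square test with an LD-eigenvalue weighted null.

#' Map SNPs to gene intervals
#'
#' A SNP is assigned to every gene whose `[start - window, end + window]`
#' interval (1-based, inclusive) contains its position. Genes without SNPs
#' are omitted.
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos`.
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param window symmetric flank in base pairs (default 0).
#' @return named list: per gene, the character vector of contained SNP ids.
#' @export
annotateSnpsToGenes <- function(snps, genes, window = 0L) {
    bad <- genes$start > genes$end
    if (any(bad))
        stop("malformed interval for gene(s): ",
             paste(genes$gene[bad], collapse = ", "))
    snpGr <- GenomicRanges::GRanges(
        snps$chrom, IRanges::IRanges(snps$pos, width = 1L))
    geneGr <- GenomicRanges::GRanges(
        genes$chrom,
        IRanges::IRanges(pmax(genes$start - window, 1L), genes$end + window))
    hits <- GenomicRanges::findOverlaps(snpGr, geneGr)
    sp <- split(snps$snp[S4Vectors::queryHits(hits)],
                genes$gene[S4Vectors::subjectHits(hits)])
    lapply(sp, unique)
}

# Imhof-style numerical inversion for the upper tail of a positively weighted
# sum of independent 1-df chi-squares; gamma moment matching backs it up in
# the extreme tail where the oscillating integral loses accuracy.
.weightedChisqTail <- function(q, lambda, tol = 1e-9) {
    lambda <- lambda[lambda > 1e-12]
    if (length(lambda) == 0L) return(1)
    # equal weights (e.g. identity LD): plain scaled chi-square, exact
    if (diff(range(lambda)) < 1e-10 * max(lambda))
        return(pchisq(q / lambda[1L], df = length(lambda),
                      lower.tail = FALSE))
    gammaP <- function() {
        sh <- sum(lambda)^2 / (2 * sum(lambda^2))
        sc <- 2 * sum(lambda^2) / sum(lambda)
        pgamma(q, shape = sh, scale = sc, lower.tail = FALSE)
    }
    integrand <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
        rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
        sin(theta) / (u * rho)
    }
    p <- tryCatch({
        it <- integrate(integrand, 0, Inf, rel.tol = tol, abs.tol = tol,
                        subdivisions = 2000L, stop.on.error = FALSE)
        0.5 + it$value / pi
    }, error = function(e) NA_real_)
    if (!is.finite(p) || p < 1e-12 || p > 1) p <- gammaP()
    min(max(p, 1e-300), 1)
}

#' LD-aware gene-based association test (SNP-wise mean model)
#'
#' The gene statistic is the sum of the per-SNP 1-df chi-squares; under the
#' null the statistic is distributed as a weighted sum of independent 1-df
#' chi-squares with weights equal to the eigenvalues of the SNP correlation
#' (LD) matrix. The tail probability is obtained by numerical inversion of
#' the characteristic function (Imhof), with a gamma moment-matching fallback
#' for the extreme tail. `Z = qnorm(1 - p)`.
#'
#' @param p per-SNP p-values (two-sided); alternatively supply `chisq`.
#' @param ld signed SNP correlation matrix (see [snpCorrelation()]); a
#'   non-positive-semidefinite matrix is projected to the nearest PSD with a
#'   warning.
#' @param chisq per-SNP 1-df chi-squares (overrides `p`).
#' @param gene,snps optional labels carried into the result.
#' @return one-row data.frame: gene, nSnps, stat (mean chi-square), z, p.
#' @export
geneTest <- function(p = NULL, ld, chisq = NULL, gene = NA_character_,
                     snps = NULL) {
    if (is.null(chisq)) {
        if (is.null(p)) stop("supply p or chisq")
        chisq <- qchisq(p, df = 1L, lower.tail = FALSE)
    }
    m <- length(chisq)
    ld <- as.matrix(ld)
    stopifnot(nrow(ld) == m, ncol(ld) == m)
    ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
        warning("LD matrix not positive semidefinite; projecting")
        e <- eigen(ld, symmetric = TRUE)
        ld <- e$vectors %*% (t(e$vectors) * pmax(e$values, 0))
        ev <- pmax(e$values, 0)
    }
    q <- sum(chisq)
    pg <- .weightedChisqTail(q, pmax(ev, 0))
    data.frame(gene = gene, nSnps = m, stat = q / m,
               z = qnorm(pg, lower.tail = FALSE), p = pg,
               snps = if (is.null(snps)) NA_character_
                      else paste(snps, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Run gene-based tests across an annotation
#'
#' @param assoc association data.frame with `snp` and `p`.
#' @param geneMap output of [annotateSnpsToGenes()].
#' @param dosageMat samples x SNPs dosage matrix used to estimate in-sample
#'   LD for each gene.
#' @return data.frame with one row per gene with at least one tested SNP.
#' @export
geneTestAll <- function(assoc, geneMap, dosageMat) {
    rows <- lapply(names(geneMap), function(g) {
        ss <- intersect(geneMap[[g]], assoc$snp)
        ss <- intersect(ss, colnames(dosageMat))
        if (length(ss) == 0L) return(NULL)
        pv <- assoc$p[match(ss, assoc$snp)]
        R <- snpCorrelation(dosageMat[, ss, drop = FALSE])
        geneTest(p = pv, ld = R, gene = g, snps = ss)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    rownames(out) <- NULL
    out
}

#' Bonferroni threshold for gene-based tests
#'
#' @param nGenes number of genes tested.
#' @param alpha family-wise error rate.
#' @return `alpha / nGenes`.
#' @export
geneBonferroni <- function(nGenes, alpha = 0.05) {
    stopifnot(nGenes >= 1)
    alpha / nGenes
}
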