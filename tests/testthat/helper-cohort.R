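# fixtures are generated in code; all randomness is seeded per test

# a cohort with the canonical loading structure and the study's sample size
structuredCohort <- function(n = 1158, seed = 1, nSnps = 5, ...) {
    simulateCohort(simConfig(nSamples = n, nSnps = nSnps, seed = seed, ...))
}

# transformed (per-study INT) panel of a cohort
transformedPanel <- function(cohort) {
    transformPanel(biomarkers(cohort), sampleData(cohort)$study)
}

# data drawn from an exact k-factor model with given loadings/uniqueness
factorPanel <- function(n, L, uniq, seed) {
    set.seed(seed)
    k <- ncol(L)
    S <- matrix(rnorm(n * k), n, k)
    X <- S %*% t(L) + matrix(rnorm(n * nrow(L)), n) %*% diag(sqrt(uniq))
    colnames(X) <- rownames(L)
    X
}

# independent greedy-free oracle for LD clumping: enumerate admissible
# (pairwise r2 <= r2Max) subsets of significant SNPs and pick the one that
# wins lexicographic comparison on the sorted p-values
clumpOracle <- function(assoc, ld, r2Max = 0.6, pMax = 5e-8) {
    sig <- assoc[assoc$p < pMax, , drop = FALSE]
    snps <- sig$snp
    best <- NULL
    for (bits in 0:(2^length(snps) - 1)) {
        sel <- snps[bitwAnd(bits, 2^(seq_along(snps) - 1)) > 0]
        if (length(sel) < 2L ||
            all(ld[sel, sel][upper.tri(diag(length(sel)))] <= r2Max)) {
            ps <- sort(sig$p[match(sel, sig$snp)])
            if (is.null(best)) { best <- sel; bestP <- ps; next }
            cmp <- 0
            for (i in seq_len(max(length(ps), length(bestP)))) {
                a <- if (i <= length(ps)) ps[i] else Inf
                b <- if (i <= length(bestP)) bestP[i] else Inf
                if (a < b) { cmp <- -1; break }
                if (a > b) { cmp <- 1; break }
            }
            if (cmp < 0 || (cmp == 0 && length(ps) > length(bestP))) {
                best <- sel; bestP <- ps
            }
        }
    }
    sort(best)
}
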