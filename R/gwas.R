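# Single-SNP association engine: QC, vectorized OLS under main / stratified /
# interaction models, inflation diagnostics, variance explained, clumping.

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square goodness of fit of the hard-called
#' genotype counts against Hardy-Weinberg expectations. Monomorphic SNPs
#' return p = 1 by convention.
#'
#' @param nAA,nAa,naa genotype counts (vectorized).
#' @return p-value(s).
#' @export
hweTest <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    if (any(n <= 0)) stop("total genotype count must be positive")
    p <- (2 * nAA + nAa) / (2 * n)
    mono <- p <= 0 | p >= 1
    eAA <- n * p^2; eAa <- 2 * n * p * (1 - p); eaa <- n * (1 - p)^2
    chi2 <- ifelse(mono, 0,
                   (nAA - eAA)^2 / pmax(eAA, 1e-300) +
                   (nAa - eAa)^2 / pmax(eAa, 1e-300) +
                   (naa - eaa)^2 / pmax(eaa, 1e-300))
    ifelse(mono, 1, pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Default QC thresholds
#'
#' MAF at least 0.01 in every study, imputation quality strictly above 0.30,
#' and Hardy-Weinberg p of at least 5e-6.
#' @param mafMin,impR2Min,hwePMin the three thresholds.
#' @export
qcThresholds <- function(mafMin = 0.01, impR2Min = 0.30, hwePMin = 5e-6) {
    stopifnot(mafMin > 0, mafMin < 1, impR2Min > 0, impR2Min < 1,
              hwePMin > 0, hwePMin < 1)
    list(mafMin = mafMin, impR2Min = impR2Min, hwePMin = hwePMin)
}

#' Filter SNPs on allele frequency, imputation quality and HWE
#'
#' A SNP survives iff its MAF meets `mafMin` in *every* study, its imputation
#' quality strictly exceeds `impR2Min`, and its Hardy-Weinberg p (chi-square
#' on rounded hard calls, computed per study; females only for X-chromosome
#' SNPs, where hemizygous male 0/2 coding would fake disequilibrium) is at
#' least `hwePMin`. Idempotent by construction.
#'
#' @param cohort a [CsfCohort-class].
#' @param thresholds see [qcThresholds()].
#' @return list with `keep` (SNP names), logical `pass`, and `counts`, the
#'   per-criterion exclusion tally.
#' @export
qcFilter <- function(cohort, thresholds = qcThresholds()) {
    G <- dosages(cohort)
    info <- snpInfo(cohort)
    sdat <- sampleData(cohort)
    studies <- levels(factor(sdat$study))
    m <- ncol(G)
    mafOK <- rep(TRUE, m); hweOK <- rep(TRUE, m)
    for (s in studies) {
        idx <- sdat$study == s
        Gs <- G[idx, , drop = FALSE]
        af <- colMeans(Gs) / 2
        maf <- pmin(af, 1 - af)
        mafOK <- mafOK & maf >= thresholds$mafMin
        hwep <- vapply(seq_len(m), function(j) {
            g <- Gs[, j]
            if (info$chrom[j] %in% c("X", "23")) g <- g[sdat$sex[idx] == 1]
            hc <- round(g)
            hweTest(sum(hc == 0), sum(hc == 1), sum(hc == 2))
        }, 0)
        hweOK <- hweOK & hwep >= thresholds$hwePMin
    }
    impOK <- info$impQuality > thresholds$impR2Min
    pass <- mafOK & impOK & hweOK
    if (!any(pass)) warning("no SNPs pass QC")
    list(keep = info$snp[pass], pass = pass,
         counts = c(maf = sum(!mafOK), impQuality = sum(!impOK),
                    hwe = sum(!hweOK), kept = sum(pass)))
}

# residualize a matrix on the column space of C via one QR decomposition
.residualize <- function(qrC, M) M - qr.fitted(qrC, M)

#' Per-SNP linear association models
#'
#' Ordinary least squares of a standardized component score on each SNP's
#' dosage. `model = "main"` adjusts for sex and the supplied covariates;
#' `"male"` / `"female"` fit within the sex stratum without the sex term;
#' `"interaction"` adds dosage x sex (female = 1) and reports the product
#' term — the female-minus-male difference in the per-allele effect. The
#' algebra residualizes outcome and dosages on the covariate design once
#' (Frisch-Waugh), so estimates, standard errors and t-based p-values are
#' exactly those of the full OLS fit. SNPs whose (residualized) design is
#' numerically collinear — e.g. monomorphic within a stratum — are dropped
#' and logged in the `"failures"` attribute rather than reported.
#'
#' @param dosageMat samples x SNPs dosage matrix.
#' @param outcome numeric outcome (a PC score vector).
#' @param covariates data.frame or matrix of covariates (no intercept; one is
#'   added), or NULL.
#' @param model one of "main", "male", "female", "interaction".
#' @param sex 0/1 vector, required for all models except a covariate-free
#'   main model.
#' @param snpInfo optional per-SNP metadata merged into the result.
#' @param outcomeName,study labels carried into the records.
#' @return data.frame with one row per converged SNP: snp, beta, se, p, n,
#'   model, outcome, study (plus any snpInfo columns).
#' @export
runGwas <- function(dosageMat, outcome, covariates = NULL,
                    model = c("main", "male", "female", "interaction"),
                    sex = NULL, snpInfo = NULL, outcomeName = "PC",
                    study = NA_character_) {
    model <- match.arg(model)
    G <- as.matrix(dosageMat)
    y <- as.numeric(outcome)
    n0 <- length(y)
    Cov <- if (is.null(covariates)) matrix(0, n0, 0L)
    else model.matrix(~ ., data = as.data.frame(covariates))[, -1L, drop = FALSE]
    if (model %in% c("male", "female")) {
        if (is.null(sex)) stop("sex is required for stratified models")
        keep <- sex == (model == "female")
        G <- G[keep, , drop = FALSE]; y <- y[keep]
        Cov <- Cov[keep, , drop = FALSE]
        C <- cbind(`(Intercept)` = 1, Cov)
    } else if (model == "main") {
        C <- cbind(`(Intercept)` = 1, Cov)
        if (!is.null(sex)) C <- cbind(C, sex = sex)
    } else {
        if (is.null(sex)) stop("sex is required for the interaction model")
        C <- cbind(`(Intercept)` = 1, Cov, sex = sex)
    }
    n <- length(y)
    qrC <- qr(C)
    yt <- .residualize(qrC, y)
    Gt <- .residualize(qrC, G)
    snps <- colnames(G)
    if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
    if (model == "interaction") {
        Ht <- .residualize(qrC, G * sex)
        a <- colSums(Gt^2); b <- colSums(Gt * Ht); d <- colSums(Ht^2)
        det <- a * d - b^2
        ok <- det > 1e-10 * pmax(a * d, 1e-300) & a > 1e-10 & d > 1e-10
        r1 <- colSums(Gt * yt); r2 <- colSums(Ht * yt)
        bG <- (d * r1 - b * r2) / det
        bI <- (a * r2 - b * r1) / det
        df <- n - ncol(C) - 2L
        rss <- sum(yt^2) - bG * r1 - bI * r2
        sigma2 <- pmax(rss, 0) / df
        se <- sqrt(sigma2 * a / det)
        beta <- bI
    } else {
        a <- colSums(Gt^2)
        ok <- a > 1e-10
        r1 <- colSums(Gt * yt)
        beta <- r1 / a
        df <- n - ncol(C) - 1L
        rss <- sum(yt^2) - beta * r1
        sigma2 <- pmax(rss, 0) / df
        se <- sqrt(sigma2 / a)
    }
    tstat <- beta / se
    p <- 2 * pt(-abs(tstat), df)
    res <- data.frame(snp = snps, beta = beta, se = se, p = p, n = n,
                      model = model, outcome = outcomeName, study = study,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(snpInfo))
        res <- merge(snpInfo, res, by = "snp", sort = FALSE)
    failures <- data.frame(snp = snps[!ok],
                           reason = rep("collinear or monomorphic design",
                                        sum(!ok)),
                           stringsAsFactors = FALSE)
    res <- res[res$snp %in% snps[ok], , drop = FALSE]
    res <- res[order(match(res$snp, snps)), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "failures") <- failures
    res
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square (from two-sided p-values)
#' divided by the null median 0.4549; values near 1 indicate no systematic
#' test-statistic inflation.
#'
#' @param p vector of p-values (or a data.frame with a `p` column).
#' @return lambda.
#' @export
genomicLambda <- function(p) {
    if (is.data.frame(p)) p <- p$p
    p <- p[is.finite(p)]
    if (length(p) < 100L)
        warning("fewer than 100 records; lambda estimate is unstable")
    median(qchisq(p, df = 1L, lower.tail = FALSE)) / qchisq(0.5, df = 1L)
}

#' Variance explained by a SNP (or dosage block) beyond covariates
#'
#' Difference in R-squared between the model with the SNP dosage(s) and the
#' covariate-only baseline.
#'
#' @param dosage numeric vector or matrix (multi-SNP locus block).
#' @param outcome numeric outcome.
#' @param covariates covariate data.frame/matrix or NULL.
#' @return delta R-squared in \[0, 1\].
#' @export
deltaR2 <- function(dosage, outcome, covariates = NULL) {
    y <- as.numeric(outcome)
    Cov <- if (is.null(covariates)) matrix(1, length(y), 1L)
    else cbind(1, model.matrix(~ ., as.data.frame(covariates))[, -1L, drop = FALSE])
    r2 <- function(X) {
        f <- lm.fit(X, y)
        1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    }
    max(0, r2(cbind(Cov, as.matrix(dosage))) - r2(Cov))
}

#' Signed dosage correlation and LD matrices
#'
#' @param dosageMat samples x SNPs dosage matrix.
#' @return `snpCorrelation()` the signed Pearson correlation matrix;
#'   `ldMatrix()` its square (r-squared).
#' @export
snpCorrelation <- function(dosageMat) {
    r <- suppressWarnings(cor(as.matrix(dosageMat)))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    r
}

#' @rdname snpCorrelation
#' @export
ldMatrix <- function(dosageMat) snpCorrelation(dosageMat)^2

#' Greedy selection of independent genome-wide significant SNPs
#'
#' Significant SNPs (p below `pMax`) are visited in order of ascending p; a
#' SNP is accepted iff its LD r-squared with every already-accepted SNP is at
#' most `r2Max`. Missing LD entries are treated as r-squared 0 with a
#' warning.
#'
#' @param assoc data.frame with columns `snp` and `p`.
#' @param ld r-squared matrix with SNP dimnames.
#' @param r2Max LD ceiling (default 0.6).
#' @param pMax significance threshold (default 5e-8).
#' @return the accepted rows of `assoc`, ordered by p.
#' @export
selectIndependentHits <- function(assoc, ld, r2Max = 0.6, pMax = 5e-8) {
    sig <- assoc[assoc$p < pMax, , drop = FALSE]
    sig <- sig[order(sig$p), , drop = FALSE]
    if (nrow(sig) == 0L) return(sig)
    accepted <- character()
    keep <- logical(nrow(sig))
    warned <- FALSE
    for (i in seq_len(nrow(sig))) {
        s <- sig$snp[i]
        r2 <- vapply(accepted, function(a) {
            if (s %in% rownames(ld) && a %in% colnames(ld)) ld[s, a]
            else { warned <<- TRUE; 0 }
        }, 0)
        if (all(r2 <= r2Max)) {
            accepted <- c(accepted, s)
            keep[i] <- TRUE
        }
    }
    if (warned) warning("missing LD entries treated as r2 = 0")
    out <- sig[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
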