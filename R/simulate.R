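# Synthetic two-study cohort generator. The defaults reproduce the study
# conditions the analysis was designed for: ~973-1158 elderly participants in
# two studies, six CSF analytes with the canonical five-component loading
# structure, probit diagnosis thresholds at -1.47 / 0.40 SD of the latent
# scale, and female mean shifts of -0.40 SD (injury/inflammation) and
# +0.21 SD (non-AD synaptic functioning).

#' Canonical loading structure of the six CSF biomarkers
#'
#' The 6 x 5 structure matrix used as the generator default: tau and pTau
#' anchor the tau pathology/degeneration component, Abeta42 alone defines the
#' Abeta pathology component, NfL the injury/inflammation component, YKL-40
#' the non-AD inflammation component and neurogranin the non-AD synaptic
#' functioning component.
#'
#' @return 6 x 5 numeric matrix with marker rownames and PC1..PC5 colnames.
#' @export
defaultLoadingMatrix <- function() {
    L <- rbind(
        tau   = c(0.87, -0.06, 0.23, 0.24, 0.27),
        pTau  = c(0.91, -0.08, 0.14, 0.20, 0.26),
        Abeta = c(-0.07, 1.00, -0.03, 0.00, 0.04),
        NfL   = c(0.21, -0.03, 0.94, 0.25, 0.08),
        YKL40 = c(0.32, 0.00, 0.32, 0.88, 0.17),
        Ng    = c(0.51, 0.07, 0.10, 0.18, 0.83))
    colnames(L) <- paste0("PC", 1:5)
    L
}

#' Default residual (uniqueness) variances for the six markers
#'
#' One minus the communality implied by [defaultLoadingMatrix()], floored at
#' 0.005 (rounded published loadings can imply communalities slightly above 1).
#' @export
defaultUniqueness <- function() {
    u <- 1 - rowSums(defaultLoadingMatrix()^2)
    pmax(u, 0.005)
}

.COMPONENT_TAGS <- c(
    PC1 = "tau pathology/degeneration",
    PC2 = "Abeta pathology",
    PC3 = "injury/inflammation",
    PC4 = "non-AD inflammation",
    PC5 = "non-AD synaptic functioning")

#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the cohort generator.
#'
#' @param nSamples,nSnps cohort and panel size.
#' @param mafRange range the per-SNP minor allele frequency is drawn from.
#' @param loadingMatrix 6 x 5 biomarker-by-component structure matrix.
#' @param uniqueness 6-vector of residual variances on the marker scale.
#' @param snpEffects data.frame with columns `snp` (index), `component`
#'   (index 1..5), `beta` (per-allele effect in SD) and optionally
#'   `betaFemale` (additional female-only per-allele effect), or NULL.
#' @param sexShifts 5-vector of female-minus-male PC mean differences in SD.
#' @param diagCoeffs 5-vector of standardized PC effects on latent AD.
#' @param diagThresholds two increasing cutpoints on the latent AD SD scale
#'   separating control / MCI / AD.
#' @param missingRate probability a biomarker cell is missing (MCAR).
#' @param nStudies number of studies (additive assay offsets are planted per
#'   study and removed again by the per-study inverse normal transform).
#' @param xFraction fraction of SNPs placed on the X chromosome (hemizygous
#'   males coded 0/2).
#' @param distortion apply the monotone marginal distortion exp(x / 2) to the
#'   raw biomarker scale so the rank-based transform has real work to do.
#' @param studyShift additive raw-scale study offset (per additional study).
#' @param seed integer seed; the full cohort is reproducible from
#'   (config, seed).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 973, nSnps = 1000,
                      mafRange = c(0.05, 0.5),
                      loadingMatrix = defaultLoadingMatrix(),
                      uniqueness = defaultUniqueness(),
                      snpEffects = NULL,
                      sexShifts = c(0, 0, -0.40, 0, 0.21),
                      diagCoeffs = c(0.41, -0.34, 0.40, 0, 0),
                      diagThresholds = c(-1.47, 0.40),
                      missingRate = 0.10,
                      nStudies = 2L,
                      xFraction = 0,
                      distortion = TRUE,
                      studyShift = 0.3,
                      seed = 1L) {
    if (length(mafRange) != 2L || any(mafRange <= 0) || any(mafRange >= 1) ||
        mafRange[1] > mafRange[2])
        stop("mafRange must be an increasing pair within (0, 1)")
    if (!is.matrix(loadingMatrix) || nrow(loadingMatrix) != 6L ||
        ncol(loadingMatrix) != 5L)
        stop("loadingMatrix must be 6 x 5")
    if (length(uniqueness) != 6L || any(uniqueness < 0))
        stop("uniqueness must be six non-negative variances")
    if (length(diagThresholds) != 2L || diff(diagThresholds) <= 0)
        stop("diagThresholds must be strictly increasing")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must be in [0, 1)")
    if (!is.null(snpEffects)) {
        snpEffects <- as.data.frame(snpEffects)
        if (!all(c("snp", "component", "beta") %in% names(snpEffects)))
            stop("snpEffects needs columns snp, component, beta")
        if (is.null(snpEffects$betaFemale)) snpEffects$betaFemale <- 0
        if (any(snpEffects$snp < 1 | snpEffects$snp > nSnps) ||
            any(snpEffects$component < 1 | snpEffects$component > 5))
            stop("snpEffects indexes a SNP or component outside the panel")
    }
    structure(list(nSamples = as.integer(nSamples), nSnps = as.integer(nSnps),
                   mafRange = mafRange, loadingMatrix = loadingMatrix,
                   uniqueness = uniqueness, snpEffects = snpEffects,
                   sexShifts = sexShifts, diagCoeffs = diagCoeffs,
                   diagThresholds = diagThresholds, missingRate = missingRate,
                   nStudies = as.integer(nStudies), xFraction = xFraction,
                   distortion = isTRUE(distortion), studyShift = studyShift,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Autosomal dosages are Binomial(2, p); X-chromosome male dosages are
#' 2 * Bernoulli(p) so hemizygous males carry 0 or 2 copies, matching the
#' dosage coding used on the X throughout the package.
#'
#' @param n samples, `m` SNPs.
#' @param m number of SNPs.
#' @param mafRange pair within (0, 1); per-SNP frequency drawn uniformly.
#' @param xFraction fraction of SNPs assigned to the X chromosome.
#' @param sex 0/1 vector (female = 1); required when `xFraction > 0`.
#' @param seed optional integer seed.
#' @param blockSize,blockR optional local LD structure: SNPs are grouped in
#'   consecutive blocks of `blockSize` whose latent liabilities share an
#'   exchangeable correlation `blockR` (Gaussian-copula genotypes with
#'   Hardy-Weinberg margins); the defaults give independent SNPs.
#' @return list with `dosages` (n x m), and `info` data.frame
#'   (snp, chrom, pos, ref, alt, eaf, impQuality). Imputation-quality values
#'   are drawn Uniform(0.3, 1) so downstream QC filtering has work to do.
#' @export
simulateGenotypes <- function(n, m, mafRange = c(0.05, 0.5), xFraction = 0,
                              sex = NULL, seed = NULL, blockSize = 1L,
                              blockR = 0) {
    if (!is.null(seed)) set.seed(seed)
    if (n < 1 || m < 1) stop("n and m must be at least 1")
    if (length(mafRange) != 2L || any(mafRange <= 0) || any(mafRange >= 1))
        stop("mafRange must lie within (0, 1)")
    if (xFraction > 0 && is.null(sex))
        stop("sex is required when simulating X-chromosome SNPs")
    p <- runif(m, mafRange[1], mafRange[2])
    nX <- round(xFraction * m)
    isX <- seq_len(m) > (m - nX)
    G <- matrix(0, n, m)
    corArm <- if (blockSize > 1L && blockR > 0) {
        # exchangeable latent correlation: z = sqrt(r) * shared + sqrt(1-r) * own
        function(shared) sqrt(blockR) * shared + sqrt(1 - blockR) * rnorm(n)
    } else NULL
    block <- (seq_len(m) - 1L) %/% max(blockSize, 1L)
    shared1 <- shared2 <- NULL
    curBlock <- -1L
    for (j in seq_len(m)) {
        if (!is.null(corArm) && block[j] != curBlock) {
            curBlock <- block[j]
            shared1 <- rnorm(n); shared2 <- rnorm(n)
        }
        if (isX[j]) {
            male <- sex == 0
            G[!male, j] <- rbinom(sum(!male), 2L, p[j])
            G[male, j] <- 2L * rbinom(sum(male), 1L, p[j])
        } else if (is.null(corArm)) {
            G[, j] <- rbinom(n, 2L, p[j])
        } else {
            # two latent haplotype liabilities per sample, thresholded at the
            # allele frequency, keep HWE margins within the block copula
            a1 <- qnorm(p[j], lower.tail = FALSE)
            G[, j] <- (corArm(shared1) > a1) + (corArm(shared2) > a1)
        }
    }
    snp <- sprintf("snp%04d", seq_len(m))
    colnames(G) <- snp
    # avoid strand-ambiguous (A/T, C/G) pairs so cross-study harmonization
    # never has to drop a simulated variant
    alleles <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(alleles, c(r, comp[[r]])), 1L), "")
    info <- data.frame(snp = snp,
                       chrom = ifelse(isX, "X", "1"),
                       pos = seq_len(m) * 1000L,
                       ref = ref, alt = unname(alt),
                       eaf = p,
                       impQuality = runif(m, 0.3, 1.0),
                       stringsAsFactors = FALSE)
    list(dosages = G, info = info)
}

#' Categorize a latent Alzheimer's disease index into control / MCI / AD
#'
#' The latent index is the linear combination of PC scores (plus optional
#' covariate terms) with a normal residual scaled so the index has unit
#' variance; samples below the first threshold are controls, between the
#' thresholds MCI, above the second AD.
#'
#' @param pcScores n x 5 matrix of component scores.
#' @param diagCoeffs 5-vector of standardized PC effects on the latent index.
#' @param diagThresholds increasing pair of cutpoints in latent SD units.
#' @param covariates,covariateEffects optional design matrix and coefficient
#'   vector added to the linear predictor.
#' @param seed optional integer seed.
#' @return ordered factor control < MCI < AD, with the latent index in
#'   attribute `"latent"`.
#' @export
simulateDiagnosis <- function(pcScores, diagCoeffs,
                              diagThresholds = c(-1.47, 0.40),
                              covariates = NULL, covariateEffects = NULL,
                              seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (diff(diagThresholds) <= 0)
        stop("diagThresholds must be strictly increasing")
    pcScores <- as.matrix(pcScores)
    lp <- drop(pcScores %*% diagCoeffs)
    if (!is.null(covariates) && !is.null(covariateEffects))
        lp <- lp + drop(as.matrix(covariates) %*% covariateEffects)
    resVar <- max(1 - var(lp), 0.02)
    latent <- lp + rnorm(length(lp), sd = sqrt(resVar))
    d <- cut(latent, c(-Inf, diagThresholds, Inf), labels = .DIAG_LEVELS,
             right = FALSE)
    d <- factor(d, .DIAG_LEVELS, ordered = TRUE)
    attr(d, "latent") <- latent
    d
}

# sign-preserving monotone marginal distortion: creates the strong right skew
# typical of raw CSF analyte concentrations
.distort <- function(x) exp(x / 2)

#' Generate biomarkers, covariates and diagnosis on top of given genotypes
#'
#' Component scores are drawn standard normal, shifted by planted per-allele
#' SNP effects (female-only effects apply only when sex = 1) and by the
#' female-vs-male mean shifts; the six biomarkers are loadings x scores plus
#' normal noise with the configured uniqueness variances; a monotone marginal
#' distortion and additive per-study assay offsets are then applied to the
#' raw scale, and cells are deleted completely at random.
#'
#' @param genotypes output of [simulateGenotypes()].
#' @param config a [simConfig()] object.
#' @param sex optional 0/1 vector; drawn Bernoulli(0.5) when NULL.
#' @return A [CsfCohort-class] with the generating truth in `metadata()$truth`
#'   (including the true PC scores and latent index).
#' @export
simulatePhenotypes <- function(genotypes, config, sex = NULL) {
    G <- genotypes$dosages
    n <- nrow(G)
    L <- config$loadingMatrix
    if (is.null(sex)) sex <- rbinom(n, 1L, 0.5)
    scores <- matrix(rnorm(n * 5L), n, 5L, dimnames = list(NULL, colnames(L)))
    if (!is.null(config$snpEffects)) {
        for (i in seq_len(nrow(config$snpEffects))) {
            e <- config$snpEffects[i, ]
            if (e$snp > ncol(G)) stop("snpEffects indexes a missing SNP")
            scores[, e$component] <- scores[, e$component] +
                e$beta * G[, e$snp] + e$betaFemale * G[, e$snp] * sex
        }
    }
    scores <- scores + outer(sex, config$sexShifts)

    eps <- matrix(rnorm(n * 6L), n, 6L)
    bm <- scores %*% t(L) + eps %*% diag(sqrt(config$uniqueness))
    colnames(bm) <- rownames(L)
    if (config$distortion) bm <- .distort(bm)
    study <- factor(paste0("study", 1L + (seq_len(n) %% config$nStudies)))
    bm <- bm + (as.integer(study) - 1L) * config$studyShift
    if (config$missingRate > 0) {
        del <- matrix(runif(n * 6L) < config$missingRate, n, 6L)
        bm[del] <- NA_real_
    }

    age <- rnorm(n, mean = 72, sd = 6)
    ancestry <- matrix(rnorm(n * 5L), n, 5L,
                       dimnames = list(NULL, paste0("ancestry", 1:5)))
    diag <- simulateDiagnosis(scores, config$diagCoeffs, config$diagThresholds)

    cd <- S4Vectors::DataFrame(
        sex = sex, age = age, study = study,
        diagnosis = factor(diag, .DIAG_LEVELS, ordered = TRUE))
    for (j in 1:5) cd[[paste0("ancestry", j)]] <- ancestry[, j]
    cd$biomarkers <- bm

    info <- genotypes$info
    gr <- GenomicRanges::GRanges(
        info$chrom, IRanges::IRanges(info$pos, width = 1L))
    names(gr) <- info$snp
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = info$ref, alt = info$alt, eaf = info$eaf,
        impQuality = info$impQuality)
    samples <- sprintf("sample%04d", seq_len(n))
    rownames(cd) <- samples
    ds <- t(G)
    dimnames(ds) <- list(info$snp, samples)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(DS = ds), rowRanges = gr, colData = cd)
    truth <- config
    truth$scores <- scores
    truth$latent <- attr(diag, "latent")
    obj <- methods::new("CsfCohort", se)
    S4Vectors::metadata(obj)$truth <- truth
    obj
}

#' Simulate a complete two-study cohort
#'
#' Convenience wrapper: seeds the generator, draws sex, genotypes
#' ([simulateGenotypes()]) and phenotypes/diagnosis ([simulatePhenotypes()]).
#'
#' @param config a [simConfig()] object.
#' @return A [CsfCohort-class].
#' @export
simulateCohort <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    sex <- rbinom(config$nSamples, 1L, 0.5)
    geno <- simulateGenotypes(config$nSamples, config$nSnps, config$mafRange,
                              xFraction = config$xFraction, sex = sex)
    simulatePhenotypes(geno, config, sex = sex)
}
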