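test_that("HWE chi-square matches hand-computed worked examples", {
    expect_equal(hweTest(25, 50, 25), 1)
    # (50, 0, 50): expected (25, 50, 25), chi2 = 100
    expect_equal(hweTest(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
    expect_lt(hweTest(50, 0, 50), 5e-6)
    expect_equal(hweTest(0, 0, 100), 1)
    expect_equal(hweTest(c(25, 0), c(50, 0), c(25, 100)), c(1, 1))
    expect_error(hweTest(0, 0, 0), "positive")
})

test_that("QC filtering applies each criterion with correct boundaries", {
    # hand-built cohort: 5 SNPs, one violation each of MAF / R2 / HWE, two clean
    set.seed(131)
    n <- 400
    study <- factor(rep(c("study1", "study2"), each = n / 2))
    G <- cbind(
        clean1 = rbinom(n, 2, 0.3),
        lowmaf = c(rbinom(n / 2, 2, 0.005), rbinom(n / 2, 2, 0.05)),
        lowr2 = rbinom(n, 2, 0.3),
        hwefail = rep(c(0, 2), n / 2),
        clean2 = rbinom(n, 2, 0.4))
    info <- S4Vectors::DataFrame(ref = "A", alt = "G",
                                 eaf = colMeans(G) / 2,
                                 impQuality = c(0.9, 0.9, 0.30, 0.9, 0.9))
    gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:5 * 100, width = 1))
    names(gr) <- colnames(G)
    S4Vectors::mcols(gr) <- info
    cd <- S4Vectors::DataFrame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 70),
                               study = study,
                               diagnosis = factor(rep("MCI", n),
                                                  c("control", "MCI", "AD")))
    cd$biomarkers <- matrix(rnorm(n * 6), n, 6)
    rownames(cd) <- paste0("s", 1:n)
    ds <- t(G); colnames(ds) <- rownames(cd)
    ch <- new("CsfCohort", SummarizedExperiment::SummarizedExperiment(
        assays = list(DS = ds), rowRanges = gr, colData = cd))
    qc <- qcFilter(ch)
    expect_setequal(qc$keep, c("clean1", "clean2"))
    # boundary: imputation quality exactly 0.30 fails the strict filter
    expect_false("lowr2" %in% qc$keep)
    # MAF must clear the bar in every study
    expect_false("lowmaf" %in% qc$keep)
    # idempotence on the surviving subset
    ch2 <- ch[qc$pass, ]
    qc2 <- qcFilter(ch2)
    expect_identical(sort(qc2$keep), sort(qc$keep))
})

test_that("association estimates equal the normal-equations oracle exactly", {
    set.seed(137)
    n <- 18
    G <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    sex <- rbinom(n, 1, 0.5)
    covs <- data.frame(age = rnorm(n, 70, 5), anc = rnorm(n))
    y <- rnorm(n)
    oracle <- function(X, y) {
        XtXi <- solve(t(X) %*% X)
        b <- XtXi %*% t(X) %*% y
        res <- y - X %*% b
        s2 <- sum(res^2) / (n - ncol(X))
        list(b = as.numeric(b), se = unname(sqrt(s2 * diag(XtXi))))
    }
    r <- runGwas(G, y, covs, model = "main", sex = sex)
    for (j in 1:5) {
        X <- cbind(1, G[, j], covs$age, covs$anc, sex)
        o <- oracle(X, y)
        expect_equal(r$beta[j], o$b[2], tolerance = 1e-8)
        expect_equal(r$se[j], o$se[2], tolerance = 1e-8)
    }
    ri <- runGwas(G, y, covs, model = "interaction", sex = sex)
    for (j in 1:5) {
        X <- cbind(1, covs$age, covs$anc, sex, G[, j], G[, j] * sex)
        o <- oracle(X, y)
        expect_equal(ri$beta[j], o$b[6], tolerance = 1e-8)
        expect_equal(ri$se[j], o$se[6], tolerance = 1e-8)
    }
    rm <- runGwas(G, y, covs, model = "male", sex = sex)
    idx <- sex == 0
    X <- cbind(1, G[idx, 1], covs$age[idx], covs$anc[idx])
    o <- oracle(X, y[idx])
    expect_equal(rm$beta[1], o$b[2], tolerance = 1e-8)
})

test_that("noise-free designs return exact coefficients", {
    g <- c(0, 1, 2, 1, 0)
    r <- runGwas(matrix(g, ncol = 1), 0.1 + 0.5 * g)
    expect_equal(r$beta, 0.5, tolerance = 1e-10)
    expect_lt(r$se, 1e-7)
    # balanced two-sex toy: interaction = female minus male slope
    sex <- rep(c(0, 1), each = 10)
    g2 <- rep(c(0, 1, 2, 0, 1), 4)
    y2 <- 0.2 * g2 * (sex == 0) + 0.5 * g2 * (sex == 1)
    ri <- runGwas(matrix(g2, ncol = 1), y2, model = "interaction", sex = sex)
    expect_equal(ri$beta, 0.3, tolerance = 1e-10)
})

test_that("stratified and interaction estimates obey beta_int = beta_F - beta_M", {
    set.seed(139)
    n <- 300
    g <- rbinom(n, 2, 0.3)
    sex <- rbinom(n, 1, 0.5)
    y <- 0.1 * g + 0.25 * g * sex + rnorm(n)
    G <- matrix(g, ncol = 1, dimnames = list(NULL, "s1"))
    bM <- runGwas(G, y, model = "male", sex = sex)$beta
    bF <- runGwas(G, y, model = "female", sex = sex)$beta
    bI <- runGwas(G, y, model = "interaction", sex = sex)$beta
    expect_equal(bI, bF - bM, tolerance = 1e-10)
})

test_that("planted effect recovery matches the closed-form sampling variance", {
    set.seed(149)
    est <- replicate(60, {
        g <- simulateGenotypes(973, 1, c(0.3, 0.3))$dosages
        y <- -0.5 * g + rnorm(973, sd = sqrt(0.895))
        r <- runGwas(g, y)
        c(r$beta, r$se)
    })
    expect_lt(abs(mean(est[1, ]) + 0.5), 0.02)
    # sqrt(sigma2 / (n * 2pq)) = 0.047
    expect_lt(abs(mean(est[2, ]) - sqrt(0.895 / (973 * 2 * 0.3 * 0.7))),
              0.003)
})

test_that("collinear SNPs are dropped and logged, not reported", {
    set.seed(151)
    n <- 40
    sex <- rep(c(0, 1), each = n / 2)
    G <- cbind(poly = rbinom(n, 2, 0.4),
               monoInMales = c(rep(0, n / 2), rbinom(n / 2, 2, 0.3)))
    y <- rnorm(n)
    r <- runGwas(G, y, model = "male", sex = sex)
    expect_false("monoInMales" %in% r$snp)
    expect_true("monoInMales" %in% attr(r, "failures")$snp)
    ri <- runGwas(G, y, model = "interaction", sex = sex)
    expect_false("monoInMales" %in% ri$snp)
})

test_that("genomic lambda behaves as a median chi-square ratio", {
    expect_warning(l1 <- genomicLambda(rep(0.5, 50)), "unstable")
    expect_equal(l1, 1)
    set.seed(157)
    p <- runif(1e5)
    expect_equal(genomicLambda(p), 1, tolerance = 0.02)
    expect_gt(genomicLambda(p / 2), genomicLambda(p))
})

test_that("null GWAS is calibrated: uniform p, lambda near 1, 5% type I error", {
    set.seed(163)
    G <- simulateGenotypes(500, 5000, c(0.05, 0.5))$dosages
    y <- rnorm(500)
    r <- runGwas(G, y)
    expect_gt(stats::ks.test(r$p, "punif")$p.value, 0.01)
    lam <- genomicLambda(r$p)
    expect_gt(lam, 0.95); expect_lt(lam, 1.05)
    expect_lt(abs(mean(r$p < 0.05) - 0.05), 0.01)
})

test_that("delta R2 matches its variance-partition oracle", {
    set.seed(167)
    n <- 4000
    g <- rbinom(n, 2, 0.15)
    y0 <- rnorm(n)
    expect_lt(deltaR2(g, y0), 0.003)
    # no covariates: identical to the squared Pearson correlation
    y1 <- 0.2 * g + rnorm(n)
    expect_equal(deltaR2(g, y1), cor(g, y1)^2, tolerance = 1e-10)
    # planted beta = -0.31 at MAF 0.15 on unit-variance outcome:
    # delta R2 ~ 2 beta^2 p (1 - p)
    b <- -0.31; pq <- 0.15 * 0.85
    y2 <- b * g + rnorm(n, sd = sqrt(1 - 2 * b^2 * pq))
    expect_lt(abs(deltaR2(g, y2) - 2 * b^2 * pq), 0.005)
})

test_that("greedy clumping matches the exhaustive-search oracle", {
    # trivial rules first
    ld2 <- matrix(c(1, 0.9, 0.9, 1), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
    hits <- selectIndependentHits(
        data.frame(snp = c("a", "b"), p = c(1e-10, 1e-9)), ld2)
    expect_identical(hits$snp, "a")
    ld0 <- diag(3); dimnames(ld0) <- list(letters[1:3], letters[1:3])
    all3 <- selectIndependentHits(
        data.frame(snp = letters[1:3], p = c(1e-9, 1e-10, 1e-12)), ld0)
    expect_setequal(all3$snp, letters[1:3])
    # chained-LD fixture against brute force
    snps <- c("A", "B", "C", "D")
    ld <- matrix(c(1, 0.7, 0.1, 0.2,
                   0.7, 1, 0.7, 0.9,
                   0.1, 0.7, 1, 0.05,
                   0.2, 0.9, 0.05, 1), 4, byrow = TRUE,
                 dimnames = list(snps, snps))
    assoc <- data.frame(snp = snps, p = c(1e-12, 1e-11, 1e-10, 1e-9))
    got <- selectIndependentHits(assoc, ld)
    expect_identical(sort(got$snp), clumpOracle(assoc, ld))
    # missing LD entries are tolerated with a warning
    expect_warning(
        selectIndependentHits(assoc, ld[1:3, 1:3]), "missing LD")
})
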