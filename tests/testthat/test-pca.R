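test_that("imputation is a no-op on complete data and completes rank-1 exactly", {
    x <- matrix(rnorm(40), 10, 4)
    expect_identical(imputeIterativePCA(x, 2), x)

    u <- c(1, 2, 3, 4, 5, 6, 7, 8)
    v <- c(2, -1, 0.5, 1)
    x1 <- outer(u, v)
    x1[3, 2] <- NA
    out <- imputeIterativePCA(x1, 1, regularization = 0, scale = FALSE,
                              tol = 1e-10)
    expect_equal(out[3, 2], u[3] * v[2], tolerance = 1e-6)
    expect_identical(out[-3, ], outer(u, v)[-3, ])
})

test_that("imputation errors are informative", {
    x <- matrix(rnorm(40), 10, 4)
    x[, 2] <- NA
    colnames(x) <- letters[1:4]
    expect_error(imputeIterativePCA(x, 2), "b")
    expect_error(imputeIterativePCA(matrix(rnorm(20), 5, 4), 4), "smaller")
    x2 <- matrix(rnorm(40), 10, 4); x2[1, 1] <- NA
    expect_error(imputeIterativePCA(x2, 2, maxIter = 0), "converge")
})

test_that("structured imputation beats column-mean filling", {
    ch <- structuredCohort(n = 600, seed = 41)
    z <- transformedPanel(ch)
    zFull <- transformPanel(
        biomarkers(simulateCohort(simConfig(nSamples = 600, nSnps = 5,
                                            missingRate = 0, seed = 41))),
        sampleData(ch)$study)
    miss <- is.na(z)
    imp <- imputeIterativePCA(z, 5)
    mu <- colMeans(z, na.rm = TRUE)
    meanImp <- z
    for (j in 1:6) meanImp[miss[, j], j] <- mu[j]
    # the reference values come from the same underlying draw without deletion,
    # ranked on slightly different sample sets; compare on imputed cells only
    rmse <- function(a) sqrt(mean((a[miss] - zFull[miss])^2))
    expect_lt(rmse(imp), rmse(meanImp))
})

test_that("cell-wise cross-validation recovers a planted rank", {
    # full leave-one-observation-out sweep: the candidate ranks above the
    # truth are separated only by the regularization penalty, which cell
    # subsampling would drown
    L2 <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
    hits <- 0L
    for (s in 1:10) {
        x <- factorPanel(100, L2, rep(0.01, 6), seed = 50 + s)
        sel <- selectNComponents(x, kMax = 3, tol = 1e-3)
        hits <- hits + (sel$k == 2L)
    }
    expect_gte(hits, 9L)
})

test_that("cross-validation does not overfit white noise", {
    set.seed(61)
    x <- matrix(rnorm(120 * 6), 120, 6)
    sel <- selectNComponents(x, kMax = 4, tol = 1e-3)
    expect_lte(sel$k, 1L)
    # error curve grows past the optimum
    expect_gt(sel$cv$msep[5], sel$cv$msep[sel$k + 1])
    expect_error(selectNComponents(x, kMax = 6), "kMax")
})

test_that("varimax finds perfect simple structure in a two-block panel", {
    # two equally strong blocks: the pre-rotation basis is an arbitrary
    # mixture (equal eigenvalues) and the identity start sits on a saddle;
    # the pairwise-rotation solver must still reach simple structure
    set.seed(71)
    z1 <- rnorm(300)
    z2 <- residuals(lm(rnorm(300) ~ z1))   # exactly uncorrelated in-sample
    x <- cbind(z1, z1, z1, z2, z2, z2)
    m <- fitVarimaxPCA(x, 2)
    L <- abs(loadings(m))
    blockOf <- apply(L, 1, which.max)
    expect_true(all(blockOf == rep(blockOf[c(1, 4)], each = 3)))
    expect_true(all(L[cbind(1:6, blockOf)] > 0.99))
    expect_true(all(L[cbind(1:6, 3 - blockOf)] < 0.05))
})

test_that("the rotation agrees with the reference varimax implementation", {
    # independent cross-check on a non-degenerate panel
    x <- factorPanel(1000, defaultLoadingMatrix(), defaultUniqueness(),
                     seed = 401)
    R <- cor(x)
    e <- eigen(R, symmetric = TRUE)
    A <- e$vectors[, 1:5] %*% diag(sqrt(e$values[1:5]))
    ref <- A %*% stats::varimax(A, normalize = TRUE, eps = 1e-10)$rotmat
    m <- fitVarimaxPCA(x, 5)
    cg <- abs(tuckerCongruence(ref, loadings(m)))
    expect_true(all(apply(cg, 1, max) > 0.999))
})

test_that("varimax of an already simple loading pattern is a fixed point", {
    L <- defaultLoadingMatrix()
    x <- factorPanel(800, L, defaultUniqueness(), seed = 73)
    m1 <- fitVarimaxPCA(scale(x), 5)
    m2 <- fitVarimaxPCA(m1@imputed, 5)
    expect_equal(loadings(m1), loadings(m2), tolerance = 1e-10)
    cg <- tuckerCongruence(loadings(m1), loadings(m2))
    expect_true(all(abs(diag(cg)) > 0.9999))
})

test_that("rotated components stay orthogonal and respect anchor alignment", {
    ch <- structuredCohort(n = 800, seed = 79)
    z <- transformedPanel(ch)
    m <- fitVarimaxPCA(imputeIterativePCA(z, 5), 5)
    rot <- m@rotation$rotmat
    expect_equal(crossprod(rot), diag(5), tolerance = 1e-8)
    expect_true(sum(varianceExplained(m)) <= 1)
    # anchors load positively on their own component
    L <- loadings(m)
    expect_gt(L["tau", "PC1"], 0)
    expect_gt(L["Abeta", "PC2"], 0)
    expect_gt(L["NfL", "PC3"], 0)
    expect_gt(L["YKL40", "PC4"], 0)
    expect_gt(L["Ng", "PC5"], 0)
    v <- rnorm(100)
    expect_error(fitVarimaxPCA(matrix(v, 100, 6), 5), "rank deficient")
})

test_that("regression scores are standardized, near-orthogonal and frozen", {
    ch <- structuredCohort(n = 1000, seed = 83)
    z <- transformedPanel(ch)
    m <- fitVarimaxPCA(imputeIterativePCA(z, 5), 5)
    sc <- computeScores(m)
    expect_equal(unname(colMeans(sc)), rep(0, 5), tolerance = 1e-10)
    expect_equal(unname(apply(sc, 2, sd)), rep(1, 5), tolerance = 0.1)
    offdiag <- cor(sc)[upper.tri(diag(5))]
    expect_lt(max(abs(offdiag)), 0.1)
    # frozen contract: same input, same output; new data needs no refit
    expect_identical(computeScores(m), sc)
    newx <- imputeIterativePCA(transformedPanel(
        structuredCohort(n = 200, seed = 89)), 5)
    s1 <- computeScores(m, newx)
    s2 <- computeScores(m, newx)
    expect_identical(s1, s2)
    expect_identical(loadings(m), loadings(m))
    # marker-name mismatch is refused
    bad <- newx; colnames(bad) <- letters[1:6]
    expect_error(computeScores(m, bad), "marker names")
})

test_that("scores reduce to standardized markers under identity structure", {
    set.seed(97)
    x <- matrix(rnorm(500 * 3), 500, 3)
    m <- fitVarimaxPCA(x, 3)
    sc <- computeScores(m)
    z <- scale(x)
    match <- apply(abs(cor(sc, z)), 1, max)
    expect_true(all(match > 0.95))
})

test_that("impute-then-fit is equivariant under sample permutation", {
    ch <- structuredCohort(n = 300, seed = 101)
    z <- transformedPanel(ch)
    perm <- sample(nrow(z))
    a <- imputeIterativePCA(z, 5)
    b <- imputeIterativePCA(z[perm, ], 5)
    expect_equal(a[perm, ], b, tolerance = 1e-8)
    expect_equal(loadings(fitVarimaxPCA(a, 5)),
                 loadings(fitVarimaxPCA(b, 5)), tolerance = 1e-6)
})

test_that("group comparison flags only real loading differences", {
    ch <- structuredCohort(n = 500, seed = 103)
    bm <- biomarkers(ch)
    dup <- rbind(bm, bm)
    g <- rep(c("m", "f"), each = nrow(bm))
    st <- rep(sampleData(ch)$study, 2)
    cmp <- compareGroupLoadings(dup, g, k = 5, study = st)
    expect_lt(max(abs(cmp$difference)), 1e-8)
    expect_true(all(cmp$indifferent))
    expect_error(compareGroupLoadings(bm[1:10, ], rep(c("a", "b"), 5), k = 5),
                 "at least 6")
})

test_that("a planted NfL loading difference between sexes is recovered", {
    # varimax partially reabsorbs a planted cross-loading contrast, so the
    # expected *fitted* difference is computed from the same pipeline at
    # large n (the population mapping), not assumed equal to the planted
    # factor-loading difference
    Lf <- defaultLoadingMatrix(); Lf["NfL", "PC1"] <- 0.25
    Lm <- defaultLoadingMatrix(); Lm["NfL", "PC1"] <- 0.19
    pop <- function(L) {
        x <- factorPanel(60000, L, defaultUniqueness(), seed = 7)
        loadings(fitVarimaxPCA(scale(x), 5))["NfL", "PC1"]
    }
    oracle <- pop(Lm) - pop(Lf)
    expect_lt(oracle, -0.015)   # the contrast survives rotation
    ds <- vapply(1:6, function(i) {
        xf <- factorPanel(557, Lf, defaultUniqueness(), seed = 200 + i)
        xm <- factorPanel(601, Lm, defaultUniqueness(), seed = 300 + i)
        x <- rbind(xm, xf)
        g <- rep(c("male", "female"), c(601, 557))
        cmp <- compareGroupLoadings(x, g, k = 5)
        cmp$models$male@loadings["NfL", "PC1"] -
            cmp$models$female@loadings["NfL", "PC1"]
    }, 0)
    expect_lt(abs(mean(ds) - oracle), 0.03)
})

test_that("random half-splits of a homogeneous panel look indifferent", {
    # at ~550 per half the null max loading difference routinely reaches
    # 0.05-0.08 from rotation noise alone; the indifference bound is a
    # large-sample statement, tested at 3000 per half
    ok <- 0L
    for (s in 1:10) {
        x <- factorPanel(6000, defaultLoadingMatrix(), defaultUniqueness(),
                         seed = 120 + s)
        g <- rep(c("h1", "h2"), length.out = nrow(x))
        cmp <- compareGroupLoadings(x, g, k = 5)
        ok <- ok + (max(abs(cmp$difference)) < 0.04)
    }
    expect_gte(ok, 8L)
})

test_that("variance explained of the canonical structure sums to ~0.99", {
    ch <- structuredCohort(n = 1158, seed = 113)
    z <- transformedPanel(ch)
    m <- fitVarimaxPCA(imputeIterativePCA(z, 5), 5)
    expect_lt(abs(sum(varianceExplained(m)) - 0.99), 0.05)
})
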