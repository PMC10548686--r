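# Component construction: regularized iterative-PCA imputation, cell-wise
# cross-validation for the component count, varimax-rotated PCA, and frozen
# regression scores.

# One sweep of the regularized rank-k fit: returns the fitted matrix on the
# original scale. `reg` scales the noise-variance shrinkage (0 = plain
# iterative PCA, 1 = full regularization).
.rankKFit <- function(Xc, k, reg, scale) {
    n <- nrow(Xc); p <- ncol(Xc)
    mu <- colMeans(Xc)
    sds <- if (scale) apply(Xc, 2L, sd) else rep(1, p)
    sds[sds < 1e-12] <- 1e-12
    Z <- sweep(sweep(Xc, 2L, mu), 2L, sds, "/")
    if (k == 0L)
        return(sweep(sweep(matrix(0, n, p), 2L, sds, "*"), 2L, mu, "+"))
    S <- crossprod(Z) / (n - 1)
    e <- eigen(S, symmetric = TRUE)
    lambda <- pmax(e$values, 0)
    sigma2 <- if (k < p) reg * mean(lambda[(k + 1L):p]) else 0
    f <- pmax(lambda[seq_len(k)] - sigma2, 0) / pmax(lambda[seq_len(k)], 1e-12)
    V <- e$vectors[, seq_len(k), drop = FALSE]
    Zhat <- (Z %*% V) %*% (t(V) * f)
    sweep(sweep(Zhat, 2L, sds, "*"), 2L, mu, "+")
}

.iterativePCA <- function(x, k, reg, tol, maxIter, scale, init = NULL) {
    miss <- is.na(x)
    Xc <- x
    if (is.null(init)) {
        mu <- colMeans(x, na.rm = TRUE)
        for (j in seq_len(ncol(x))) Xc[miss[, j], j] <- mu[j]
    } else {
        Xc[miss] <- init[miss]
    }
    delta <- Inf
    for (it in seq_len(maxIter)) {
        Xhat <- .rankKFit(Xc, k, reg, scale)
        delta <- max(abs(Xhat[miss] - Xc[miss]))
        Xc[miss] <- Xhat[miss]
        if (delta < tol) return(Xc)
    }
    stop(sprintf(
        "iterative PCA did not converge in %d iterations (last delta %.3g)",
        maxIter, delta))
}

#' Impute missing biomarker cells by regularized iterative PCA
#'
#' EM-style matrix completion: alternate a rank-`k` truncated PCA fit (with
#' each retained eigenvalue shrunk toward the mean residual eigenvalue, which
#' damps overfitting of the refilled cells) and refilling of the missing
#' cells, until the largest absolute change on an imputed cell falls below
#' `tol`. Observed cells are returned unchanged.
#'
#' @param x numeric matrix with NAs.
#' @param k number of components.
#' @param regularization multiplier on the noise-variance shrinkage; 1 is the
#'   regularized algorithm, 0 plain iterative PCA.
#' @param tol,maxIter convergence control.
#' @param scale standardize columns inside the fit (the default; the panel is
#'   usually already inverse-normal transformed, where this is near a no-op).
#' @return completed matrix of the same shape.
#' @export
imputeIterativePCA <- function(x, k, regularization = 1, tol = 1e-6,
                               maxIter = 1000L, scale = TRUE) {
    x <- as.matrix(x)
    if (k >= ncol(x)) stop("k must be smaller than the number of markers")
    if (!anyNA(x)) return(x)
    allMiss <- colSums(!is.na(x)) == 0L
    if (any(allMiss))
        stop("column(s) entirely missing: ",
             paste(colnames(x)[allMiss], collapse = ", "))
    .iterativePCA(x, k, regularization, tol, maxIter, scale)
}

#' Choose the component count by cell-wise cross-validation
#'
#' For each candidate `k`, every observed cell is in turn deleted and
#' predicted by the regularized iterative-PCA model fitted to the remaining
#' data; the `k` with the smallest mean squared error of prediction wins.
#' Deleting individual matrix cells (not whole rows) is what makes held-out
#' prediction well defined for a matrix-completion model. The per-cell refits
#' are warm-started from the full-data completion, so each one converges in a
#' few sweeps.
#'
#' @param x biomarker matrix (NAs allowed; only observed cells are held out).
#' @param kMax largest component count tried; must be below the number of
#'   markers.
#' @param kMin smallest count tried (0 = column-mean prediction).
#' @param maxCells optionally subsample this many held-out cells (with
#'   `seed`) to bound runtime; default uses every observed cell (leave one
#'   observation out).
#' @param regularization,tol,maxIter,scale passed to the imputation engine
#'   (`tol` is coarser here than in [imputeIterativePCA()]; prediction error
#'   is insensitive below it).
#' @param seed used only when subsampling cells.
#' @return list with `k` (the argmin) and `cv`, the k-by-MSEP error curve.
#' @export
selectNComponents <- function(x, kMax, kMin = 0L, maxCells = Inf,
                              regularization = 1, tol = 1e-4, maxIter = 200L,
                              scale = TRUE, seed = NULL) {
    x <- as.matrix(x)
    p <- ncol(x)
    if (kMax >= p)
        stop("kMax must be smaller than the number of markers")
    obs <- which(!is.na(x), arr.ind = TRUE)
    if (nrow(obs) > maxCells) {
        if (!is.null(seed)) set.seed(seed)
        obs <- obs[sample.int(nrow(obs), maxCells), , drop = FALSE]
    }
    ks <- seq.int(kMin, kMax)
    msep <- numeric(length(ks))
    for (ki in seq_along(ks)) {
        k <- ks[ki]
        full <- if (anyNA(x))
            .iterativePCA(x, k, regularization, tol, maxIter, scale)
        else x
        err <- numeric(nrow(obs))
        missBase <- is.na(x)
        for (c in seq_len(nrow(obs))) {
            i <- obs[c, 1L]; j <- obs[c, 2L]
            xho <- x[i, j]
            Xw <- full
            missO <- missBase
            missO[i, j] <- FALSE      # the other (original) missing cells
            # column mean of the *other* observed values: no leakage
            c0 <- (sum(x[, j], na.rm = TRUE) - xho) /
                (sum(!is.na(x[, j])) - 1L)
            # one EM sweep viewed as a scalar map of the held-out cell
            # (the warm-started original missing cells are re-swept too);
            # Steffensen extrapolation jumps to its fixed point, which the
            # plain iteration approaches only at the slow linear rate set by
            # the panel's high communalities
            g <- function(cc) {
                Xw[i, j] <<- cc
                Xhat <- .rankKFit(Xw, k, regularization, scale)
                Xw[missO] <<- Xhat[missO]
                Xhat[i, j]
            }
            lim <- 10 * max(1, abs(range(x, na.rm = TRUE)))
            for (it in seq_len(maxIter)) {
                c1 <- g(c0); c2 <- g(c1)
                den <- c2 - 2 * c1 + c0
                cn <- if (abs(den) > 1e-12) c0 - (c1 - c0)^2 / den else c2
                # extrapolation must stay in a sane bracket, otherwise trust
                # the plain EM step
                if (!is.finite(cn) || abs(cn) > lim) cn <- c2
                if (abs(cn - c0) < tol) { c0 <- cn; break }
                c0 <- cn
            }
            err[c] <- (c0 - xho)^2
        }
        msep[ki] <- mean(err)
    }
    list(k = ks[which.min(msep)], cv = data.frame(k = ks, msep = msep))
}

# Cyclic pairwise planar rotations maximizing the varimax criterion on
# Kaiser-normalized rows. The per-pair angle is maximized in closed form
# (atan2 of the criterion's fourth-order moments), which steps cleanly off
# the rotation-indeterminate saddle that equal-strength components create —
# a case where SVD-based varimax updates stall on a zero gradient.
.pairwiseVarimax <- function(A, tol = 1e-12, maxit = 500L) {
    p <- nrow(A); k <- ncol(A)
    h <- sqrt(rowSums(A^2))
    h[h < 1e-12] <- 1e-12
    Z <- A / h
    rot <- diag(k)
    iter <- 0L
    for (it in seq_len(maxit)) {
        iter <- it
        tot <- 0
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            a <- Z[, i]; b <- Z[, j]
            u <- a^2 - b^2; v <- 2 * a * b
            num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
            den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
            phi <- atan2(num, den) / 4
            if (abs(phi) < 1e-14) next
            G <- diag(k)
            G[i, i] <- G[j, j] <- cos(phi)
            G[i, j] <- -sin(phi); G[j, i] <- sin(phi)
            Z <- Z %*% G
            rot <- rot %*% G
            tot <- tot + abs(phi)
        }
        if (tot < tol) break
    }
    list(rotmat = rot, loadings = Z * h, iterations = iter)
}

.DEFAULT_ANCHORS <- c(PC1 = "tau", PC2 = "Abeta", PC3 = "NfL",
                      PC4 = "YKL40", PC5 = "Ng")

# reorder/sign-flip rotated components: each canonical component claims the
# unassigned column loading strongest (in absolute value) on its anchor
# marker, and is flipped so the anchor loads positively
.alignComponents <- function(L, anchors) {
    k <- ncol(L)
    ord <- integer(k); sgn <- rep(1, k)
    free <- rep(TRUE, k)
    for (j in seq_len(k)) {
        a <- anchors[j]
        cand <- which(free)
        pick <- cand[which.max(abs(L[a, cand]))]
        ord[j] <- pick
        sgn[j] <- if (L[a, pick] < 0) -1 else 1
        free[pick] <- FALSE
    }
    list(order = ord, sign = sgn)
}

#' Fit a varimax-rotated PCA of the completed biomarker matrix
#'
#' Principal axes of the marker correlation matrix are extracted and rotated
#' with varimax (Kaiser-normalized rows, iterative pairwise planar rotations);
#' the returned loadings are structure coefficients, i.e. correlations between
#' markers and the rotated components. For the canonical six-marker panel with
#' `k = 5`, components are reordered and sign-aligned so tau, Abeta, NfL,
#' YKL-40 and neurogranin anchor PC1..PC5 with positive loadings; otherwise
#' components are ordered by variance explained with the dominant marker
#' loading positive.
#'
#' @param x complete numeric matrix (run [imputeIterativePCA()] first if
#'   needed).
#' @param k number of components to retain.
#' @param anchors optional named character vector mapping component labels to
#'   anchor markers.
#' @param scoreMethod default scoring method stored in the model.
#' @return A [PCModel-class].
#' @export
fitVarimaxPCA <- function(x, k, anchors = NULL, scoreMethod = "regression") {
    x <- as.matrix(x)
    if (anyNA(x)) stop("x must be complete; impute first")
    p <- ncol(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
    R <- cor(x)
    e <- eigen(R, symmetric = TRUE)
    if (sum(e$values > 1e-10) < k)
        stop("marker correlation matrix is rank deficient: cannot extract ",
             k, " components")
    A <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(e$values[seq_len(k)]), k)
    rownames(A) <- colnames(x)
    if (k > 1L) {
        vm <- .pairwiseVarimax(A)
        L <- vm$loadings
        rotation <- list(rotmat = vm$rotmat, kaiser = TRUE,
                         iterations = vm$iterations)
    } else {
        L <- A
        rotation <- list(rotmat = diag(1), kaiser = TRUE, iterations = 0L)
    }
    if (is.null(anchors) && k == 5L && all(.MARKERS %in% colnames(x)))
        anchors <- .DEFAULT_ANCHORS
    if (!is.null(anchors)) {
        al <- .alignComponents(L, anchors[seq_len(k)])
        cn <- names(anchors)[seq_len(k)]
    } else {
        ve0 <- colSums(L^2)
        ord <- order(ve0, decreasing = TRUE)
        sgn <- vapply(ord, function(c) {
            m <- which.max(abs(L[, c])); if (L[m, c] < 0) -1 else 1
        }, 0)
        al <- list(order = ord, sign = sgn)
        cn <- paste0("PC", seq_len(k))
    }
    L <- L[, al$order, drop = FALSE] %*% diag(al$sign, k)
    colnames(L) <- cn
    rotation$order <- al$order; rotation$sign <- al$sign
    methods::new("PCModel",
        loadings = L,
        varianceExplained = colSums(L^2) / p,
        k = as.integer(k),
        rotation = rotation,
        center = colMeans(x),
        scale = apply(x, 2L, sd),
        corMatrix = R,
        imputed = x,
        scoreMethod = scoreMethod,
        markerNames = colnames(x),
        componentNames = cn)
}

#' Compute component scores from a fitted model
#'
#' Regression scores: weights `W = solve(R) %*% L` (inverse marker correlation
#' times rotated loadings), applied to the column-standardized data, then
#' rescaled so each score column has theoretical SD 1 under the training
#' correlation matrix. The model is frozen — applying it to a new sample uses
#' the stored weights, never a refit. Bartlett-style weights are available via
#' `method = "bartlett"`.
#'
#' @param model a [PCModel-class].
#' @param x data matrix with the model's markers as columns; defaults to the
#'   matrix the model was fitted on.
#' @param method "regression" or "bartlett".
#' @return n x k score matrix in SD units.
#' @export
computeScores <- function(model, x = NULL,
                          method = c("regression", "bartlett")) {
    method <- match.arg(method, c("regression", "bartlett"),
                        several.ok = FALSE)
    if (is.null(x)) x <- model@imputed
    x <- as.matrix(x)
    if (!is.null(colnames(x)) && !identical(colnames(x), model@markerNames)) {
        if (!all(model@markerNames %in% colnames(x)))
            stop("marker names of x do not match the fitted model")
        x <- x[, model@markerNames, drop = FALSE]
    }
    R <- model@corMatrix
    L <- model@loadings
    W <- if (method == "regression") solve(R, L)
    else solve(R, L) %*% solve(t(L) %*% solve(R, L))
    z <- scale(x)
    sc <- z %*% W
    thsd <- sqrt(diag(t(W) %*% R %*% W))
    sc <- sweep(sc, 2L, thsd, "/")
    colnames(sc) <- model@componentNames
    sc
}

#' Tucker congruence coefficients between two loading matrices
#'
#' Column-wise cosine similarity; values near 1 (in absolute value) indicate
#' the same component recovered in two fits.
#'
#' @param a,b loading matrices with matching rows.
#' @return k_a x k_b matrix of congruences.
#' @export
tuckerCongruence <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    cp <- crossprod(a, b)
    cp / outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
}

#' Compare component loadings between two groups
#'
#' Fits the transform-impute-rotate pipeline separately per group (e.g. males
#' and females), aligns the second group's components to the first by maximal
#' absolute Tucker congruence (with sign flips), and tabulates loading
#' differences; absolute differences below `indifferenceBound` are flagged
#' "indifferent".
#'
#' @param bm raw biomarker matrix (NAs allowed).
#' @param group two-level grouping (e.g. sex).
#' @param k component count.
#' @param study optional study labels for the within-study inverse normal
#'   transform (applied within group x study cells).
#' @param indifferenceBound classification bound for negligible differences.
#' @param ... passed to [imputeIterativePCA()].
#' @return list with per-group `models`, the aligned `difference` matrix
#'   (group1 - group2), logical `indifferent`, and per-component `congruence`.
#' @export
compareGroupLoadings <- function(bm, group, k = 5L, study = NULL,
                                 indifferenceBound = 0.04, ...) {
    group <- factor(group)
    if (nlevels(group) != 2L) stop("group must have exactly two levels")
    if (any(table(group) < 6L)) stop("each group needs at least 6 samples")
    fit1 <- function(g) {
        idx <- group == g
        st <- if (is.null(study)) NULL else study[idx]
        z <- transformPanel(bm[idx, , drop = FALSE], st)
        xc <- if (anyNA(z)) imputeIterativePCA(z, k, ...) else z
        fitVarimaxPCA(xc, k)
    }
    m1 <- fit1(levels(group)[1L])
    m2 <- fit1(levels(group)[2L])
    # align m2's columns to m1's by congruence (anchor alignment already
    # applied inside fitVarimaxPCA; this guards residual swaps)
    cg <- tuckerCongruence(m1@loadings, m2@loadings)
    ord <- integer(k); sgn <- rep(1, k); free <- rep(TRUE, k)
    for (j in seq_len(k)) {
        cand <- which(free)
        pick <- cand[which.max(abs(cg[j, cand]))]
        ord[j] <- pick
        sgn[j] <- sign(cg[j, pick])
        free[pick] <- FALSE
    }
    L2 <- m2@loadings[, ord, drop = FALSE] %*% diag(sgn, k)
    dimnames(L2) <- dimnames(m1@loadings)
    diffs <- m1@loadings - L2
    list(models = stats::setNames(list(m1, m2), levels(group)),
         difference = diffs,
         indifferent = abs(diffs) < indifferenceBound,
         congruence = vapply(seq_len(k),
                             function(j) abs(cg[j, ord[j]]), 0))
}
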