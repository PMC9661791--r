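# Isolation forest: anomaly scoring of window feature vectors.

# expected path length of an unsuccessful BST search among n points
.cPath <- function(n) {
    if (n <= 1L) return(0)
    if (n == 2L) return(1)
    2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

# run expr with a temporary RNG state seeded at `seed`
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# grow one isolation tree on X[rows, ]; flat table via closure accumulators
.growTree <- function(X, rows, maxDepth) {
    feature <- integer(0); split <- numeric(0)
    left <- integer(0); right <- integer(0)
    size <- integer(0); depth <- integer(0)
    newNode <- function() {
        feature[length(feature) + 1L] <<- NA_integer_
        split[length(split) + 1L] <<- NA_real_
        left[length(left) + 1L] <<- 0L
        right[length(right) + 1L] <<- 0L
        size[length(size) + 1L] <<- 0L
        depth[length(depth) + 1L] <<- 0L
        length(feature)
    }
    build <- function(rows, d) {
        id <- newNode()
        depth[id] <<- d
        size[id] <<- length(rows)
        if (length(rows) <= 1L || d >= maxDepth) return(id)
        # draw a split feature; skip features constant within this node
        f <- NA_integer_
        for (cand in sample.int(ncol(X))) {
            rng <- range(X[rows, cand])
            if (rng[2] > rng[1]) { f <- cand; break }
        }
        if (is.na(f)) return(id)
        s <- runif(1L, rng[1], rng[2])
        goLeft <- X[rows, f] < s
        if (!any(goLeft) || all(goLeft)) return(id)
        feature[id] <<- f
        split[id] <<- s
        lid <- build(rows[goLeft], d + 1L)
        rid <- build(rows[!goLeft], d + 1L)
        left[id] <<- lid
        right[id] <<- rid
        id
    }
    build(rows, 0L)
    list(feature = feature, split = split, left = left, right = right,
         size = size, depth = depth)
}

#' Fit an isolation forest
#'
#' Builds `nTrees` isolation trees, each on a uniform subsample of
#' `sampleSize` rows, with uniformly random axis-parallel splits, grown to
#' depth `ceiling(log2(sampleSize))`. Deterministic for a fixed seed.
#'
#' The default subsample is `min(n, 4096)`: a larger subsample than the
#' classic 256 sharpens the resolution of rare single-window anomalies and
#' raises the attainable score ceiling `2^(-1/c(sampleSize))`, which matters
#' when an absolute score threshold is applied downstream.
#'
#' @param X numeric matrix or data.frame of feature vectors (rows = points).
#' @param nTrees number of trees (default 100).
#' @param sampleSize subsample size per tree (default `min(nrow(X), 4096)`).
#' @param seed integer seed.
#' @return an [IsolationForest-class] object.
#' @export
isolationForest <- function(X, nTrees = 100L, sampleSize = NULL, seed = 1L) {
    X <- as.matrix(X)
    if (nrow(X) < 2L) stop("isolation forest needs at least 2 points")
    if (is.null(sampleSize)) sampleSize <- min(nrow(X), 4096L)
    sampleSize <- min(sampleSize, nrow(X))
    trees <- .withSeed(seed, lapply(seq_len(nTrees), function(i) {
        rows <- sample.int(nrow(X), sampleSize, replace = FALSE)
        .growTree(X, rows, maxDepth = ceiling(log2(sampleSize)))
    }))
    new("IsolationForest", trees = trees, sampleSize = as.integer(sampleSize),
        nTrees = as.integer(nTrees),
        manifest = colnames(X) %||% character(0), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anomaly scores from an isolation forest
#'
#' Returns the canonical isolation score `s = 2^(-E[h]/c(psi))` in (0, 1)
#' for each row of `X`; higher scores are more anomalous.
#'
#' @param forest an [IsolationForest-class] object.
#' @param X matrix/data.frame with the columns the forest was fitted on.
#' @return numeric vector of scores.
#' @export
isolationScore <- function(forest, X) {
    X <- as.matrix(X)
    if (length(forest@manifest) > 0 && !is.null(colnames(X))) {
        if (!all(forest@manifest %in% colnames(X)))
            stop("feature columns do not match the fitted manifest")
        X <- X[, forest@manifest, drop = FALSE]
    }
    n <- nrow(X)
    h <- numeric(n)
    for (tr in forest@trees) {
        # batch traversal: propagate point sets down the flat tree
        nodePts <- vector("list", length(tr$feature))
        nodePts[[1L]] <- seq_len(n)
        for (id in seq_along(tr$feature)) {
            pts <- nodePts[[id]]
            if (is.null(pts) || length(pts) == 0L) next
            f <- tr$feature[id]
            if (is.na(f)) { # leaf
                h[pts] <- h[pts] + tr$depth[id] + .cPath(tr$size[id])
                next
            }
            goLeft <- X[pts, f] < tr$split[id]
            lid <- tr$left[id]; rid <- tr$right[id]
            nodePts[[lid]] <- c(nodePts[[lid]], pts[goLeft])
            nodePts[[rid]] <- c(nodePts[[rid]], pts[!goLeft])
            nodePts[id] <- list(NULL)
        }
    }
    eh <- h / forest@nTrees
    2^(-eh / .cPath(forest@sampleSize))
}
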