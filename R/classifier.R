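# Misassembly classifier: down-sampled random-forest ensemble over
# contig-level features.

.checkManifest <- function(features, manifest) {
    miss <- setdiff(manifest, colnames(features))
    if (length(miss) > 0L)
        stop("feature table does not match the model manifest; missing: ",
             paste(head(miss, 5), collapse = ", "))
    as.matrix(features[, manifest, drop = FALSE])
}

#' Train the down-sampled random-forest ensemble
#'
#' Trains 10 sub-classifiers. Each uses all misassembled (positive) contigs
#' plus an equal-size subset of correctly assembled (negative) contigs drawn
#' without replacement (a fresh draw per sub-model), countering the strong
#' class imbalance of real assemblies. Every sub-model is a 1000-tree
#' probability forest. Deterministic for a fixed seed.
#'
#' Contigs shorter than the eligibility threshold (5000 bp, strict) should
#' be excluded before training; see [eligibleContigs()].
#'
#' @param features data.frame containing the manifest columns
#'   ([featureManifest()]).
#' @param labels logical (or 0/1) vector: TRUE = misassembled.
#' @param nTrees trees per sub-model (default 1000).
#' @param mtry features tried per split (default: ranger's sqrt rule).
#' @param nSub number of down-sampling rounds / sub-models (default 10).
#' @param seed integer seed.
#' @return an [EnsembleModel-class] object.
#' @export
trainEnsemble <- function(features, labels, nTrees = 1000L, mtry = NULL,
                          nSub = 10L, seed = 1L) {
    labels <- as.logical(labels)
    if (length(labels) != nrow(features))
        stop("labels must align with feature rows")
    if (anyNA(labels)) stop("labels must not contain NA")
    if (length(unique(labels)) < 2L)
        stop("both classes must be present to train the ensemble")
    X <- .checkManifest(features, featureManifest())
    pos <- which(labels)
    neg <- which(!labels)
    if (length(neg) < length(pos))
        warning("fewer negatives than positives: down-sampling degenerates ",
                "to the full negative set")
    forests <- .withSeed(seed, lapply(seq_len(nSub), function(i) {
        negSub <- if (length(neg) <= length(pos)) neg else
            sample(neg, length(pos), replace = FALSE)
        idx <- c(pos, negSub)
        df <- data.frame(X[idx, , drop = FALSE], check.names = FALSE)
        df$.label <- factor(ifelse(labels[idx], "misassembled", "clean"),
                            levels = c("clean", "misassembled"))
        ranger::ranger(
            dependent.variable.name = ".label", data = df,
            num.trees = nTrees, mtry = mtry, probability = TRUE,
            seed = seed * 1000L + i, num.threads = 1L)
    }))
    new("EnsembleModel", forests = forests, manifest = featureManifest(),
        meta = list(seed = as.integer(seed), nTrees = as.integer(nTrees),
                    nSub = as.integer(nSub), nPos = length(pos),
                    nNeg = length(neg)))
}

# positive-class probabilities from one sub-model (ranger fit or function)
.subScore <- function(sub, X) {
    if (is.function(sub)) return(sub(X))
    p <- predict(sub, data.frame(X, check.names = FALSE),
                 num.threads = 1L)$predictions
    p[, "misassembled"]
}

#' Contig eligibility for misassembly calling
#'
#' Only contigs strictly longer than `minLength` (default 5000 bp) are
#' scored; shorter contigs carry no call.
#'
#' @param lengths integer vector of contig lengths.
#' @param minLength eligibility threshold in bp.
#' @return logical vector.
#' @export
eligibleContigs <- function(lengths, minLength = 5000L) {
    lengths > minLength
}

#' Score contigs with the ensemble
#'
#' The misassembly score `S(c)` of a contig is the mean positive-class
#' probability over the ensemble's sub-models. Ineligible contigs (length
#' not above `minLength`, or undefined features) receive `NA` with a reason.
#'
#' @param model an [EnsembleModel-class].
#' @param features data.frame with the manifest columns, a `contig_id`
#'   column, and a `length` column (as produced by [extractFeatures()] in
#'   contig mode).
#' @param minLength eligibility threshold in bp (default 5000, strict).
#' @param flagThreshold score above which a contig is flagged suspicious in
#'   the output label (default 0.5; the correction step applies its own,
#'   stricter threshold).
#' @return data.frame: `contig_id`, `length`, `score`, `eligible`, `label`,
#'   `reason`.
#' @export
scoreContigs <- function(model, features, minLength = 5000L,
                         flagThreshold = 0.5) {
    stopifnot(is(model, "EnsembleModel"))
    X <- .checkManifest(features, model@manifest)
    ok <- stats::complete.cases(X)
    eligible <- eligibleContigs(features$length, minLength) & ok
    score <- rep(NA_real_, nrow(X))
    if (any(eligible)) {
        subp <- vapply(model@forests,
                       function(f) .subScore(f, X[eligible, , drop = FALSE]),
                       numeric(sum(eligible)))
        subp <- matrix(subp, nrow = sum(eligible))
        score[eligible] <- rowMeans(subp)
    }
    data.frame(
        contig_id = features$contig_id,
        length = features$length,
        score = score,
        eligible = eligible,
        label = !is.na(score) & score >= flagThreshold,
        reason = ifelse(eligible, "",
                        ifelse(!ok, "features undefined", "contig too short")),
        stringsAsFactors = FALSE)
}

#' Persist / restore an ensemble model
#'
#' The archive embeds the feature manifest and a format version; loading
#' refuses archives whose manifest does not match the current
#' [featureManifest()].
#'
#' @param model an [EnsembleModel-class].
#' @param path file path for the model archive.
#' @return `loadEnsemble()` returns the [EnsembleModel-class].
#' @export
saveEnsemble <- function(model, path) {
    stopifnot(is(model, "EnsembleModel"))
    saveRDS(list(format = "contigMend-ensemble-1", manifest = model@manifest,
                 forests = model@forests, meta = model@meta), path)
    invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "contigMend-ensemble-1"))
        stop("not a contigMend ensemble archive: ", path)
    if (!identical(obj$manifest, featureManifest()))
        stop("model archive manifest does not match this package's ",
             "feature manifest; re-train the model")
    new("EnsembleModel", forests = obj$forests, manifest = obj$manifest,
        meta = obj$meta)
}
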