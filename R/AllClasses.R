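#' @import methods
#' @importFrom stats median rnorm runif rbinom rlnorm predict setNames
#' @importFrom utils write.table read.delim head
NULL

#' Read-to-contig alignment collection
#'
#' Container for parsed primary and supplementary alignment records of
#' paired-end reads against an assembly, together with the contig lengths
#' declared in the alignment header. Records use 0-based half-open
#' coordinates. Created by [readContigAlignments()].
#'
#' @slot records data.frame of alignment records (one row per retained
#'   alignment; see [readContigAlignments()] for columns).
#' @slot contigLengths named integer vector of contig lengths from the header.
#' @slot path path of the BAM file the records were read from.
#' @slot minMapq the MAPQ threshold applied on ingestion.
#' @export
setClass("ContigAlignments",
    representation(
        records = "data.frame",
        contigLengths = "integer",
        path = "character",
        minMapq = "integer"
    )
)

#' Insert-size model of a paired-end library
#'
#' The insert size of a read pair is assumed to follow a normal distribution
#' N(mu, sigma). mu is estimated as the median of all insert sizes and sigma
#' as their median absolute deviation (unscaled, floored at `sigmaFloor`).
#' A pair is proper when its insert size lies within `[mu - 3 sigma,
#' mu + 3 sigma]` and the mates have consistent (forward-reverse)
#' orientation.
#'
#' @slot mu median insert size (bp).
#' @slot sigma floored median absolute deviation of insert sizes (bp).
#' @slot lower,upper proper-pair insert bounds, `mu +/- 3 sigma`.
#' @slot nPairs number of read pairs used in the fit.
#' @export
setClass("InsertSizeModel",
    representation(mu = "numeric", sigma = "numeric",
                   lower = "numeric", upper = "numeric", nPairs = "integer"),
    validity = function(object) {
        if (object@sigma <= 0) return("sigma must be positive")
        if (object@lower > object@mu || object@mu > object@upper)
            return("bounds must satisfy lower <= mu <= upper")
        TRUE
    }
)

#' Per-base pileup tracks over one contig
#'
#' Integer arrays of length `L` (contig length), all 0-based positionally:
#' read coverage (primary aligned spans), fragment coverage (bases spanned by
#' the sequencing fragment of proper pairs, each pair once), per-base counts
#' of correct / discordant / ambiguous base alignments, read-breakpoint
#' counts (alignment boundaries that do not coincide with read ends), and the
#' number of reads whose full extent (including soft-clipped tails) overlaps
#' each base.
#'
#' @export
setClass("PileupTrack",
    representation(
        contig = "character",
        length = "integer",
        readCoverage = "integer",
        fragmentCoverage = "integer",
        nCorrect = "integer",
        nDiscordant = "integer",
        nAmbiguous = "integer",
        readBreakpointCount = "integer",
        readsAtBase = "integer"
    ),
    validity = function(object) {
        L <- object@length
        arr <- list(object@readCoverage, object@fragmentCoverage,
                    object@nCorrect, object@nDiscordant, object@nAmbiguous,
                    object@readBreakpointCount, object@readsAtBase)
        if (any(vapply(arr, length, 1L) != L))
            return("all per-base arrays must have length equal to the contig length")
        if (any(vapply(arr, function(x) any(x < 0L), TRUE)))
            return("per-base counts must be non-negative")
        if (any(object@nCorrect + object@nDiscordant + object@nAmbiguous >
                object@readCoverage))
            return("base-call counts cannot exceed read coverage")
        TRUE
    }
)

#' Isolation forest model
#'
#' An ensemble of isolation trees built on uniformly subsampled rows with
#' uniformly random axis-parallel splits. The anomaly score of a point is the
#' canonical isolation score `s = 2^(-E[h]/c(psi))` in (0, 1), where `E[h]`
#' is the mean path length over trees (leaf depth plus the `c(size)`
#' adjustment for unresolved leaves) and `c(psi)` the expected path length of
#' an unsuccessful BST search among `psi` points. Higher scores mean easier
#' to isolate, i.e. more anomalous.
#'
#' @slot trees list of flattened tree tables.
#' @slot sampleSize subsample size psi per tree.
#' @slot nTrees number of trees.
#' @slot manifest column names the model was fitted on.
#' @slot seed seed used for fitting.
#' @export
setClass("IsolationForest",
    representation(trees = "list", sampleSize = "integer", nTrees = "integer",
                   manifest = "character", seed = "integer")
)

#' Down-sampled random-forest ensemble for misassembly scoring
#'
#' Ten sub-classifiers, each a 1000-tree probability forest trained on all
#' misassembled (positive) contigs plus an equal-size random subset of
#' correctly assembled (negative) contigs drawn without replacement. The
#' misassembly score S(c) of a contig is the mean positive-class probability
#' over the sub-models.
#'
#' @slot forests list of sub-models (ranger fits, or plain functions mapping
#'   a feature matrix to positive-class probabilities).
#' @slot manifest ordered feature names the ensemble was trained on.
#' @slot meta list of training metadata (seed, hyperparameters, class counts).
#' @export
setClass("EnsembleModel",
    representation(forests = "list", manifest = "character", meta = "list")
)

#' @describeIn ContigAlignments-class compact display
#' @param object a `ContigAlignments` object
#' @export
setMethod("show", "ContigAlignments", function(object) {
    r <- object@records
    cat("ContigAlignments:", sum(!r$isSupplementary), "primary and",
        sum(r$isSupplementary), "supplementary records on",
        length(unique(r$contig)), "of", length(object@contigLengths),
        "contigs (MAPQ >=", object@minMapq, ")\n")
})

#' @describeIn InsertSizeModel-class compact display
#' @param object an `InsertSizeModel` object
#' @export
setMethod("show", "InsertSizeModel", function(object) {
    cat(sprintf(
        "InsertSizeModel: mu = %g bp, sigma (MAD) = %g bp, proper range [%g, %g], n = %d pairs\n",
        object@mu, object@sigma, object@lower, object@upper, object@nPairs))
})

#' @describeIn PileupTrack-class compact display
#' @param object a `PileupTrack` object
#' @export
setMethod("show", "PileupTrack", function(object) {
    cat(sprintf("PileupTrack for %s (%d bp): mean read coverage %.2f, mean fragment coverage %.2f\n",
                object@contig, object@length, mean(object@readCoverage),
                mean(object@fragmentCoverage)))
})

#' @describeIn IsolationForest-class compact display
#' @param object an `IsolationForest` object
#' @export
setMethod("show", "IsolationForest", function(object) {
    cat(sprintf("IsolationForest: %d trees, subsample %d, %d features\n",
                object@nTrees, object@sampleSize, length(object@manifest)))
})

#' @describeIn EnsembleModel-class compact display
#' @param object an `EnsembleModel` object
#' @export
setMethod("show", "EnsembleModel", function(object) {
    cat(sprintf("EnsembleModel: %d sub-models over %d features\n",
                length(object@forests), length(object@manifest)))
})

#' Accessors for alignment collections
#'
#' @param x a [ContigAlignments-class] object
#' @return `alignmentRecords()` returns the records data.frame;
#'   `contigLengths()` the named integer vector of contig lengths.
#' @export
alignmentRecords <- function(x) {
    stopifnot(is(x, "ContigAlignments"))
    x@records
}

#' @rdname alignmentRecords
#' @export
contigLengths <- function(x) {
    stopifnot(is(x, "ContigAlignments"))
    x@contigLengths
}

#' @rdname alignmentRecords
#' @param model an [InsertSizeModel-class] object
#' @export
insertMu <- function(model) model@mu

#' @rdname alignmentRecords
#' @export
insertSigma <- function(model) model@sigma

#' @rdname alignmentRecords
#' @export
insertBounds <- function(model) c(lower = model@lower, upper = model@upper)
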