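#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width reduce
#'   findOverlaps granges ranges
#' @importFrom IRanges IRanges
NULL

#' Genome annotation with derived introns
#'
#' Container for a gene -> transcript -> exon hierarchy plus derived
#' introns. All ranges are \code{GRanges} in the usual Bioconductor
#' 1-based closed convention; conversion to/from the 1-based inclusive
#' GTF and 0-based half-open BED conventions happens only at the I/O
#' boundary (see \code{\link{parseGTF}}, \code{\link{intronsAsBED}}).
#'
#' @slot genes \code{GRanges}, one per gene; mcols: \code{gene_id},
#'   \code{biotype}. Start/end are the outermost transcript boundaries,
#'   so the TSS is \code{start} on \code{+} and \code{end} on \code{-}.
#' @slot transcripts \code{GRanges}; mcols: \code{transcript_id},
#'   \code{gene_id}.
#' @slot exons \code{GRanges}; mcols: \code{transcript_id},
#'   \code{gene_id}. Sorted by genomic coordinate within transcript.
#' @slot cds \code{GRanges}; mcols: \code{transcript_id}. May be empty.
#' @slot utr3 \code{GRanges}; mcols: \code{transcript_id}. May be empty.
#' @slot introns \code{GRanges} derived by \code{\link{deriveIntrons}};
#'   mcols: \code{intron_id}, \code{gene_id}, \code{transcript_id},
#'   \code{index} (1-based from the transcript 5' end),
#'   \code{n_introns}, \code{phase} (0/1/2, NA outside a CDS),
#'   \code{is_utr3}.
#' @slot chromLengths named numeric, chromosome lengths in bp.
#'
#' @export
setClass("GenomeAnnotation",
    representation(
        genes = "GRanges",
        transcripts = "GRanges",
        exons = "GRanges",
        cds = "GRanges",
        utr3 = "GRanges",
        introns = "GRanges",
        chromLengths = "numeric"
    )
)

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    gid <- mcols(object@genes)$gene_id
    if (anyDuplicated(gid))
        msg <- c(msg, "gene IDs must be unique")
    tx <- mcols(object@transcripts)
    if (length(object@transcripts) &&
        !all(tx$gene_id %in% gid))
        msg <- c(msg, "every transcript must belong to a known gene")
    if (anyDuplicated(tx$transcript_id))
        msg <- c(msg, "transcript IDs must be unique")
    cl <- object@chromLengths
    if (length(cl)) {
        ex <- object@exons
        known <- as.character(seqnames(ex)) %in% names(cl)
        if (!all(known)) {
            msg <- c(msg, "exons on chromosomes absent from chromLengths")
        } else if (length(ex) &&
                   any(end(ex) > cl[as.character(seqnames(ex))]))
            msg <- c(msg, "exon intervals exceed chromosome bounds")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GenomeAnnotation gene ranges
#' @param x a \code{GenomeAnnotation}
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation transcript ranges
#' @export
setGeneric("txRanges", function(x) standardGeneric("txRanges"))
#' @export
setMethod("txRanges", "GenomeAnnotation", function(x) x@transcripts)

#' @describeIn GenomeAnnotation exon ranges
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @export
setMethod("exonRanges", "GenomeAnnotation", function(x) x@exons)

#' @describeIn GenomeAnnotation CDS ranges
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @export
setMethod("cdsRanges", "GenomeAnnotation", function(x) x@cds)

#' @describeIn GenomeAnnotation 3' UTR ranges
#' @export
setGeneric("utr3Ranges", function(x) standardGeneric("utr3Ranges"))
#' @export
setMethod("utr3Ranges", "GenomeAnnotation", function(x) x@utr3)

#' @describeIn GenomeAnnotation derived introns
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @export
setMethod("introns", "GenomeAnnotation", function(x) x@introns)

#' @describeIn GenomeAnnotation chromosome lengths (bp)
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) x@chromLengths)

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:",
        length(object@genes), "genes,",
        length(object@transcripts), "transcripts,",
        length(object@exons), "exons,",
        length(object@introns), "introns\n")
    cat("  chromosomes:", length(object@chromLengths), "\n")
    cat("  CDS/3'UTR segments:", length(object@cds), "/",
        length(object@utr3), "\n")
})

#' Maximum-entropy splice-site model
#'
#' Log-linear distribution over fixed-width sequence windows whose
#' constrained marginals (single positions plus adjacent and skip-one
#' position pairs by default) match the empirical marginals of the
#' training sites. Fitted by iterative proportional scaling with exact
#' model marginals from a transfer-matrix recursion; see
#' \code{\link{trainMaxEnt}}.
#'
#' @slot kind "donor" or "acceptor" (or free-form for toy models).
#' @slot width window width in nt.
#' @slot alphabet character vector of residues (default A,C,G,T).
#' @slot singleton list of per-position log-potential vectors.
#' @slot pairs list of list(pos = c(i, j), logpot = 4x4 matrix).
#' @slot logZ log partition function.
#' @slot background per-residue order-0 composition used for log-odds
#'   scoring.
#' @slot trainedOn number of training sites.
#' @slot iterations scaling sweeps used.
#' @slot maxDeviation largest absolute difference between a constrained
#'   model marginal and its empirical counterpart at convergence.
#'
#' @export
setClass("MaxEntModel",
    representation(
        kind = "character",
        width = "integer",
        alphabet = "character",
        singleton = "list",
        pairs = "list",
        logZ = "numeric",
        background = "numeric",
        trainedOn = "integer",
        iterations = "integer",
        maxDeviation = "numeric"
    )
)

setValidity("MaxEntModel", function(object) {
    msg <- character()
    if (length(object@singleton) != object@width)
        msg <- c(msg, "need one singleton potential per position")
    if (length(object@background) != length(object@alphabet))
        msg <- c(msg, "background must cover the alphabet")
    if (abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must sum to 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MaxEntModel", function(object) {
    cat(sprintf(
        "MaxEntModel (%s): width %d, %d pair constraints, trained on %d sites\n",
        object@kind, object@width, length(object@pairs), object@trainedOn))
    cat(sprintf("  converged after %d sweeps, max marginal deviation %.3g\n",
        object@iterations, object@maxDeviation))
})
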