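#' @importFrom stats median
NULL

#' Trimmed mean of per-base depths
#'
#' Mean after removing the top and bottom \code{trim_frac} of the
#' sorted values (symmetric trim, \code{floor(n * trim_frac)} values
#' per tail).
#'
#' @param depth numeric vector of per-base depths
#' @param trim_frac fraction trimmed from each tail, in [0, 0.5)
#' @return numeric scalar
#' @export
trimmedMean <- function(depth, trim_frac = 0.05) {
    if (!length(depth)) stop("empty depth vector")
    if (trim_frac < 0 || trim_frac >= 0.5)
        stop("trim_frac must be in [0, 0.5)")
    mean(depth, trim = trim_frac)
}

.jxKey <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

#' Splicing depth of an intron
#'
#' Count of junction reads whose donor and acceptor exactly match the
#' intron boundaries. Junctions matching only one boundary, or lying
#' strictly inside the intron, contribute to internal-splicing
#' evidence instead.
#'
#' @param junctions data.frame chrom/start/end/strand/count (1-based
#'   closed intron coordinates)
#' @param intron a length-1 GRanges
#' @return list(splice_depth, internal_reads) where
#'   \code{internal_reads} is the largest read count of any junction
#'   inside the intron that does not match both boundaries
#' @export
spliceDepth <- function(junctions, intron) {
    ch <- as.character(seqnames(intron))
    s <- start(intron); e <- end(intron)
    j <- junctions[junctions$chrom == ch &
                   junctions$start >= s & junctions$end <= e, ,
                   drop = FALSE]
    exact <- j$start == s & j$end == e
    internal <- j[!exact, , drop = FALSE]
    list(splice_depth = sum(j$count[exact]),
         internal_reads = if (nrow(internal)) max(internal$count) else 0L)
}

.covWindow <- function(coverage, chrom, s, e) {
    as.integer(S4Vectors::window(coverage[[chrom]], s, e))
}

#' IR ratio of one intron
#'
#' IR ratio = median per-base depth of the intron over the median of
#' the pooled per-base depths of its two flanking exons, clamped to
#' [0, 1] (0 when the exon median is 0). Internal splicing is flagged
#' when any junction with at least \code{min_internal_reads} reads lies
#' inside the intron without matching both boundaries.
#'
#' @param intron length-1 GRanges carrying mcols \code{intron_id},
#'   \code{transcript_id}
#' @param ann the \code{GenomeAnnotation} (for the flanking exons)
#' @param coverage per-chromosome \code{RleList}
#' @param junctions junction count data.frame
#' @param trim_frac trim for the intron-depth trimmed mean
#' @param min_internal_reads reads needed to call internal splicing
#' @return one-row data.frame (an IR call)
#' @export
computeIRRatio <- function(intron, ann, coverage, junctions,
                           trim_frac = 0.05, min_internal_reads = 2) {
    ch <- as.character(seqnames(intron))
    s <- start(intron); e <- end(intron)
    ex <- exonRanges(ann)
    ex <- ex[mcols(ex)$transcript_id == mcols(intron)$transcript_id]
    left <- ex[end(ex) == s - 1L]
    right <- ex[start(ex) == e + 1L]
    if (length(left) != 1L || length(right) != 1L)
        stop("intron ", mcols(intron)$intron_id,
             " lacks a flanking exon on one side")
    d_in <- .covWindow(coverage, ch, s, e)
    d_ex <- c(.covWindow(coverage, ch, start(left), end(left)),
              .covWindow(coverage, ch, start(right), end(right)))
    ex_med <- median(d_ex)
    ir <- if (ex_med == 0) 0 else min(1, max(0, median(d_in) / ex_med))
    sd <- spliceDepth(junctions, intron)
    data.frame(
        intron_id = mcols(intron)$intron_id,
        gene_id = mcols(intron)$gene_id,
        chrom = ch, start = s, end = e,
        strand = as.character(strand(intron)),
        ir_ratio = ir,
        splice_depth = sd$splice_depth,
        intron_depth_trimmed_mean = trimmedMean(d_in, trim_frac),
        flank_exon_median_depth = ex_med,
        internal_splicing_detected = sd$internal_reads >= min_internal_reads,
        stringsAsFactors = FALSE)
}

#' IR calls for every intron of an annotation
#'
#' Applies \code{\link{computeIRRatio}} to each derived intron and
#' attaches the filter verdicts of \code{\link{filterIRCalls}}.
#'
#' @inheritParams computeIRRatio
#' @param ir_ratio_min retention-call threshold on the IR ratio
#' @param splice_depth_min minimum junction reads spanning the intron
#' @param coverage_min minimum splice depth + trimmed intron depth
#' @return data.frame, one row per intron
#' @export
irCalls <- function(ann, coverage, junctions, trim_frac = 0.05,
                    min_internal_reads = 2, ir_ratio_min = 0.1,
                    splice_depth_min = 4, coverage_min = 10) {
    intr <- introns(ann)
    n <- length(intr)
    ex <- exonRanges(ann)
    ## flanking exons by boundary lookup within transcript
    exkey_end <- paste(mcols(ex)$transcript_id, end(ex))
    exkey_start <- paste(mcols(ex)$transcript_id, start(ex))
    tid <- mcols(intr)$transcript_id
    left <- match(paste(tid, start(intr) - 1L), exkey_end)
    right <- match(paste(tid, end(intr) + 1L), exkey_start)
    if (anyNA(left) || anyNA(right))
        stop("intron without a flanking exon: ",
             mcols(intr)$intron_id[which(is.na(left) | is.na(right))[1]])
    ## junction assignment: exact-boundary vs internal
    key_i <- .jxKey(as.character(seqnames(intr)), start(intr), end(intr))
    key_j <- .jxKey(junctions$chrom, junctions$start, junctions$end)
    sdep <- vapply(split(junctions$count, key_j), sum,
                   numeric(1))[key_i]
    sdep[is.na(sdep)] <- 0
    jgr <- GRanges(junctions$chrom,
                   IRanges(junctions$start, junctions$end))
    hits <- findOverlaps(jgr, granges(intr), type = "within")
    internal_reads <- numeric(n)
    if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        inner <- key_j[qh] != key_i[sh]
        for (k in which(inner))
            internal_reads[sh[k]] <- max(internal_reads[sh[k]],
                                         junctions$count[qh[k]])
    }
    chv <- as.character(seqnames(intr))
    ## decode each chromosome's coverage once; Rle window dispatch per
    ## intron is the hot path otherwise
    covv <- lapply(coverage, as.integer)
    ir <- numeric(n); tmean <- numeric(n); exmed <- numeric(n)
    for (i in seq_len(n)) {
        v <- covv[[chv[i]]]
        d_in <- v[start(intr)[i]:end(intr)[i]]
        d_ex <- c(v[start(ex)[left[i]]:end(ex)[left[i]]],
                  v[start(ex)[right[i]]:end(ex)[right[i]]])
        exmed[i] <- median(d_ex)
        ir[i] <- if (exmed[i] == 0) 0
                 else min(1, max(0, median(d_in) / exmed[i]))
        tmean[i] <- trimmedMean(d_in, trim_frac)
    }
    calls <- data.frame(
        intron_id = mcols(intr)$intron_id,
        gene_id = mcols(intr)$gene_id,
        chrom = chv, start = start(intr), end = end(intr),
        strand = as.character(strand(intr)),
        ir_ratio = ir, splice_depth = unname(sdep),
        intron_depth_trimmed_mean = tmean,
        flank_exon_median_depth = exmed,
        internal_splicing_detected = internal_reads >= min_internal_reads,
        stringsAsFactors = FALSE)
    filterIRCalls(calls, ir_ratio_min, splice_depth_min, coverage_min)
}

#' Partition IR calls into retained / not retained / unmeasurable
#'
#' An intron is \emph{retained} when it passes all filters: IR ratio at
#' least \code{ir_ratio_min}, splicing depth at least
#' \code{splice_depth_min}, splicing depth plus trimmed mean intron
#' depth at least \code{coverage_min}, and no internal splicing.
#' Introns failing the depth/coverage/internal-splicing filters are
#' \emph{unmeasurable}; measurable introns below the IR-ratio threshold
#' are \emph{not_retained}. Idempotent.
#'
#' @param calls data.frame from \code{\link{irCalls}} or
#'   \code{\link{computeIRRatio}}
#' @inheritParams irCalls
#' @return \code{calls} with added columns \code{passes_filters},
#'   \code{category}, \code{filter_reasons}
#' @export
filterIRCalls <- function(calls, ir_ratio_min = 0.1,
                          splice_depth_min = 4, coverage_min = 10) {
    sd_ok <- calls$splice_depth >= splice_depth_min
    cov_ok <- calls$splice_depth + calls$intron_depth_trimmed_mean >=
        coverage_min
    int_ok <- !calls$internal_splicing_detected
    ratio_ok <- calls$ir_ratio >= ir_ratio_min
    measurable <- sd_ok & cov_ok & int_ok
    calls$passes_filters <- measurable & ratio_ok
    calls$category <- ifelse(!measurable, "unmeasurable",
                             ifelse(ratio_ok, "retained", "not_retained"))
    reasons <- mapply(function(a, b, c) {
        r <- c(if (!a) "splicing depth",
               if (!b) "coverage",
               if (!c) "internal splicing")
        paste(r, collapse = ";")
    }, sd_ok, cov_ok, int_ok)
    calls$filter_reasons <- unname(reasons)
    calls
}

#' FPKM from read counts
#'
#' FPKM = count / (merged exonic kbp x total mapped reads / 1e6), the
#' union-exon gene model.
#'
#' @param counts named numeric of per-gene read counts
#' @param exon_kbp named numeric of merged exonic lengths (kbp), as
#'   from \code{\link{mergedExonicKbp}}
#' @param total_reads total mapped reads
#' @return named numeric FPKM per gene
#' @export
computeFPKM <- function(counts, exon_kbp, total_reads) {
    if (total_reads <= 0) stop("total_reads must be positive")
    if (any(exon_kbp <= 0)) stop("exon_kbp must be positive")
    counts / (exon_kbp[names(counts)] * total_reads / 1e6)
}

#' Aggregate IR calls to genes
#'
#' The gene's IR ratio is the highest IR ratio among its measurable
#' introns (0 when none); a gene is an IR gene when it is expressed
#' (FPKM at or above \code{fpkm_expressed}) and has at least one
#' retained intron. Also reports the IR-gene fraction among expressed
#' genes as attribute \code{fraction_ir}.
#'
#' @param calls filtered IR call table
#' @param fpkm named numeric FPKM per gene (defines the gene universe)
#' @param fpkm_expressed expressed-gene threshold
#' @return data.frame gene_id/fpkm/gene_ir_ratio/n_retained/
#'   retained_intron_ids/is_expressed/is_ir_gene, with attribute
#'   \code{fraction_ir}
#' @export
aggregateGeneIR <- function(calls, fpkm, fpkm_expressed = 1) {
    gene_id <- names(fpkm)
    meas <- calls[calls$category != "unmeasurable", , drop = FALSE]
    ret <- calls[calls$category == "retained", , drop = FALSE]
    max_ir <- vapply(split(meas$ir_ratio, meas$gene_id),
                     max, numeric(1))
    n_ret <- vapply(split(ret$intron_id, ret$gene_id),
                    length, integer(1))
    ret_ids <- vapply(split(ret$intron_id, ret$gene_id),
                      paste, character(1), collapse = ",")
    out <- data.frame(
        gene_id = gene_id,
        fpkm = unname(fpkm),
        gene_ir_ratio = ifelse(gene_id %in% names(max_ir),
                               max_ir[gene_id], 0),
        n_retained = ifelse(gene_id %in% names(n_ret),
                            n_ret[gene_id], 0L),
        retained_intron_ids = ifelse(gene_id %in% names(ret_ids),
                                     ret_ids[gene_id], ""),
        stringsAsFactors = FALSE)
    out$is_expressed <- out$fpkm >= fpkm_expressed
    out$is_ir_gene <- out$is_expressed & out$n_retained >= 1
    attr(out, "fraction_ir") <-
        if (any(out$is_expressed))
            sum(out$is_ir_gene) / sum(out$is_expressed) else NA_real_
    out
}

#' Gene-body coverage profile
#'
#' Mean depth per percentile bin of the spliced gene body, 5' to 3' in
#' transcript orientation (so minus-strand genes are reversed), using
#' one representative transcript per gene (most exons, ties broken by
#' length then ID). Each gene's profile is scaled by its mean depth
#' before averaging; the averaged profile is normalized to max 1.
#'
#' @param coverage per-chromosome \code{RleList}
#' @param ann a \code{GenomeAnnotation}
#' @param n_bins number of percentile bins
#' @param genes optional gene IDs to restrict to (e.g. expressed genes)
#' @return numeric vector of length \code{n_bins}, max 1
#' @export
geneBodyCoverage <- function(coverage, ann, n_bins = 100, genes = NULL) {
    rep_tx <- .representativeTx(ann)
    if (!is.null(genes)) rep_tx <- rep_tx[names(rep_tx) %in% genes]
    ex <- exonRanges(ann)
    covv <- lapply(coverage, as.integer)
    prof <- rep(0, n_bins)
    n_used <- 0L
    for (tid in rep_tx) {
        e <- ex[mcols(ex)$transcript_id == tid]
        e <- e[order(start(e))]
        ch <- as.character(seqnames(e)[1])
        d <- unlist(lapply(seq_along(e), function(i)
            covv[[ch]][start(e)[i]:end(e)[i]]))
        if (as.character(strand(e)[1]) == "-") d <- rev(d)
        if (mean(d) == 0 || length(d) < n_bins) next
        bin <- ceiling(seq_along(d) / length(d) * n_bins)
        p <- vapply(split(d, bin), mean, numeric(1))
        prof <- prof + p / mean(d)
        n_used <- n_used + 1L
    }
    if (n_used == 0) stop("no expressed genes with coverage")
    prof <- prof / n_used
    prof / max(prof)
}
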