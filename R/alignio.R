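#' Simulate read placements
#'
#' Emits individual read alignments consistent with the coverage model
#' of \code{\link{simulateEvidence}}: exon-body reads, intron-body
#' reads at rate rho, and junction reads whose N operation matches the
#' intron boundaries exactly.
#'
#' @param sim output of \code{\link{simulateAnnotation}}
#' @param cfg the \code{\link{simConfig}}
#' @param seed RNG seed
#' @return data.frame chrom/pos/cigar/strand (SAM-ready, 1-based pos)
#' @export
simulateReads <- function(sim, cfg, seed = cfg$seed + 2L) {
    set.seed(seed)
    ann <- sim$annotation
    tg <- sim$truth$genes
    ti <- sim$truth$introns
    rl <- cfg$read_length
    ex <- exonRanges(ann)
    intr <- introns(ann)
    out <- list()
    emit <- function(ch, pos, cigar, strand) {
        out[[length(out) + 1L]] <<- data.frame(
            chrom = ch, pos = pos, cigar = cigar, strand = strand,
            stringsAsFactors = FALSE)
    }
    for (g in seq_len(nrow(tg))) {
        gid <- tg$gene_id[g]
        lambda <- cfg$depth_per_fpkm * tg$fpkm[g]
        ch <- tg$chrom[g]
        st <- tg$strand[g]
        gex <- ex[mcols(ex)$gene_id == gid]
        for (i in seq_along(gex)) {
            w <- width(gex)[i]
            len <- min(rl, w)
            n <- rpois(1, lambda * w / len)
            if (n > 0)
                emit(ch, start(gex)[i] +
                         sample.int(w - len + 1L, n, replace = TRUE) - 1L,
                     sprintf("%dM", len), st)
        }
        gintr <- intr[mcols(intr)$gene_id == gid]
        if (!length(gintr)) next
        m <- match(mcols(gintr)$intron_id, ti$intron_id)
        for (i in seq_along(gintr)) {
            rho <- ti$rho[m[i]]
            w <- width(gintr)[i]
            len <- min(rl, w)
            n <- rpois(1, lambda * rho * w / len)
            if (n > 0)
                emit(ch, start(gintr)[i] +
                         sample.int(w - len + 1L, n, replace = TRUE) - 1L,
                     sprintf("%dM", len), st)
            nj <- rpois(1, cfg$junction_factor * lambda * (1 - rho))
            if (nj > 0) {
                a <- sample(20:(rl - 20), nj, replace = TRUE)
                for (k in seq_len(nj))
                    emit(ch, start(gintr)[i] - a[k],
                         sprintf("%dM%dN%dM", a[k], w, rl - a[k]), st)
            }
        }
    }
    do.call(rbind, out)
}

#' Write reads as SAM
#'
#' Minimal coordinate-sortable SAM with @SQ headers; sequences and
#' qualities are omitted ("*").
#'
#' @param reads data.frame from \code{\link{simulateReads}}
#' @param chromLengths named numeric
#' @param path output .sam path
#' @export
writeSAM <- function(reads, chromLengths, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    body <- sprintf("r%06d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                    seq_len(nrow(reads)), flag, reads$chrom, reads$pos,
                    reads$cigar)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read coverage and junction evidence from SAM/BAM
#'
#' Walks each alignment's CIGAR: M/=/X operations add to per-base
#' coverage, N operations define splice junctions (a junction read
#' counts as correctly crossing only when its N operation matches an
#' intron's boundaries exactly -- the matching happens later in
#' \code{\link{spliceDepth}}), D consumes reference without coverage.
#' SAM input is converted on the fly via \code{Rsamtools::asBam}.
#'
#' @param path SAM or BAM file
#' @param chromLengths named numeric of chromosome lengths
#' @return list(coverage = RleList, junctions = data.frame)
#' @export
readAlignmentEvidence <- function(path, chromLengths) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                 indexDestination = FALSE)
    }
    bam <- Rsamtools::scanBam(
        path, param = Rsamtools::ScanBamParam(
            what = c("rname", "pos", "cigar")))[[1]]
    keep <- !is.na(bam$pos)
    rname <- as.character(bam$rname)[keep]
    pos <- bam$pos[keep]
    cigar <- bam$cigar[keep]

    cov_seg <- list()
    jx_key <- character(0)
    ops_list <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
    for (k in seq_along(cigar)) {
        ref <- pos[k]
        for (op in ops_list[[k]]) {
            n <- as.integer(sub("[A-Z=]$", "", op))
            type <- substr(op, nchar(op), nchar(op))
            if (type %in% c("M", "=", "X")) {
                cov_seg[[length(cov_seg) + 1L]] <-
                    c(ref, ref + n - 1L, match(rname[k], names(chromLengths)))
                ref <- ref + n
            } else if (type == "D") {
                ref <- ref + n
            } else if (type == "N") {
                jx_key <- c(jx_key,
                            .jxKey(rname[k], ref, ref + n - 1L))
                ref <- ref + n
            }
            ## I/S/H/P consume no reference
        }
    }
    segs <- do.call(rbind, cov_seg)
    gr <- GRanges(names(chromLengths)[segs[, 3]],
                  IRanges(segs[, 1], segs[, 2]))
    cov <- GenomicRanges::coverage(
        gr, width = setNames(as.integer(chromLengths),
                             names(chromLengths)))
    jt <- table(jx_key)
    parts <- strsplit(names(jt), ":", fixed = TRUE)
    junctions <- data.frame(
        chrom = vapply(parts, `[[`, character(1), 1),
        start = as.integer(vapply(parts, `[[`, character(1), 2)),
        end = as.integer(vapply(parts, `[[`, character(1), 3)),
        strand = "*",
        count = as.integer(jt),
        stringsAsFactors = FALSE)
    list(coverage = cov, junctions = junctions)
}
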