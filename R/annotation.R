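#' @importFrom rtracklayer import export
NULL

## ---- construction -----------------------------------------------------

#' Assemble a GenomeAnnotation from component ranges
#'
#' Low-level constructor used by \code{\link{parseGTF}} and the
#' synthetic-data generator. Exons are sorted by coordinate within
#' transcript, gene/transcript ranges are recomputed from the exons,
#' 3' UTRs are derived from the CDS when not supplied, and introns are
#' derived with index, phase and 3'-UTR flags.
#'
#' @param exons GRanges with mcols \code{transcript_id}, \code{gene_id}.
#' @param cds optional GRanges with mcols \code{transcript_id}.
#' @param utr3 optional GRanges with mcols \code{transcript_id}; derived
#'   from the CDS when \code{NULL}.
#' @param biotype named character of per-gene biotypes (default
#'   "protein_coding" where a CDS exists).
#' @param chromLengths named numeric; inferred from the exon extent when
#'   missing.
#' @return a \code{\linkS4class{GenomeAnnotation}}
#' @export
makeGenomeAnnotation <- function(exons, cds = GRanges(), utr3 = NULL,
                                 biotype = NULL, chromLengths = NULL) {
    stopifnot(is(exons, "GRanges"),
              all(c("transcript_id", "gene_id") %in% names(mcols(exons))))
    o <- order(mcols(exons)$transcript_id, start(exons))
    exons <- exons[o]
    txid <- mcols(exons)$transcript_id
    gid <- mcols(exons)$gene_id

    ## structural check: exons within one transcript must not overlap
    n <- length(exons)
    if (n > 1) {
        same <- txid[-1] == txid[-n]
        bad <- same & start(exons)[-1] <= end(exons)[-n]
        if (any(bad))
            stop("overlapping exons in transcript(s): ",
                 paste(unique(txid[-1][bad]), collapse = ", "))
    }

    tx_first <- !duplicated(txid)
    tx_start <- vapply(split(start(exons), txid), min, numeric(1))
    tx_end <- vapply(split(end(exons), txid), max, numeric(1))
    transcripts <- GRanges(
        seqnames(exons)[tx_first],
        IRanges(tx_start[txid[tx_first]], tx_end[txid[tx_first]]),
        strand = strand(exons)[tx_first])
    mcols(transcripts)$transcript_id <- txid[tx_first]
    mcols(transcripts)$gene_id <- gid[tx_first]

    ggid <- mcols(transcripts)$gene_id
    g_first <- !duplicated(ggid)
    g_start <- vapply(split(start(transcripts), ggid), min, numeric(1))
    g_end <- vapply(split(end(transcripts), ggid), max, numeric(1))
    genes <- GRanges(
        seqnames(transcripts)[g_first],
        IRanges(g_start[ggid[g_first]], g_end[ggid[g_first]]),
        strand = strand(transcripts)[g_first])
    mcols(genes)$gene_id <- ggid[g_first]
    if (is.null(biotype)) {
        coding <- unique(mcols(transcripts)$gene_id[
            mcols(transcripts)$transcript_id %in% mcols(cds)$transcript_id])
        biotype <- ifelse(mcols(genes)$gene_id %in% coding,
                          "protein_coding", "non_coding")
    } else {
        biotype <- unname(biotype[mcols(genes)$gene_id])
    }
    mcols(genes)$biotype <- biotype

    if (is.null(utr3))
        utr3 <- .deriveUTR3(exons, cds)
    if (is.null(chromLengths)) {
        mx <- vapply(split(end(exons), as.character(seqnames(exons))),
                     max, numeric(1))
        chromLengths <- mx + 1000
    }
    ann <- new("GenomeAnnotation", genes = genes, transcripts = transcripts,
               exons = exons, cds = cds, utr3 = utr3, introns = GRanges(),
               chromLengths = chromLengths)
    ann@introns <- deriveIntrons(ann)
    ann
}

## 3' UTR = exonic sequence strictly 3' of the stop codon, per transcript
.deriveUTR3 <- function(exons, cds) {
    empty <- GRanges()
    mcols(empty)$transcript_id <- character(0)
    if (!length(cds)) return(empty)
    e_tid <- mcols(exons)$transcript_id
    c_tid <- mcols(cds)$transcript_id
    e_sp <- split(seq_along(exons), e_tid)
    ## per coding transcript stop boundary
    neg_tx <- tapply(as.character(strand(cds)), c_tid,
                     function(s) s[1] == "-")
    bnd <- ifelse(neg_tx,
                  tapply(start(cds), c_tid, min),
                  tapply(end(cds), c_tid, max))
    chv <- character(0); sv <- integer(0); ev <- integer(0)
    stv <- character(0); tv <- character(0)
    for (tid in names(bnd)) {
        idx <- e_sp[[tid]]
        if (is.null(idx)) next
        s <- start(exons)[idx]; e <- end(exons)[idx]
        if (neg_tx[[tid]]) {
            e2 <- pmin(e, bnd[[tid]] - 1L)
            keep <- which(s <= e2)
            s_out <- s[keep]; e_out <- e2[keep]
        } else {
            s2 <- pmax(s, bnd[[tid]] + 1L)
            keep <- which(s2 <= e)
            s_out <- s2[keep]; e_out <- e[keep]
        }
        if (!length(keep)) next
        k <- length(keep)
        chv <- c(chv, rep(as.character(seqnames(exons))[idx[1]], k))
        stv <- c(stv, rep(as.character(strand(exons))[idx[1]], k))
        sv <- c(sv, as.integer(s_out)); ev <- c(ev, as.integer(e_out))
        tv <- c(tv, rep(tid, k))
    }
    if (!length(sv)) return(empty)
    out <- GRanges(chv, IRanges(sv, ev), strand = stv)
    mcols(out)$transcript_id <- tv
    out
}

## ---- GTF I/O ----------------------------------------------------------

#' Parse an Ensembl-dialect GTF into a GenomeAnnotation
#'
#' Coordinates are 1-based inclusive in the file and kept in the native
#' GRanges convention internally; BED-style export converts to 0-based
#' half-open at the boundary. Exon and CDS rows lacking a
#' \code{gene_id} or \code{transcript_id} attribute are a parse error
#' naming the offending line; feature types other than
#' exon/CDS/UTR/gene/transcript are skipped with a message.
#'
#' @param path GTF file path.
#' @param chromLengths optional named numeric of chromosome lengths.
#' @return a \code{\linkS4class{GenomeAnnotation}}
#' @export
parseGTF <- function(path, chromLengths = NULL) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    lineno <- which(body)
    bad_ncol <- lengths(fields) < 9
    if (any(bad_ncol))
        stop("malformed GTF line (fewer than 9 fields) at line ",
             lineno[which(bad_ncol)[1]])
    ftype <- vapply(fields, `[[`, character(1), 3L)
    attrs <- vapply(fields, `[[`, character(1), 9L)
    need <- ftype %in% c("exon", "CDS")
    miss <- need & (!grepl("gene_id", attrs) | !grepl("transcript_id", attrs))
    if (any(miss))
        stop("GTF line ", lineno[which(miss)[1]],
             " lacks a gene_id/transcript_id attribute")
    known <- c("gene", "transcript", "exon", "CDS",
               "five_prime_utr", "three_prime_utr", "UTR",
               "start_codon", "stop_codon")
    n_skip <- sum(!ftype %in% known)
    if (n_skip > 0)
        message("parseGTF: skipped ", n_skip, " line(s) of unknown feature type")

    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    exons <- granges(ex)
    mcols(exons)$transcript_id <- ex$transcript_id
    mcols(exons)$gene_id <- ex$gene_id
    cd <- gr[gr$type == "CDS"]
    cds <- granges(cd)
    mcols(cds)$transcript_id <- cd$transcript_id
    ut <- gr[gr$type == "three_prime_utr"]
    utr3 <- NULL
    if (length(ut)) {
        utr3 <- granges(ut)
        mcols(utr3)$transcript_id <- ut$transcript_id
    }
    biotype <- NULL
    gg <- gr[gr$type == "gene"]
    if (length(gg) && !is.null(gg$gene_biotype)) {
        biotype <- gg$gene_biotype
        names(biotype) <- gg$gene_id
    }
    makeGenomeAnnotation(exons, cds = cds, utr3 = utr3,
                         biotype = biotype, chromLengths = chromLengths)
}

#' Write a GenomeAnnotation as Ensembl-dialect GTF
#'
#' Emits gene, transcript, exon and CDS rows; 1-based inclusive
#' coordinates per the GTF convention. \code{parseGTF(writeGTF(ann))}
#' preserves all coordinates exactly.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGTF <- function(ann, path) {
    fmt <- function(gr, type, attr) {
        if (!length(gr)) return(character(0))
        sprintf("%s\tIRkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(seqnames(gr)), type, start(gr), end(gr),
                as.character(strand(gr)), attr)
    }
    g <- geneRanges(ann)
    tx <- txRanges(ann)
    ex <- exonRanges(ann)
    cd <- cdsRanges(ann)
    tx2g <- structure(mcols(tx)$gene_id, names = mcols(tx)$transcript_id)
    lines <- c(
        fmt(g, "gene", sprintf('gene_id "%s"; gene_biotype "%s";',
                               mcols(g)$gene_id, mcols(g)$biotype)),
        fmt(tx, "transcript", sprintf('gene_id "%s"; transcript_id "%s";',
                                      mcols(tx)$gene_id,
                                      mcols(tx)$transcript_id)),
        fmt(ex, "exon", sprintf('gene_id "%s"; transcript_id "%s";',
                                mcols(ex)$gene_id, mcols(ex)$transcript_id)),
        fmt(cd, "CDS", sprintf('gene_id "%s"; transcript_id "%s";',
                               unname(tx2g[mcols(cd)$transcript_id]),
                               mcols(cd)$transcript_id)))
    writeLines(lines, path)
    invisible(path)
}

## ---- introns ----------------------------------------------------------

#' Derive introns for one transcript
#'
#' Introns are the gaps between consecutive exons. The index counts
#' from the transcript's 5' end (reverse genomic order on the minus
#' strand); the phase of intron i is the number of bases of the
#' interrupted codon already emitted upstream, i.e. (cumulative CDS
#' length 5' of the intron) mod 3, and is NA for transcripts without a
#' CDS or for introns outside the CDS.
#'
#' @param exons GRanges of one transcript's exons (same strand).
#' @param cds optional GRanges of that transcript's CDS segments.
#' @return GRanges of introns with mcols \code{index},
#'   \code{n_introns}, \code{phase}
#' @export
deriveTranscriptIntrons <- function(exons, cds = GRanges()) {
    exons <- exons[order(start(exons))]
    if (length(exons) >= 2 &&
        any(start(exons)[-1] <= end(exons)[-length(exons)]))
        stop("overlapping exons")
    n <- length(exons) - 1L
    if (n < 1L) {
        out <- GRanges()
        mcols(out)$index <- integer(0)
        mcols(out)$n_introns <- integer(0)
        mcols(out)$phase <- integer(0)
        return(out)
    }
    strnd <- as.character(strand(exons)[1])
    s <- end(exons)[-length(exons)] + 1L
    e <- start(exons)[-1] - 1L
    out <- GRanges(seqnames(exons)[1], IRanges(s, e), strand = strnd)
    mcols(out)$index <- if (strnd == "-") rev(seq_len(n)) else seq_len(n)
    mcols(out)$n_introns <- n
    mcols(out)$phase <- .intronPhases(s, e, strnd,
                                      start(cds), end(cds))
    out
}

## phase of each intron given CDS segment coordinates (same chrom)
.intronPhases <- function(int_start, int_end, strnd, cds_start, cds_end) {
    n <- length(int_start)
    phase <- rep(NA_integer_, n)
    if (!length(cds_start)) return(phase)
    cmin <- min(cds_start); cmax <- max(cds_end)
    for (i in seq_len(n)) {
        inside <- int_start[i] > cmin && int_end[i] < cmax
        if (!inside) next
        b <- if (strnd == "-") {
            sum(pmax(0L, cds_end - pmax(cds_start, int_end[i] + 1L) + 1L))
        } else {
            sum(pmax(0L, pmin(cds_end, int_start[i] - 1L) - cds_start + 1L))
        }
        phase[i] <- as.integer(b %% 3L)
    }
    phase
}

#' Derive all introns of an annotation
#'
#' Gaps between consecutive exons of every transcript, with stable IDs
#' (\code{<transcript_id>.I<index>}), 5'-based index, phase, and
#' 3'-UTR flags via \code{\link{flagUtr3Introns}}.
#'
#' @param ann a \code{GenomeAnnotation}
#' @return GRanges of introns
#' @export
deriveIntrons <- function(ann) {
    ex <- ann@exons   # sorted by (transcript, start)
    empty <- GRanges()
    for (f in c("intron_id", "gene_id", "transcript_id"))
        mcols(empty)[[f]] <- character(0)
    for (f in c("index", "n_introns", "phase"))
        mcols(empty)[[f]] <- integer(0)
    mcols(empty)$is_utr3 <- logical(0)
    n <- length(ex)
    if (n < 2) return(empty)
    txid <- mcols(ex)$transcript_id
    same <- txid[-1] == txid[-n]
    if (!any(same)) return(empty)
    li <- which(same)          # left exon row of each intron
    s <- end(ex)[li] + 1L
    e <- start(ex)[li + 1L] - 1L
    tid <- txid[li]
    gid <- mcols(ex)$gene_id[li]
    strnd <- as.character(strand(ex))[li]
    chrom <- as.character(seqnames(ex))[li]
    ## genomic ordinal within transcript -> 5'-based index
    ord <- stats::ave(seq_along(li), tid, FUN = seq_along)
    ntr <- stats::ave(seq_along(li), tid, FUN = length)
    idx <- ifelse(strnd == "-", ntr - ord + 1L, as.integer(ord))

    ## phases per coding transcript
    phase <- rep(NA_integer_, length(li))
    cd <- ann@cds
    if (length(cd)) {
        cd_sp <- split(seq_along(cd), mcols(cd)$transcript_id)
        in_sp <- split(seq_along(li), tid)
        for (t in intersect(names(cd_sp), names(in_sp))) {
            ii <- in_sp[[t]]; ci <- cd_sp[[t]]
            phase[ii] <- .intronPhases(s[ii], e[ii], strnd[ii][1],
                                       start(cd)[ci], end(cd)[ci])
        }
    }
    out <- GRanges(chrom, IRanges(s, e), strand = strnd)
    mcols(out)$intron_id <- sprintf("%s.I%d", tid, idx)
    mcols(out)$gene_id <- gid
    mcols(out)$transcript_id <- tid
    mcols(out)$index <- idx
    mcols(out)$n_introns <- as.integer(ntr)
    mcols(out)$phase <- phase
    mcols(out)$is_utr3 <- FALSE
    tmp <- ann
    tmp@introns <- out
    mcols(out)$is_utr3 <- mcols(out)$intron_id %in% flagUtr3Introns(tmp)
    out
}

#' Flag introns located in a 3' UTR
#'
#' An intron is flagged when its interval lies entirely 3' of the stop
#' codon in at least one transcript of its gene; introns spanning the
#' stop codon are not flagged. Genes without a CDS yield no flags.
#'
#' @param ann a \code{GenomeAnnotation}
#' @return character vector of flagged intron IDs
#' @export
flagUtr3Introns <- function(ann) {
    intr <- ann@introns
    cd <- ann@cds
    if (!length(intr) || !length(cd)) return(character(0))
    tx <- ann@transcripts
    tx2g <- structure(mcols(tx)$gene_id, names = mcols(tx)$transcript_id)
    c_tid <- mcols(cd)$transcript_id
    neg_tx <- tapply(as.character(strand(cd)), c_tid,
                     function(x) x[1] == "-")
    bnd <- ifelse(neg_tx,
                  tapply(start(cd), c_tid, min),
                  tapply(end(cd), c_tid, max))
    bnd_gene <- unname(tx2g[names(bnd)])
    gi <- mcols(intr)$gene_id
    flagged <- logical(length(intr))
    for (k in seq_along(bnd)) {
        idx <- which(gi == bnd_gene[k])
        if (!length(idx)) next
        hit <- if (neg_tx[k]) end(intr)[idx] < bnd[k]
               else start(intr)[idx] > bnd[k]
        flagged[idx] <- flagged[idx] | hit
    }
    mcols(intr)$intron_id[flagged]
}

#' Merged exonic length in kbp
#'
#' Length of the union of exon intervals, per gene, in kbp; overlapping
#' exons from different transcripts are counted once.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param genes optional character vector restricting to those gene IDs
#' @return named numeric, kbp of merged exon sequence per gene
#' @export
mergedExonicKbp <- function(ann, genes = NULL) {
    ex <- ann@exons
    if (!is.null(genes)) ex <- ex[mcols(ex)$gene_id %in% genes]
    sp <- split(ranges(ex), mcols(ex)$gene_id)
    vapply(sp, function(r) sum(width(IRanges::reduce(r))) / 1000,
           numeric(1))
}

#' Export introns as BED6
#'
#' 0-based half-open coordinates per the BED convention; score is the
#' IR ratio x 1000 when calls are supplied, 0 otherwise.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param path output path
#' @param calls optional IR call table (see \code{\link{irCalls}}) with
#'   columns \code{intron_id}, \code{ir_ratio}
#' @return \code{path}, invisibly
#' @export
intronsAsBED <- function(ann, path, calls = NULL) {
    intr <- ann@introns
    score <- rep(0L, length(intr))
    if (!is.null(calls)) {
        m <- match(mcols(intr)$intron_id, calls$intron_id)
        score <- ifelse(is.na(m), 0L,
                        as.integer(round(calls$ir_ratio[m] * 1000)))
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     as.character(seqnames(intr)), start(intr) - 1L,
                     end(intr), mcols(intr)$intron_id, score,
                     as.character(strand(intr)))
    writeLines(lines, path)
    invisible(path)
}

## representative transcript per gene for gene-level intron summaries:
## most exons, ties -> longest spliced length, then lexicographic ID
.representativeTx <- function(ann) {
    ex <- ann@exons
    txid <- mcols(ex)$transcript_id
    n_ex <- lengths(split(seq_along(ex), txid))
    len <- vapply(split(width(ex), txid), sum, numeric(1))
    tx <- mcols(ann@transcripts)
    df <- data.frame(transcript_id = names(n_ex),
                     gene_id = tx$gene_id[match(names(n_ex),
                                                tx$transcript_id)],
                     n_exons = as.integer(n_ex), len = len[names(n_ex)])
    df <- df[order(df$gene_id, -df$n_exons, -df$len, df$transcript_id), ]
    df <- df[!duplicated(df$gene_id), ]
    structure(df$transcript_id, names = df$gene_id)
}
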