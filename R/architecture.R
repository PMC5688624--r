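#' @importFrom stats fisher.test
NULL

#' Classify adjacent gene pairs by orientation
#'
#' Genes are ordered by TSS per chromosome; each consecutive pair is
#' classified: HH (head-to-head, strands -/+ with TSSs adjacent and
#' facing away -- the bidirectional-promoter configuration), TT
#' (tail-to-tail, +/-), or TH (same strand). Distance: HH = TSS to
#' TSS, TT = transcript end to transcript end, TH = upstream gene's
#' end to downstream gene's TSS; overlapping genes get distance 0.
#' Gene-level TSS/TES are the outermost transcript boundaries.
#'
#' @param ann a \code{GenomeAnnotation}
#' @return data.frame gene_a/gene_b/orientation/distance
#' @export
classifyAdjacentPairs <- function(ann) {
    g <- geneRanges(ann)
    tss <- ifelse(as.character(strand(g)) == "-", end(g), start(g))
    tes <- ifelse(as.character(strand(g)) == "-", start(g), end(g))
    df <- data.frame(gene_id = mcols(g)$gene_id,
                     chrom = as.character(seqnames(g)),
                     strand = as.character(strand(g)),
                     start = start(g), end = end(g),
                     tss = tss, tes = tes, stringsAsFactors = FALSE)
    out <- list()
    for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, , drop = FALSE]
        d <- d[order(d$tss, d$gene_id), , drop = FALSE]
        if (nrow(d) < 2) next
        for (i in seq_len(nrow(d) - 1)) {
            a <- d[i, ]; b <- d[i + 1, ]
            orient <- if (a$strand == b$strand) "TH"
                      else if (a$strand == "-" && b$strand == "+") "HH"
                      else "TT"
            overlap <- a$end >= b$start && b$end >= a$start
            dist <- if (overlap) 0 else switch(orient,
                HH = abs(b$tss - a$tss),
                TT = abs(b$tes - a$tes),
                TH = if (a$strand == "+") abs(b$tss - a$tes)
                     else abs(a$tss - b$tes))
            out[[length(out) + 1L]] <- data.frame(
                gene_a = a$gene_id, gene_b = b$gene_id,
                orientation = orient, distance = dist,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          orientation = character(0),
                          distance = numeric(0)))
    do.call(rbind, out)
}

#' Fraction of bidirectional (head-to-head, close) pairs
#'
#' Fraction of pairs whose both members are in \code{subset} (all pairs
#' when NULL) that are head-to-head with distance at most
#' \code{cutoff} -- the putatively co-regulated, shared-promoter
#' configuration.
#'
#' @param pairs output of \code{\link{classifyAdjacentPairs}}
#' @param subset optional character vector of gene IDs
#' @param cutoff distance cutoff in bp
#' @return fraction in [0, 1] (NA when no pairs qualify)
#' @export
bidirectionalFraction <- function(pairs, subset = NULL, cutoff = 1000) {
    if (!is.null(subset))
        pairs <- pairs[pairs$gene_a %in% subset &
                       pairs$gene_b %in% subset, , drop = FALSE]
    if (!nrow(pairs)) return(NA_real_)
    mean(pairs$orientation == "HH" & pairs$distance <= cutoff)
}

#' Test bidirectional-promoter enrichment in IR genes
#'
#' Fisher's exact test comparing the bidirectional fraction among
#' both-IR pairs vs other pairs.
#'
#' @param pairs output of \code{\link{classifyAdjacentPairs}}
#' @param ir_genes character vector of IR gene IDs
#' @param cutoff distance cutoff in bp
#' @return list(fraction_ir, fraction_other, p_value)
#' @export
bidirectionalEnrichment <- function(pairs, ir_genes, cutoff = 1000) {
    both_ir <- pairs$gene_a %in% ir_genes & pairs$gene_b %in% ir_genes
    hh <- pairs$orientation == "HH" & pairs$distance <= cutoff
    tab <- table(factor(both_ir, c(TRUE, FALSE)),
                 factor(hh, c(TRUE, FALSE)))
    list(fraction_ir = if (any(both_ir)) mean(hh[both_ir]) else NA_real_,
         fraction_other = if (any(!both_ir)) mean(hh[!both_ir])
                          else NA_real_,
         p_value = fisher.test(tab)$p.value)
}

#' Histogram of retained-intron counts per IR gene
#'
#' @param gene_ir gene table from \code{\link{aggregateGeneIR}}
#' @return integer vector: genes with k = 1, 2, ... retained introns
#' @export
retainedCountHistogram <- function(gene_ir) {
    k <- gene_ir$n_retained[gene_ir$is_ir_gene]
    if (!length(k)) return(integer(0))
    tabulate(k, nbins = max(k))
}

#' Retained introns per kbp of exon sequence
#'
#' @param n_retained_introns total retained introns
#' @param exonic_kbp merged exonic length in kbp
#' @return density (introns per kbp)
#' @export
retainedDensity <- function(n_retained_introns, exonic_kbp) {
    if (exonic_kbp <= 0) stop("exonic_kbp must be positive")
    n_retained_introns / exonic_kbp
}

#' Intron-number distributions for IR vs other expressed genes
#'
#' Transcripts with more introns are more prone to IR; this compares
#' the per-gene intron counts of IR genes against other expressed
#' genes (representative transcript per gene) with a rank test.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param gene_ir gene table from \code{\link{aggregateGeneIR}}
#' @return list(counts_ir, counts_other, mean_ir, mean_other, p_value,
#'   prop_ir, prop_other)
#' @export
intronCountVsIR <- function(ann, gene_ir) {
    rep_tx <- .representativeTx(ann)
    ex <- exonRanges(ann)
    n_ex <- lengths(split(seq_along(ex), mcols(ex)$transcript_id))
    n_intr <- pmax(0L, as.integer(n_ex[rep_tx]) - 1L)
    names(n_intr) <- names(rep_tx)
    ir <- gene_ir$gene_id[gene_ir$is_ir_gene]
    other <- gene_ir$gene_id[gene_ir$is_expressed & !gene_ir$is_ir_gene]
    ci <- n_intr[names(n_intr) %in% ir]
    co <- n_intr[names(n_intr) %in% other]
    p <- if (length(ci) && length(co))
        wilcox.test(ci, co, exact = FALSE)$p.value else NA_real_
    mx <- max(c(ci, co, 1))
    list(counts_ir = ci, counts_other = co,
         mean_ir = mean(ci), mean_other = mean(co), p_value = p,
         prop_ir = tabulate(ci + 1L, mx + 1L) / max(1, length(ci)),
         prop_other = tabulate(co + 1L, mx + 1L) / max(1, length(co)))
}
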