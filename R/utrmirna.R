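#' @importFrom stats phyper
NULL

#' 3' UTR length per gene
#'
#' Per gene, the longest annotated 3' UTR across its transcripts, as
#' spliced length (3'-UTR introns excluded). With
#' \code{include_retained_introns}, the lengths of retained 3'-UTR
#' introns are added to their transcript's UTR.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param include_retained_introns logical
#' @param retained_ids intron IDs considered retained (required with
#'   \code{include_retained_introns})
#' @return named numeric, nt per gene (genes without UTR omitted)
#' @export
utr3LengthPerGene <- function(ann, include_retained_introns = FALSE,
                              retained_ids = NULL) {
    u <- utr3Ranges(ann)
    if (!length(u)) return(setNames(numeric(0), character(0)))
    tx <- txRanges(ann)
    tx2g <- structure(mcols(tx)$gene_id, names = mcols(tx)$transcript_id)
    per_tx <- vapply(split(width(u), mcols(u)$transcript_id), sum,
                     numeric(1))
    if (include_retained_introns) {
        if (is.null(retained_ids))
            stop("retained_ids needed with include_retained_introns")
        intr <- introns(ann)
        sel <- mcols(intr)$is_utr3 &
               mcols(intr)$intron_id %in% retained_ids
        if (any(sel)) {
            add <- vapply(split(width(intr)[sel],
                                mcols(intr)$transcript_id[sel]),
                          sum, numeric(1))
            common <- intersect(names(per_tx), names(add))
            per_tx[common] <- per_tx[common] + add[common]
        }
    }
    g <- unname(tx2g[names(per_tx)])
    vapply(split(per_tx, g), max, numeric(1))
}

#' Scan 3' UTRs for miRNA seed sites
#'
#' A seed site is the exact reverse complement of miRNA offset
#' positions 2-8 (a 7-mer; strict Watson-Crick, no G:U wobble). An
#' optional duplex-energy hook filters matches: it receives the miRNA
#' and the UTR site sequence and must return an energy (kcal/mol);
#' matches above \code{energy_threshold} are dropped.
#'
#' @param utrs named character (or DNAStringSet) of 3' UTR sequences,
#'   sense strand
#' @param mirnas named character of miRNA sequences (RNA or DNA
#'   alphabet)
#' @param energy_fun optional function(mirna, site) -> kcal/mol
#' @param energy_threshold kcal/mol cutoff used with \code{energy_fun}
#' @return data.frame mirna_id/gene_id/position (1-based offset in the
#'   UTR)
#' @export
scanSeedSites <- function(utrs, mirnas, energy_fun = NULL,
                          energy_threshold = -14) {
    nm <- names(utrs)
    utrs <- toupper(as.character(utrs))   # as.character drops names
    names(utrs) <- nm
    out <- list()
    for (mid in names(mirnas)) {
        seed <- chartr("U", "T", toupper(substr(mirnas[[mid]], 2, 8)))
        target <- as.character(reverseComplement(DNAString(seed)))
        for (gid in names(utrs)) {
            hits <- gregexpr(target, utrs[[gid]], fixed = TRUE)[[1]]
            if (hits[1] == -1) next
            for (h in as.integer(hits)) {
                if (!is.null(energy_fun)) {
                    e <- energy_fun(mirnas[[mid]],
                                    substr(utrs[[gid]], h, h + 6))
                    if (e > energy_threshold) next
                }
                out[[length(out) + 1L]] <- data.frame(
                    mirna_id = mid, gene_id = gid, position = h,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(mirna_id = character(0), gene_id = character(0),
                          position = integer(0)))
    do.call(rbind, out)
}

#' Compare per-gene seed-site counts between groups
#'
#' Percent increase = (median_ir - median_other) / median_other x 100,
#' with an unpaired two-sided Wilcoxon test.
#'
#' @param counts_ir,counts_other numeric vectors of per-gene site
#'   counts
#' @return list(median_ir, median_other, percent_increase, wilcoxon_p)
#' @export
siteCountComparison <- function(counts_ir, counts_other) {
    m1 <- median(counts_ir); m0 <- median(counts_other)
    list(median_ir = m1, median_other = m0,
         percent_increase = if (m0 > 0) (m1 - m0) / m0 * 100
                            else NA_real_,
         wilcoxon_p = wilcox.test(counts_ir, counts_other,
                                  exact = FALSE)$p.value)
}

#' k-mer word enrichment in foreground vs background UTRs
#'
#' Presence/absence per sequence: for each of the 4^k words, count
#' sequences containing at least one occurrence, then compute the
#' upper-tail cumulative hypergeometric p value of the foreground
#' count given the background, Bonferroni-corrected over all words
#' (E = min(1, p * 4^k)). The canonical polyadenylation signal AATAAA
#' is reported but flagged.
#'
#' @param fg_utrs,bg_utrs named character or DNAStringSet; foreground
#'   must be a subset of the background sequence set
#' @param k word length
#' @param e_threshold significance threshold on the E-value
#' @param flag_words words flagged in the output (not excluded)
#' @return data.frame word/fg_with/fg_total/bg_with/bg_total/p/e_value/
#'   significant/flagged, sorted by E-value
#' @export
wordEnrichment <- function(fg_utrs, bg_utrs, k = 6, e_threshold = 0.01,
                           flag_words = "AATAAA") {
    if (!length(fg_utrs)) stop("empty foreground")
    fg <- Biostrings::DNAStringSet(
        chartr("U", "T", toupper(as.character(fg_utrs))))
    bg <- Biostrings::DNAStringSet(
        chartr("U", "T", toupper(as.character(bg_utrs))))
    fg_pres <- Biostrings::oligonucleotideFrequency(fg, k) > 0
    bg_pres <- Biostrings::oligonucleotideFrequency(bg, k) > 0
    fg_with <- colSums(fg_pres)
    bg_with <- colSums(bg_pres)
    n_fg <- length(fg); n_bg <- length(bg)
    ## upper tail: P(X >= fg_with), X ~ Hypergeom(bg_with, bg-bg_with, n_fg)
    p <- phyper(fg_with - 1, bg_with, n_bg - bg_with, n_fg,
                lower.tail = FALSE)
    e <- pmin(1, p * 4^k)
    out <- data.frame(word = names(fg_with),
                      fg_with = as.integer(fg_with), fg_total = n_fg,
                      bg_with = as.integer(bg_with), bg_total = n_bg,
                      p = unname(p), e_value = unname(e),
                      stringsAsFactors = FALSE)
    out$significant <- out$e_value < e_threshold
    out$flagged <- out$word %in% flag_words
    out[order(out$e_value, out$p, out$word), ]
}

#' Seed-site density in retained vs non-retained intron sequences
#'
#' Sites per kb per group, with a rank test on the per-sequence
#' densities.
#'
#' @param retained_seqs,other_seqs named character intron sequences
#' @param mirnas named character miRNA panel
#' @return list(density_retained, density_other, per_seq_retained,
#'   per_seq_other, p_value)
#' @export
intronSiteDensity <- function(retained_seqs, other_seqs, mirnas) {
    dens <- function(seqs) {
        if (!length(seqs)) return(numeric(0))
        hits <- scanSeedSites(seqs, mirnas)
        n <- table(factor(hits$gene_id, levels = names(seqs)))
        as.numeric(n) / (nchar(seqs) / 1000)
    }
    d1 <- dens(retained_seqs); d0 <- dens(other_seqs)
    p <- if (length(d1) && length(d0))
        wilcox.test(d1, d0, exact = FALSE)$p.value else NA_real_
    list(density_retained = mean(d1), density_other = mean(d0),
         per_seq_retained = d1, per_seq_other = d0, p_value = p)
}

#' Spliced 3' UTR sequences per gene
#'
#' Sense-strand UTR sequence of each gene's longest-UTR transcript,
#' with 3'-UTR introns spliced out.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param genome \code{DNAStringSet}
#' @return named character, one sequence per gene with an annotated UTR
#' @export
utr3Sequences <- function(ann, genome) {
    u <- utr3Ranges(ann)
    if (!length(u)) return(setNames(character(0), character(0)))
    tx <- txRanges(ann)
    tx2g <- structure(mcols(tx)$gene_id, names = mcols(tx)$transcript_id)
    lens <- vapply(split(width(u), mcols(u)$transcript_id), sum,
                   numeric(1))
    best <- tapply(names(lens), unname(tx2g[names(lens)]),
                   function(t) t[which.max(lens[t])])
    out <- vapply(as.character(best), function(tid) {
        seg <- u[mcols(u)$transcript_id == tid]
        seg <- seg[order(start(seg))]
        ch <- as.character(seqnames(seg)[1])
        s <- paste(vapply(seq_along(seg), function(i)
            as.character(Biostrings::subseq(genome[[ch]], start(seg)[i],
                                            end(seg)[i])), character(1)),
            collapse = "")
        if (as.character(strand(seg)[1]) == "-")
            s <- as.character(reverseComplement(DNAString(s)))
        s
    }, character(1))
    names(out) <- names(best)
    out
}
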