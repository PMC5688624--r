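#' @importFrom stats wilcox.test chisq.test ks.test quantile
NULL

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); ambiguous bases are excluded from both
#' numerator and denominator.
#'
#' @param seq character or DNAString(Set) element coercible to character
#' @return GC fraction in [0, 1]
#' @export
gcContent <- function(seq) {
    s <- toupper(as.character(seq))
    if (!nzchar(s)) stop("empty sequence")
    v <- strsplit(s, "")[[1]]
    gc <- sum(v %in% c("G", "C"))
    acgt <- sum(v %in% c("A", "C", "G", "T"))
    if (acgt == 0) return(NA_real_)
    gc / acgt
}

#' Premature-termination-codon density
#'
#' Counts in-frame stop codons (TAA, TAG, TGA) in the reading frame
#' continued from the upstream exon and divides by intron length in
#' kb. The first complete codon of the intron starts at offset
#' \code{(3 - phase) \%\% 3} (phase = bases of the interrupted codon
#' already emitted upstream).
#'
#' @param intron_seq intron sequence, sense strand of the mRNA
#' @param upstream_phase 0, 1 or 2; NA yields NA density
#' @return stops per kb, or NA when the phase is unknown
#' @export
ptcDensity <- function(intron_seq, upstream_phase) {
    if (is.na(upstream_phase)) return(NA_real_)
    s <- toupper(as.character(intron_seq))
    n <- nchar(s)
    off <- (3 - upstream_phase) %% 3
    starts <- seq(off + 1, n - 2, by = 3)
    if (length(starts) == 0 || starts[1] > n - 2) return(0)
    codons <- substring(s, starts, starts + 2)
    sum(codons %in% c("TAA", "TAG", "TGA")) / (n / 1000)
}

#' Compare a feature between retained and other introns
#'
#' Two-sided rank test (Mann-Whitney U, i.e. unpaired Wilcoxon) plus
#' medians, means and the fold difference FD = mean(other) /
#' mean(retained).
#'
#' @param values_retained,values_other numeric vectors
#' @param test "mann_whitney" or "wilcoxon" (both the unpaired
#'   rank-sum test)
#' @return list(p_value, median_retained, median_other, mean_retained,
#'   mean_other, fold_difference)
#' @export
compareFeature <- function(values_retained, values_other,
                           test = c("mann_whitney", "wilcoxon")) {
    test <- match.arg(test)
    if (!length(values_retained) || !length(values_other))
        stop("both groups must be non-empty")
    ## exact null distribution for small untied samples, normal
    ## approximation otherwise (wilcox.test's own switch)
    p <- suppressWarnings(
        wilcox.test(values_retained, values_other)$p.value)
    list(p_value = p,
         median_retained = median(values_retained),
         median_other = median(values_other),
         mean_retained = mean(values_retained),
         mean_other = mean(values_other),
         fold_difference = mean(values_other) / mean(values_retained))
}

#' Binned intron length vs IR-ratio trend
#'
#' Equal-count bins over the IR ratio; median log10 length per bin with
#' a seeded bootstrap 95% band. A deterministic descriptive substitute
#' for a smoothing-spline fit.
#'
#' @param ir_ratio,length numeric vectors (measurable introns)
#' @param n_bins number of equal-count bins
#' @param B bootstrap replicates
#' @param seed RNG seed for the bootstrap
#' @return data.frame bin_mid/median_log10_length/lo/hi
#' @export
lengthIRTrend <- function(ir_ratio, length, n_bins = 10, B = 200,
                          seed = 1) {
    stopifnot(length(ir_ratio) == length(length))
    if (length(ir_ratio) < n_bins)
        stop("need at least n_bins introns")
    o <- order(ir_ratio)
    ir <- ir_ratio[o]; len <- log10(length[o])
    bin <- ceiling(seq_along(ir) / length(ir) * n_bins)
    set.seed(seed)
    out <- lapply(split(seq_along(ir), bin), function(idx) {
        boots <- vapply(seq_len(B), function(b)
            median(len[sample(idx, length(idx), replace = TRUE)]),
            numeric(1))
        data.frame(bin_mid = median(ir[idx]),
                   median_log10_length = median(len[idx]),
                   lo = unname(quantile(boots, 0.025)),
                   hi = unname(quantile(boots, 0.975)))
    })
    do.call(rbind, out)
}

#' Intron phase distribution per group
#'
#' Proportions over phases 0/1/2 for retained vs other introns, with a
#' chi-square test of homogeneity.
#'
#' @param phase integer vector (NA dropped)
#' @param retained logical vector, same length
#' @return list(prop_retained, prop_other, p_value)
#' @export
phaseDistribution <- function(phase, retained) {
    keep <- !is.na(phase)
    phase <- factor(phase[keep], levels = 0:2)
    retained <- retained[keep]
    tab <- table(retained, phase)
    props <- prop.table(tab, margin = 1)
    p <- if (nrow(tab) == 2 && all(rowSums(tab) > 0))
        suppressWarnings(chisq.test(tab)$p.value) else NA_real_
    list(prop_retained = if ("TRUE" %in% rownames(props))
             props["TRUE", ] else setNames(rep(NA_real_, 3), 0:2),
         prop_other = if ("FALSE" %in% rownames(props))
             props["FALSE", ] else setNames(rep(NA_real_, 3), 0:2),
         p_value = p)
}

#' Relative intron position
#'
#' Position of an intron within its transcript, index divided by the
#' number of introns; values in (0, 1], 1 = last (3'-most) intron.
#' With a \code{retained} flag, compares the two groups' positional
#' densities with a Kolmogorov-Smirnov statistic. When a \code{group}
#' vector (transcript or gene IDs) is supplied, significance comes
#' from a within-group permutation null that shuffles which introns
#' are retained while preserving each group's retained count -- the
#' appropriate null, since retained introns concentrate in genes with
#' few introns and their relative-position grid therefore differs
#' structurally from the rest even without any positional bias.
#' Without \code{group}, the asymptotic two-sample KS p is returned.
#'
#' @param index,n_introns integer vectors
#' @param retained optional logical vector
#' @param group optional transcript/gene ID per intron
#' @param n_perm permutation replicates
#' @param seed RNG seed for the permutation null
#' @return list(rel_position, and when grouped: ks_p, mean_retained,
#'   mean_other)
#' @export
relativePositionDensity <- function(index, n_introns, retained = NULL,
                                    group = NULL, n_perm = 500,
                                    seed = 1) {
    rel <- index / n_introns
    out <- list(rel_position = rel)
    if (is.null(retained)) return(out)
    out$mean_retained <- mean(rel[retained])
    out$mean_other <- mean(rel[!retained])
    ksD <- function(flag) unname(suppressWarnings(
        ks.test(rel[flag], rel[!flag])$statistic))
    if (is.null(group)) {
        out$ks_p <- suppressWarnings(
            ks.test(rel[retained], rel[!retained]))$p.value
    } else {
        obs <- ksD(retained)
        sp <- split(seq_along(rel), group)
        k_per <- vapply(sp, function(ii) sum(retained[ii]), integer(1))
        sp <- sp[k_per > 0]
        k_per <- k_per[k_per > 0]
        set.seed(seed)
        perm <- vapply(seq_len(n_perm), function(b) {
            flag <- logical(length(rel))
            for (j in seq_along(sp)) {
                ii <- sp[[j]]
                flag[ii[sample.int(length(ii), k_per[j])]] <- TRUE
            }
            ksD(flag)
        }, numeric(1))
        out$ks_stat <- obs
        out$ks_p <- (1 + sum(perm >= obs)) / (n_perm + 1)
    }
    out
}

#' Intron feature table
#'
#' One row per intron: length, GC, phase, PTC density, relative
#' position, 3'-UTR flag, plus the retained flag when a call table is
#' supplied.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param genome \code{DNAStringSet} of the chromosomes
#' @param calls optional filtered IR call table
#' @return data.frame
#' @export
intronFeatureTable <- function(ann, genome, calls = NULL) {
    intr <- introns(ann)
    seqs <- intronSequences(ann, genome)
    df <- data.frame(
        intron_id = mcols(intr)$intron_id,
        gene_id = mcols(intr)$gene_id,
        length = width(intr),
        gc = vapply(as.character(seqs), gcContent, numeric(1)),
        phase = mcols(intr)$phase,
        rel_position = mcols(intr)$index / mcols(intr)$n_introns,
        is_utr3 = mcols(intr)$is_utr3,
        stringsAsFactors = FALSE)
    df$ptc_density <- mapply(ptcDensity, as.character(seqs), df$phase)
    if (!is.null(calls)) {
        m <- match(df$intron_id, calls$intron_id)
        df$ir_ratio <- calls$ir_ratio[m]
        df$category <- calls$category[m]
        df$is_retained <- !is.na(m) & calls$category[m] == "retained"
    }
    rownames(df) <- NULL
    df
}

#' Strand-aware intron sequences
#'
#' @param ann a \code{GenomeAnnotation}
#' @param genome \code{DNAStringSet}
#' @return \code{DNAStringSet}, sense strand of the mRNA
#' @export
intronSequences <- function(ann, genome) {
    intr <- introns(ann)
    out <- DNAStringSet(vapply(seq_along(intr), function(i) {
        ch <- as.character(seqnames(intr)[i])
        s <- as.character(Biostrings::subseq(genome[[ch]],
                                             start(intr)[i], end(intr)[i]))
        if (as.character(strand(intr)[i]) == "-")
            s <- as.character(reverseComplement(DNAString(s)))
        s
    }, character(1)))
    names(out) <- mcols(intr)$intron_id
    out
}
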