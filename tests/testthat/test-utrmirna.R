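## two-isoform annotation with UTRs of 200 and 500 nt
.twoIsoformAnn <- function() {
    exons <- GRanges("chr1",
        IRanges(c(101, 1001,  101, 1001), c(700, 1600, 700, 1900)),
        strand = "+")
    mcols(exons)$transcript_id <- c("t1", "t1", "t2", "t2")
    mcols(exons)$gene_id <- "g1"
    ## both isoforms stop at 1400: t1 UTR = [1401,1600] (200 nt),
    ## t2 UTR = [1401,1900] (500 nt)
    cds <- GRanges("chr1", IRanges(c(131, 1001, 131, 1001),
                                   c(700, 1400, 700, 1400)),
                   strand = "+")
    mcols(cds)$transcript_id <- c("t1", "t1", "t2", "t2")
    makeGenomeAnnotation(exons, chromLengths = c(chr1 = 3000), cds = cds)
}

test_that("per-gene UTR length is the longest isoform's spliced UTR", {
    ann <- .twoIsoformAnn()
    u <- utr3LengthPerGene(ann)
    expect_equal(unname(u["g1"]), 500)
    ## genes without UTR annotation are missing from the result
    ann0 <- tinyAnnotation()
    ann0@utr3 <- ann0@utr3[0]
    expect_length(utr3LengthPerGene(ann0), 0)
})

test_that("retained 3'-UTR introns extend the UTR when requested", {
    cfg <- simConfig(n_genes = 80, seed = 71, utr3_intron_rate = 0.5)
    sim <- simulateAnnotation(cfg)
    intr <- introns(sim$annotation)
    utr_introns <- mcols(intr)$intron_id[mcols(intr)$is_utr3]
    u0 <- utr3LengthPerGene(sim$annotation)
    u1 <- utr3LengthPerGene(sim$annotation,
                            include_retained_introns = TRUE,
                            retained_ids = utr_introns)
    grown <- unique(mcols(intr)$gene_id[mcols(intr)$is_utr3])
    expect_true(all(u1[grown] > u0[grown]))
    same <- setdiff(names(u0), grown)
    expect_equal(u1[same], u0[same])
})

test_that("seed matching is the exact reverse complement of positions 2-8", {
    ## miRNA positions 2-8 = AGCUUAC -> site GTAAGCT
    mir <- c(m1 = "UAGCUUACGGGGGGGGGGGGGG")
    utr <- c(gA = "CCCCGTAAGCTCCCC", gB = "AAAAAAAAAAAA")
    hits <- scanSeedSites(utr, mir)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$gene_id, "gA")
    expect_equal(hits$position, 5L)
    ## the matched 7-mer is the reverse complement of the seed
    expect_equal(substr(utr[["gA"]], 5, 11), "GTAAGCT")
    ## no complements -> empty
    expect_equal(nrow(scanSeedSites(c(g = "TTTTTTTT"), mir)), 0)
})

test_that("the energy hook filters matches", {
    mir <- c(m1 = "UAGCUUACGGGGGGGGGGGGGG")
    utr <- c(gA = "CCCCGTAAGCTCCCC")
    keep_all <- scanSeedSites(utr, mir, energy_fun = function(m, s) -20)
    expect_equal(nrow(keep_all), 1)
    drop_all <- scanSeedSites(utr, mir, energy_fun = function(m, s) -2)
    expect_equal(nrow(drop_all), 0)
})

test_that("generator-planted seed sites are recovered exactly", {
    cfg <- simConfig(n_genes = 100, seed = 83)
    sim <- simulateAnnotation(cfg)
    utrs <- utr3Sequences(sim$annotation, sim$genome)
    hits <- scanSeedSites(utrs, sim$mirnas)
    st <- sim$truth$seed_sites
    expect_identical(
        sort(paste(hits$gene_id, hits$mirna_id, hits$position)),
        sort(paste(st$gene_id, st$mirna_id, st$utr_offset)))
})

test_that("site-count comparison matches hand computation", {
    eq <- siteCountComparison(c(3, 5, 2, 8), c(5, 3, 8, 2))
    expect_equal(eq$percent_increase, 0)
    expect_gt(eq$wilcoxon_p, 0.9)
    ## hand medians on 6 genes
    out <- siteCountComparison(c(10, 12, 14), c(4, 5, 6))
    expect_equal(out$median_ir, 12)
    expect_equal(out$median_other, 5)
    expect_equal(out$percent_increase, (12 - 5) / 5 * 100)
    ## planted 2.5x density recovers ~150%
    set.seed(31)
    a <- rpois(400, 10); b <- rpois(400, 4)
    pl <- siteCountComparison(a, b)
    expect_lt(abs(pl$percent_increase - 150), 30)
    expect_lt(pl$wilcoxon_p, 1e-10)
})

test_that("word enrichment: symmetry, planted word, exact p values", {
    set.seed(41)
    mk <- function(n, len) vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
        character(1))
    bg <- setNames(mk(200, 300), sprintf("g%03d", 1:200))
    ## fg == bg: drawing everything leaves p = 1 for every word
    enr_eq <- wordEnrichment(bg[1:40], bg[1:40])
    expect_true(all(enr_eq$p == 1))
    ## plant CACGTG in all 20 fg and in half of the background overall;
    ## break accidental occurrences first so the counts are exact
    bg <- setNames(gsub("CACGTG", "CACATG", bg), names(bg))
    fg_names <- names(bg)[1:20]
    bg2 <- bg
    bg2[names(bg)[1:100]] <- paste0(bg2[names(bg)[1:100]], "CACGTG")
    enr <- wordEnrichment(bg2[fg_names], bg2)
    top <- enr[1, ]
    expect_equal(top$word, "CACGTG")
    expect_true(top$significant)
    ## exact p against brute-force hypergeometric summation
    for (i in c(1, 5, 50, 2000)) {
        row <- enr[i, ]
        expect_equal(row$p,
                     bruteHyperUpper(row$fg_with, row$bg_with,
                                     row$bg_total - row$bg_with,
                                     row$fg_total),
                     tolerance = 1e-12)
    }
    expect_equal(enr$e_value, pmin(1, enr$p * 4096))
})

test_that("presence/absence counting ignores duplicate occurrences", {
    bg <- c(a = "AAACACGTGTTT", b = "AAACACGTGTTTCACGTG", c = "TTTTTTTTTTT")
    e1 <- wordEnrichment(bg[c("a", "b")], bg)
    row <- e1[e1$word == "CACGTG", ]
    expect_equal(row$fg_with, 2L)
    expect_equal(row$bg_with, 2L)
})

test_that("the polyadenylation signal is flagged, not hidden", {
    bg <- c(a = "GGGAATAAAGGG", b = "CCCAATAAACCC", c = "TTTTTTTTTTTT")
    enr <- wordEnrichment(bg[c("a", "b")], bg)
    expect_true(enr$flagged[enr$word == "AATAAA"])
    expect_false(any(enr$flagged[enr$word != "AATAAA"]))
})

test_that("word-enrichment p values are calibrated under the null", {
    set.seed(51)
    mk <- function(n, len) vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
        character(1))
    bg <- setNames(mk(80, 400), sprintf("g%02d", 1:80))
    word <- "ACGTAC"
    pres <- vapply(bg, function(s) grepl(word, s), logical(1))
    n_with <- sum(pres)
    ## 300 random fg subsets; the discrete upper-tail p is transformed
    ## with the randomized-tail construction, which is exactly uniform
    ## under the null
    u <- replicate(300, {
        fg <- sample(names(bg), 30)
        k <- sum(pres[fg])
        p_ge <- phyper(k - 1, n_with, 80 - n_with, 30, lower.tail = FALSE)
        p_gt <- phyper(k, n_with, 80 - n_with, 30, lower.tail = FALSE)
        p_gt + runif(1) * (p_ge - p_gt)
    })
    expect_gt(ks.test(u, "punif")$p.value, 0.05)
    ## and the reported discrete p is never anti-conservative
    p_rep <- replicate(300, {
        fg <- sample(names(bg), 30)
        e <- wordEnrichment(bg[fg], bg)
        e$p[e$word == word]
    })
    for (t in c(0.05, 0.2, 0.5))
        expect_lte(mean(p_rep <= t), t + 3 * sqrt(t * (1 - t) / 300))
})

test_that("intron seed-site density separates planted classes", {
    mir <- c(m1 = "UAGCUUACGGGGGGGGGGGGGG")
    site <- "GTAAGCT"
    pad <- function(k) paste(rep("C", k), collapse = "")
    ## hand count: 2 sites in 1 kb vs 1 site in 1 kb
    ret <- c(r1 = paste0(pad(100), site, pad(400), site, pad(486)),
             r2 = paste0(pad(200), site, pad(300), site, pad(486)))
    oth <- c(o1 = paste0(pad(500), site, pad(493)),
             o2 = paste0(pad(993), site))
    out <- intronSiteDensity(ret, oth, mir)
    expect_equal(out$density_retained, 2)
    expect_equal(out$density_other, 1)
    ## identical pools -> equal densities
    out_eq <- intronSiteDensity(ret, ret, mir)
    expect_equal(out_eq$density_retained, out_eq$density_other)
})
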