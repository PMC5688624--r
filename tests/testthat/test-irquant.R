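test_that("trimmed mean removes floor(n * trim) values per tail", {
    expect_equal(trimmedMean(rep(7, 50), 0.1), 7)
    expect_equal(trimmedMean(c(0, 0, 0, 0, 100), 0.2), 0)
    expect_error(trimmedMean(numeric(0)), "empty")
    expect_error(trimmedMean(1:5, 0.5), "trim_frac")
    set.seed(11)
    for (rep in 1:10) {
        x <- rpois(sample(5:60, 1), 20)
        tf <- runif(1, 0, 0.45)
        expect_equal(trimmedMean(x, tf), bruteTrimmedMean(x, tf))
    }
})

.locusCalls <- function(intron_median, exon_depth, splice, internal = 0,
                        intron_len = 200L) {
    ## deterministic coverage: constant depths, explicit junction table
    exon_len <- 100L
    depth <- integer(2 * exon_len + intron_len)
    depth[1:exon_len] <- exon_depth
    depth[(exon_len + intron_len + 1):(2 * exon_len + intron_len)] <-
        exon_depth
    depth[(exon_len + 1):(exon_len + intron_len)] <- intron_median
    ex <- GRanges("chrX", IRanges(c(1, exon_len + intron_len + 1),
                                  c(exon_len, 2 * exon_len + intron_len)),
                  strand = "+")
    mcols(ex)$transcript_id <- "t1"
    mcols(ex)$gene_id <- "g1"
    ann <- makeGenomeAnnotation(ex, chromLengths = c(chrX = length(depth)))
    jx <- data.frame(chrom = "chrX", start = exon_len + 1L,
                     end = exon_len + intron_len, strand = "+",
                     count = splice)
    if (internal > 0)
        jx <- rbind(jx, data.frame(chrom = "chrX", start = exon_len + 20L,
                                   end = exon_len + 80L, strand = "+",
                                   count = internal))
    irCalls(ann, IRanges::RleList(chrX = S4Vectors::Rle(depth)), jx)
}

test_that("IR ratio is intron median over pooled flanking-exon median", {
    expect_equal(.locusCalls(0, 50, 10)$ir_ratio, 0)
    expect_equal(.locusCalls(50, 50, 10)$ir_ratio, 1)
    expect_equal(.locusCalls(10, 50, 10)$ir_ratio, 0.2)
    ## clamped at 1 even when the intron is deeper than the exons
    expect_equal(.locusCalls(80, 50, 10)$ir_ratio, 1)
    ## exon median 0 -> ratio 0 by convention
    expect_equal(.locusCalls(5, 0, 10)$ir_ratio, 0)
})

test_that("splice depth counts exact-boundary junctions only", {
    call <- .locusCalls(10, 50, 12)
    expect_equal(call$splice_depth, 12)
    ## a junction inside the intron is internal evidence, not depth
    call2 <- .locusCalls(10, 50, 12, internal = 5)
    expect_equal(call2$splice_depth, 12)
    expect_true(call2$internal_splicing_detected)
    expect_equal(call2$category, "unmeasurable")
    ## a single internal read is below the masking threshold
    call3 <- .locusCalls(10, 50, 12, internal = 1)
    expect_false(call3$internal_splicing_detected)
})

test_that("filters implement the exact thresholds", {
    ## ratio below 0.1 with ample evidence -> not retained
    c1 <- .locusCalls(4, 50, 20)           # ratio 0.08
    expect_equal(c1$category, "not_retained")
    ## ratio exactly at 0.1 counts as retained
    c2 <- .locusCalls(5, 50, 20)           # ratio 0.10
    expect_equal(c2$category, "retained")
    ## splice depth 3 is insufficient regardless of the ratio
    c3 <- .locusCalls(25, 50, 3)
    expect_equal(c3$category, "unmeasurable")
    expect_match(c3$filter_reasons, "splicing depth")
    ## boundary: splice depth 4 + trimmed mean 5.9 -> 9.9 < 10
    df <- data.frame(intron_id = "i", gene_id = "g", chrom = "c",
                     start = 1, end = 2, strand = "+",
                     ir_ratio = 0.5, splice_depth = 4,
                     intron_depth_trimmed_mean = 5.9,
                     flank_exon_median_depth = 50,
                     internal_splicing_detected = FALSE)
    expect_equal(filterIRCalls(df)$category, "unmeasurable")
    df$intron_depth_trimmed_mean <- 6.0
    expect_equal(filterIRCalls(df)$category, "retained")
})

test_that("filtering is idempotent", {
    sh <- sharedSim()
    calls <- irCalls(sh$sim$annotation, sh$ev$coverage, sh$ev$junctions)
    expect_identical(filterIRCalls(calls), calls)
})

test_that("increasing intron depth never decreases the IR ratio", {
    r <- vapply(seq(0, 60, by = 5), function(d)
        .locusCalls(d, 50, 10)$ir_ratio, numeric(1))
    expect_true(all(diff(r) >= 0))
})

test_that("FPKM follows its definition and recovers planted expression", {
    expect_equal(unname(computeFPKM(c(g = 1000), c(g = 1), 1e6)), 1000)
    expect_equal(unname(computeFPKM(c(g = 0), c(g = 2), 1e6)), 0)
    expect_error(computeFPKM(c(g = 1), c(g = 1), 0), "positive")
    sh <- sharedSim()
    fpkm <- computeFPKM(sh$ev$gene_counts,
                        mergedExonicKbp(sh$sim$annotation),
                        sh$ev$total_reads)
    expect_gt(cor(rank(fpkm[sh$sim$truth$genes$gene_id]),
                  rank(sh$sim$truth$genes$fpkm)), 0.95)
})

test_that("gene aggregation takes the max ratio and the paper's flags", {
    calls <- data.frame(
        intron_id = c("a", "b", "c", "d"),
        gene_id = c("g1", "g1", "g2", "g3"),
        ir_ratio = c(0.15, 0.4, 0.05, 0.6),
        splice_depth = 20, intron_depth_trimmed_mean = 20,
        flank_exon_median_depth = 50,
        internal_splicing_detected = FALSE)
    calls <- filterIRCalls(calls)
    gi <- aggregateGeneIR(calls, c(g1 = 10, g2 = 5, g3 = 0.5))
    expect_equal(gi$gene_ir_ratio[gi$gene_id == "g1"], 0.4)
    expect_equal(gi$n_retained[gi$gene_id == "g1"], 2L)
    ## expressed gene without retained introns is not an IR gene
    expect_false(gi$is_ir_gene[gi$gene_id == "g2"])
    ## unexpressed gene cannot be an IR gene even with a retained intron
    expect_false(gi$is_ir_gene[gi$gene_id == "g3"])
    expect_equal(attr(gi, "fraction_ir"), 0.5)
})

test_that("estimator bias shrinks with depth", {
    set.seed(5)
    bias <- vapply(c(10, 50, 200), function(depth) {
        err <- replicate(60, {
            l <- simulateIntronLocus(0.3, depth)
            computeIRRatio(l$intron, l$annotation, l$coverage,
                           l$junctions)$ir_ratio - 0.3
        })
        mean(err)
    }, numeric(1))
    expect_lt(abs(bias[3]), abs(bias[1]) + 0.02)
    expect_lt(abs(bias[3]), 0.02)
})

test_that("gene-body coverage is flat without bias, ramped with it", {
    cfg <- simConfig(n_genes = 40, seed = 61, expression_meanlog = log(50),
                     expression_sdlog = 0.2)
    sim <- simulateAnnotation(cfg)
    ev <- simulateEvidence(sim, cfg)
    prof <- geneBodyCoverage(ev$coverage, sim$annotation)
    expect_equal(max(prof), 1)
    expect_gt(min(prof), 0.95)
    ## planted linear 3' ramp -> monotone increasing profile
    cfgb <- simConfig(n_genes = 40, seed = 61, coverage_bias = 1,
                      expression_meanlog = log(50),
                      expression_sdlog = 0.2)
    simb <- simulateAnnotation(cfgb)
    evb <- simulateEvidence(simb, cfgb)
    profb <- geneBodyCoverage(evb$coverage, simb$annotation)
    expect_gt(cor(seq_along(profb), profb), 0.95)
    expect_gt(profb[100], profb[1])
})

test_that("gene-body profiles follow transcript, not genomic, orientation", {
    ## single minus-strand gene with a 3' ramp: genomic coverage
    ## decreases left to right, but the transcript profile increases
    exon_len <- 2000L
    ex <- GRanges("chr1", IRanges(101, 100 + exon_len), strand = "-")
    mcols(ex)$transcript_id <- "t1"
    mcols(ex)$gene_id <- "g1"
    ann <- makeGenomeAnnotation(ex, chromLengths = c(chr1 = 3000))
    depth <- integer(3000)
    ## transcript 5' end is the genomic right end
    depth[101:(100 + exon_len)] <- rev(round(seq(10, 100, length.out = exon_len)))
    prof <- geneBodyCoverage(IRanges::RleList(chr1 = S4Vectors::Rle(depth)),
                             ann)
    expect_gt(cor(seq_along(prof), prof), 0.99)
})
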