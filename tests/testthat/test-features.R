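test_that("GC content excludes ambiguous bases on both sides", {
    expect_equal(gcContent("GCGC"), 1)
    expect_equal(gcContent("ATAT"), 0)
    expect_equal(gcContent("GCNNAT"), 0.5)
    expect_error(gcContent(""), "empty")
})

test_that("PTC density scans the frame continued from the upstream exon", {
    ## "AAATAAAAA", phase 0: codons AAA TAA AAA -> one stop in 9 nt
    expect_equal(ptcDensity("AAATAAAAA", 0), 1 / 0.009)
    expect_equal(ptcDensity("AAAAAAAAA", 0), 0)
    expect_true(is.na(ptcDensity("AAATAAAAA", NA)))
    ## phase 1: two codon bases already emitted, first full codon at
    ## offset 2 -> "TAA" at positions 3-5
    expect_equal(ptcDensity("CCTAAAAAA", 1), 1 / 0.009)
    set.seed(3)
    for (rep in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1),
                          replace = TRUE), collapse = "")
        ph <- sample(0:2, 1)
        expect_equal(ptcDensity(s, ph),
                     bruteStopCount(s, ph) / (nchar(s) / 1000))
    }
})

test_that("group comparison: identical groups give p near 1 and FD 1", {
    x <- c(1, 2, 3, 4, 5, 6)
    out <- compareFeature(x, x)
    expect_gt(out$p_value, 0.9)
    expect_equal(out$fold_difference, 1)
})

test_that("a planted 5x length difference is detected with FD near 5", {
    set.seed(21)
    ret <- rlnorm(500, log(200), 0.3)
    oth <- rlnorm(500, log(1000), 0.3)
    out <- compareFeature(ret, oth)
    expect_lt(out$p_value, 1e-3)
    expect_lt(abs(out$fold_difference - 5) / 5, 0.15)
})

test_that("small-sample p matches exact enumeration of the rank test", {
    set.seed(9)
    for (rep in 1:6) {
        x <- sample(1:100, sample(3:5, 1))
        y <- sample(101:200, sample(3:5, 1)) / 2.7  # untied
        expect_equal(compareFeature(x, y)$p_value, exactRankSumP(x, y),
                     tolerance = 1e-10)
    }
})

test_that("swapping the groups inverts FD and preserves p", {
    set.seed(2)
    a <- rlnorm(40, 5, 1); b <- rlnorm(40, 6, 1)
    o1 <- compareFeature(a, b); o2 <- compareFeature(b, a)
    expect_equal(o1$p_value, o2$p_value)
    expect_equal(o1$fold_difference, 1 / o2$fold_difference)
})

test_that("FD is invariant under a change of units", {
    set.seed(4)
    a <- runif(30, 1, 2); b <- runif(30, 2, 4)
    expect_equal(compareFeature(a, b)$fold_difference,
                 compareFeature(a * 1000, b * 1000)$fold_difference)
})

test_that("length/IR-ratio trend reflects the planted shape", {
    set.seed(8)
    n <- 2000
    ir <- runif(n, 0.1, 0.9)
    ## monotone decreasing planted relationship
    len_dec <- 10^(4 - 2 * ir + rnorm(n, 0, 0.1))
    tr <- lengthIRTrend(ir, len_dec, n_bins = 8)
    expect_true(all(diff(tr$median_log10_length) < 0))
    expect_true(all(tr$lo <= tr$median_log10_length &
                    tr$median_log10_length <= tr$hi))
    ## constant lengths -> flat curve
    tr_flat <- lengthIRTrend(ir, rep(1000, n), n_bins = 8)
    expect_true(all(abs(tr_flat$median_log10_length - 3) < 1e-9))
    ## U shape: decreasing below 0.5, increasing above
    len_u <- 10^(3 + 2 * abs(ir - 0.5) + rnorm(n, 0, 0.05))
    tr_u <- lengthIRTrend(ir, len_u, n_bins = 8)
    d <- diff(tr_u$median_log10_length)
    expect_lt(d[1], 0)
    expect_gt(d[length(d)], 0)
    ## deterministic given the seed argument
    expect_identical(lengthIRTrend(ir, len_dec, 8, seed = 7),
                     lengthIRTrend(ir, len_dec, 8, seed = 7))
})

test_that("phase distributions normalize and planted shifts are detected", {
    out <- phaseDistribution(rep(0L, 20), rep(c(TRUE, FALSE), 10))
    expect_equal(unname(out$prop_retained), c(1, 0, 0))
    ## hand count on 10 introns
    ph <- c(0, 0, 1, 2, 2, 0, 1, 1, 2, 0)
    rt <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
    out2 <- phaseDistribution(ph, rt)
    expect_equal(unname(out2$prop_retained), c(2, 1, 2) / 5)
    expect_equal(unname(out2$prop_other), c(2, 2, 1) / 5)
    expect_equal(sum(out2$prop_retained), 1)
    ## planted shift away from phase 0 at n = 2000
    set.seed(12)
    n <- 2000
    ph_r <- sample(0:2, n, TRUE, prob = c(0.25, 0.4, 0.35))
    ph_o <- sample(0:2, n, TRUE, prob = c(0.45, 0.3, 0.25))
    out3 <- phaseDistribution(c(ph_r, ph_o),
                              rep(c(TRUE, FALSE), each = n))
    expect_lt(out3$p_value, 1e-3)
})

test_that("generator-planted phase weights shape derived phases", {
    cfg <- simConfig(n_genes = 120, seed = 44,
                     phase_weights_retained = c(0.1, 0.6, 0.3),
                     phase_weights_other = c(0.8, 0.1, 0.1),
                     ir_gene_fraction = 0.5,
                     retained_per_ir_gene_mean = 3)
    sim <- simulateAnnotation(cfg)
    intr <- introns(sim$annotation)
    tr <- sim$truth$introns
    m <- match(mcols(intr)$intron_id, tr$intron_id)
    ph <- mcols(intr)$phase
    keep <- !is.na(ph)
    out <- phaseDistribution(ph[keep], tr$retained[m][keep])
    expect_lt(out$p_value, 1e-4)
    expect_gt(out$prop_other[["0"]], out$prop_retained[["0"]])
})

test_that("relative position is index over intron count", {
    out <- relativePositionDensity(3L, 10L)
    expect_equal(out$rel_position, 0.3)
    expect_equal(relativePositionDensity(10L, 10L)$rel_position, 1)
})

test_that("a planted 3' retention bias shifts the retained density right", {
    cfg <- simConfig(n_genes = 150, seed = 55, position_bias = 2,
                     ir_gene_fraction = 0.5, retained_per_ir_gene_mean = 2)
    sim <- simulateAnnotation(cfg)
    tr <- sim$truth$introns
    out <- relativePositionDensity(tr$index, tr$n_introns, tr$retained,
                                   group = tr$gene_id)
    expect_lt(out$ks_p, 0.01)
    expect_gt(out$mean_retained, out$mean_other)
    ## no bias under the null configuration
    cfg0 <- simConfig(n_genes = 150, seed = 55, position_bias = 0,
                      ir_gene_fraction = 0.5, retained_per_ir_gene_mean = 2)
    tr0 <- simulateAnnotation(cfg0)$truth$introns
    out0 <- relativePositionDensity(tr0$index, tr0$n_introns,
                                    tr0$retained, group = tr0$gene_id)
    expect_gt(out0$ks_p, 0.001)
})

test_that("the intron feature table is complete and consistent", {
    sh <- sharedSim()
    calls <- irCalls(sh$sim$annotation, sh$ev$coverage, sh$ev$junctions)
    ft <- intronFeatureTable(sh$sim$annotation, sh$sim$genome, calls)
    expect_equal(nrow(ft), length(introns(sh$sim$annotation)))
    expect_true(all(ft$gc >= 0 & ft$gc <= 1))
    expect_true(all(ft$rel_position > 0 & ft$rel_position <= 1))
    expect_equal(ft$length,
                 unname(nchar(as.character(
                     intronSequences(sh$sim$annotation, sh$sim$genome)))))
})
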