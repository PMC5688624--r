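## toy site sampler with a planted dependency between positions 1 and 3
.depSites <- function(n, couple = 0.7, seed = 1) {
    set.seed(seed)
    base <- c("A", "C", "G", "T")
    x1 <- sample(base, n, TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    x3 <- ifelse(runif(n) < couple, x1, sample(base, n, TRUE))
    x2 <- sample(base, n, TRUE)
    paste0(x1, x2, x3)
}

test_that("order-1 training equals the positional product closed form", {
    sites <- .depSites(300)
    m <- trainMaxEnt(sites, kind = "toy", constraints = "order1")
    p <- maxEntProbTable(m)
    base <- c("A", "C", "G", "T")
    emp <- vapply(1:3, function(i)
        (table(factor(substr(sites, i, i), base)) + 2) / (300 + 8),
        numeric(4))
    expected <- vapply(names(p), function(s) {
        v <- strsplit(s, "")[[1]]
        prod(vapply(1:3, function(i) emp[v[i], i], numeric(1)))
    }, numeric(1))
    expect_equal(unname(p), unname(expected), tolerance = 1e-9)
})

test_that("training matches a direct convex maximum-entropy solve", {
    sites <- .depSites(250, seed = 3)
    m <- trainMaxEnt(sites, kind = "toy", tol = 1e-9)
    p_pkg <- maxEntProbTable(m)
    p_oracle <- maxentOracle(sites)
    tv <- 0.5 * sum(abs(p_pkg[names(p_oracle)] - p_oracle))
    expect_lt(tv, 1e-6)
})

test_that("constrained marginals match the empirical ones at tolerance", {
    sites <- .depSites(200, seed = 5)
    m <- trainMaxEnt(sites, kind = "toy", tol = 1e-6)
    expect_lt(m@maxDeviation, 1e-6)
    p <- maxEntProbTable(m)
    ## pairwise (1,3) marginal of the model vs (pseudocounted) data
    base <- c("A", "C", "G", "T")
    emp <- matrix(0.5, 4, 4, dimnames = list(base, base))
    for (s in sites) {
        v <- strsplit(s, "")[[1]]
        emp[v[1], v[3]] <- emp[v[1], v[3]] + 1
    }
    emp <- emp / sum(emp)
    mod <- matrix(0, 4, 4, dimnames = list(base, base))
    for (s in names(p)) {
        v <- strsplit(s, "")[[1]]
        mod[v[1], v[3]] <- mod[v[1], v[3]] + p[[s]]
    }
    expect_equal(mod, emp, tolerance = 1e-5)
})

test_that("a planted pairwise dependency is recovered within sampling error", {
    sites <- .depSites(1000, couple = 0.8, seed = 7)
    m <- trainMaxEnt(sites, kind = "toy", tol = 1e-8)
    p <- maxEntProbTable(m)
    same <- sum(p[substr(names(p), 1, 1) == substr(names(p), 3, 3)])
    emp_same <- mean(substr(sites, 1, 1) == substr(sites, 3, 3))
    expect_lt(abs(same - emp_same), 0.02)
    ## and the independence model cannot represent it
    m1 <- trainMaxEnt(sites, kind = "toy", constraints = "order1")
    p1 <- maxEntProbTable(m1)
    same1 <- sum(p1[substr(names(p1), 1, 1) == substr(names(p1), 3, 3)])
    expect_gt(same - same1, 0.2)
})

test_that("the fit maximizes entropy subject to its constraints", {
    sites <- .depSites(200, seed = 11)
    m <- trainMaxEnt(sites, kind = "toy", tol = 1e-9)
    h_model <- modelEntropy(m)
    ## the pseudocounted empirical joint (uniform pseudo-mass of
    ## pseudocount * 16 observations over 64 outcomes) has exactly the
    ## constrained marginals, so its entropy cannot exceed the fit's
    grid <- names(maxEntProbTable(m))
    emp <- setNames(rep(0.5 * 16 / 64, length(grid)), grid)
    for (s in sites) emp[s] <- emp[s] + 1
    emp <- emp / sum(emp)
    h_emp <- -sum(ifelse(emp > 0, emp * log2(emp), 0))
    expect_gte(h_model, h_emp - 1e-9)
    ## adding constraints never increases entropy
    m1 <- trainMaxEnt(sites, kind = "toy", constraints = "order1")
    expect_lte(h_model, modelEntropy(m1) + 1e-9)
})

test_that("scores are log2 odds against the background", {
    ## uniform model, uniform background -> score 0 everywhere
    m <- new("MaxEntModel", kind = "toy", width = 2L,
             alphabet = c("A", "C", "G", "T"),
             singleton = list(rep(0, 4), rep(0, 4)), pairs = list(),
             logZ = log(16), background = rep(0.25, 4),
             trainedOn = 0L, iterations = 0L, maxDeviation = 0)
    expect_equal(scoreWindows(m, c("AA", "CG", "TT")), rep(0, 3))
    ## a window whose model probability is twice the background scores
    ## exactly +1 bit
    m2 <- m
    m2@singleton[[1]] <- log(c(8, 8 / 3, 8 / 3, 8 / 3))  # P(x1 = A) = 0.5
    m2@logZ <- log(sum(c(8, 8 / 3, 8 / 3, 8 / 3)) * 4)
    p <- maxEntProbTable(m2)
    expect_equal(unname(p["AA"]), 0.5 * 0.25)   # 2x the uniform 0.0625
    expect_equal(unname(scoreWindows(m2, "AA")), 1)
})

test_that("strong and weak planted sites separate by score", {
    set.seed(19)
    strong <- replicate(300, paste(
        IRkit:::.sampleSite(IRkit:::.DONOR_CONSENSUS,
                            IRkit:::.DONOR_FIXED, 0.85), collapse = ""))
    weak <- replicate(100, paste(
        IRkit:::.sampleSite(IRkit:::.DONOR_CONSENSUS,
                            IRkit:::.DONOR_FIXED, 0.3), collapse = ""))
    m <- trainMaxEnt(strong, kind = "donor")
    ss <- scoreWindows(m, strong[1:100])
    sw <- scoreWindows(m, weak)
    ## AUROC by rank comparison
    r <- rank(c(ss, sw))
    auroc <- (sum(r[1:100]) - 100 * 101 / 2) / (100 * 100)
    expect_gt(auroc, 0.9)
})

test_that("site windows are extracted strand-aware with GT/AG boundaries", {
    sh <- sharedSim()
    win <- extractSiteWindows(sh$sim$annotation, sh$sim$genome)
    expect_equal(length(win$donor), length(introns(sh$sim$annotation)))
    ## canonical dinucleotides at the planted motif positions
    expect_true(all(substr(win$donor, 4, 5) == "GT"))
    expect_true(all(substr(win$acceptor, 19, 20) == "AG"))
    expect_true(all(nchar(win$donor) == 9))
    expect_true(all(nchar(win$acceptor) == 23))
})

test_that("retained introns score lower when planted with weak sites", {
    sh <- sharedSim()
    win <- extractSiteWindows(sh$sim$annotation, sh$sim$genome)
    tr <- sh$sim$truth$introns
    ret <- tr$retained[match(names(win$donor), tr$intron_id)]
    md <- trainMaxEnt(win$donor[!ret], kind = "donor")
    ma <- trainMaxEnt(win$acceptor[!ret], kind = "acceptor")
    ps <- pairScores(scoreWindows(md, win$donor),
                     scoreWindows(ma, win$acceptor), ret)
    expect_lt(ps$p_donor, 0.01)
    expect_lt(ps$p_acceptor, 0.01)
    expect_lt(ps$mean_shift_donor, 0)
    expect_lt(ps$mean_shift_acceptor, 0)
    ## bin counts conserve the intron count
    expect_equal(sum(ps$bins), length(ret))
    ## identical distributions show no shift
    ps0 <- pairScores(scoreWindows(md, win$donor[!ret]),
                      scoreWindows(ma, win$acceptor[!ret]),
                      rep(c(TRUE, FALSE), length.out = sum(!ret)))
    expect_gt(ps0$p_donor, 0.01)
})

test_that("model serialization round-trips scores", {
    sites <- .depSites(120, seed = 13)
    m <- trainMaxEnt(sites, kind = "toy")
    f <- tempfile(fileext = ".json")
    writeMaxEntModel(m, f)
    m2 <- readMaxEntModel(f)
    probe <- .depSites(20, seed = 14)
    expect_equal(maxEntLogProb(m, probe), maxEntLogProb(m2, probe),
                 tolerance = 1e-12)
    expect_equal(m@background, m2@background)
})

test_that("training refuses too few sites and non-ACGT input", {
    expect_error(trainMaxEnt(c("AAA", "CCC"), kind = "toy"), "at least")
    expect_error(trainMaxEnt(rep("ANA", 60), kind = "toy"), "ACGT")
})
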