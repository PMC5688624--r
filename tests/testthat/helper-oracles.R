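## Independent oracles and shared fixtures for the test suite.
## Everything here is deliberately naive (enumeration, brute force,
## direct convex optimization) and independent of the package's
## implementation paths.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## tiny hand-built annotation: two genes on chr1 (one +, one -), one
## transcript each, with CDS so phases and UTRs are defined
tinyAnnotation <- function() {
    exons <- GRanges("chr1",
        IRanges(c(101, 301, 601,   2001, 2401, 2801),
                c(200, 400, 800,   2200, 2600, 3000)),
        strand = c("+", "+", "+", "-", "-", "-"))
    mcols(exons)$transcript_id <- rep(c("TA.1", "TB.1"), each = 3)
    mcols(exons)$gene_id <- rep(c("GA", "GB"), each = 3)
    cds <- GRanges("chr1",
        IRanges(c(131, 301, 601,   2101, 2401, 2901),
                c(200, 400, 700,   2200, 2600, 2970)),
        strand = c("+", "+", "+", "-", "-", "-"))
    mcols(cds)$transcript_id <- rep(c("TA.1", "TB.1"), each = 3)
    makeGenomeAnnotation(exons, cds = cds,
                         chromLengths = c(chr1 = 5000))
}

## brute-force merged exonic length: mark bases on a toy chromosome
bruteUnionBp <- function(starts, ends, chrom_len = 10000) {
    hit <- logical(chrom_len)
    for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
    sum(hit)
}

## brute-force trimmed mean: sort and slice
bruteTrimmedMean <- function(x, trim) {
    k <- floor(length(x) * trim)
    s <- sort(x)
    if (k > 0) s <- s[(k + 1):(length(s) - k)]
    mean(s)
}

## exact two-sided rank-sum p by enumeration of all group assignments
exactRankSumP <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    idx <- utils::combn(length(pooled), n)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n)])
    ws <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

## brute-force upper-tail hypergeometric: P(X >= k) via choose() sums
bruteHyperUpper <- function(k, white, black, drawn) {
    kk <- k:min(white, drawn)
    sum(choose(white, kk) * choose(black, drawn - kk)) /
        choose(white + black, drawn)
}

## brute-force in-frame stop count
bruteStopCount <- function(seq, phase) {
    off <- (3 - phase) %% 3
    n <- 0
    i <- off + 1
    while (i + 2 <= nchar(seq)) {
        if (substr(seq, i, i + 2) %in% c("TAA", "TAG", "TGA")) n <- n + 1
        i <- i + 3
    }
    n
}

## direct maximum-entropy solve by convex optimization of the dual on
## the fully enumerated sequence space (toy widths only)
maxentOracle <- function(sites, constraints = "order2skip",
                         pseudocount = 0.5) {
    base <- c("A", "C", "G", "T")
    w <- nchar(sites[1])
    n <- length(sites)
    enc <- t(vapply(strsplit(sites, ""), function(v) match(v, base),
                    integer(w)))
    groups <- as.list(seq_len(w))
    if (constraints == "order2skip") {
        if (w >= 2) for (i in 1:(w - 1)) groups <- c(groups, list(c(i, i + 1)))
        if (w >= 3) for (i in 1:(w - 2)) groups <- c(groups, list(c(i, i + 2)))
    }
    ## target marginals: uniform pseudo-mass of pseudocount * 16
    targets <- lapply(groups, function(g) {
        if (length(g) == 1) {
            tab <- tabulate(enc[, g], 4) + pseudocount * 4
        } else {
            tab <- matrix(0, 4, 4)
            for (r in seq_len(n))
                tab[enc[r, g[1]], enc[r, g[2]]] <-
                    tab[enc[r, g[1]], enc[r, g[2]]] + 1
            tab <- tab + pseudocount
        }
        as.vector(tab / sum(tab))
    })
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    ## feature matrix: one indicator column per (group, cell)
    cols <- list()
    for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        if (length(g) == 1) {
            for (a in 1:4) cols[[length(cols) + 1]] <- (grid[, g] == a) * 1
        } else {
            for (b in 1:4) for (a in 1:4)
                cols[[length(cols) + 1]] <-
                    (grid[, g[1]] == a & grid[, g[2]] == b) * 1
        }
    }
    FF <- do.call(cbind, cols)
    mhat <- unlist(targets)
    fn <- function(l) {
        eta <- FF %*% l
        mx <- max(eta)
        log(sum(exp(eta - mx))) + mx - sum(l * mhat)
    }
    gr <- function(l) {
        eta <- FF %*% l
        p <- exp(eta - max(eta)); p <- p / sum(p)
        as.vector(crossprod(FF, p)) - mhat
    }
    opt <- stats::optim(rep(0, ncol(FF)), fn, gr, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    eta <- FF %*% opt$par
    p <- exp(eta - max(eta)); p <- as.vector(p / sum(p))
    names(p) <- apply(grid, 1, function(x) paste(base[x], collapse = ""))
    p
}

## naive UPGMA (average linkage) merge heights for a distance matrix
bruteAverageLinkHeights <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    active <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(active) > 1) {
        best <- c(NA, NA); bh <- Inf
        for (i in seq_along(active)) for (j in seq_along(active)) {
            if (i >= j) next
            h <- mean(d[active[[i]], active[[j]]])
            if (h < bh) { bh <- h; best <- c(i, j) }
        }
        heights <- c(heights, bh)
        merged <- c(active[[best[1]]], active[[best[2]]])
        active <- active[-best]
        active[[length(active) + 1]] <- merged
    }
    sort(heights)
}

## adjusted Rand index (small, self-contained)
ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    tot <- choose(sum(tab), 2)
    exp_ <- si * sj / tot
    (sij - exp_) / ((si + sj) / 2 - exp_)
}

## shared small simulated dataset (built once per test run)
.shared_sim_env <- new.env()
sharedSim <- function() {
    if (is.null(.shared_sim_env$sim)) {
        cfg <- simConfig(n_genes = 80, seed = 42)
        .shared_sim_env$cfg <- cfg
        .shared_sim_env$sim <- simulateAnnotation(cfg)
        .shared_sim_env$ev <- simulateEvidence(.shared_sim_env$sim, cfg)
    }
    list(cfg = .shared_sim_env$cfg, sim = .shared_sim_env$sim,
         ev = .shared_sim_env$ev)
}
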