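## Maximum-entropy splice-site strength modeling.
##
## The model is the maximum-entropy distribution over fixed-width
## sequence windows subject to marginal constraints: all single-position
## compositions plus, by default, all adjacent and skip-one position
## pairs. Because every constrained pair spans at most 2 positions, the
## log-linear model is a chain of bandwidth 2 and all marginals are
## exact via a 16-state transfer-matrix recursion; fitting is iterative
## proportional scaling on the constraint marginals.

.DNA4 <- c("A", "C", "G", "T")

## encode sites (character vector) as integer matrix n x w in 1..4
.encodeSites <- function(sites, alphabet = .DNA4) {
    w <- unique(nchar(sites))
    if (length(w) != 1) stop("all sites must share one width")
    m <- matrix(match(unlist(strsplit(toupper(sites), "")), alphabet),
                ncol = w, byrow = TRUE)
    if (anyNA(m)) stop("sites must be over ", paste(alphabet, collapse = ""))
    m
}

## Empirical marginals with a consistent pseudocount: a uniform
## pseudo-mass of pseudocount * K^2 observations is added to the joint,
## so pairwise tables get +pseudocount per cell and singleton tables
## +pseudocount * K. Inconsistent per-table pseudocounts would make the
## constraint set infeasible and stall the scaling iteration.
.empMarginals <- function(enc, groups, pseudocount, K) {
    lapply(groups, function(g) {
        if (length(g) == 1) {
            tab <- tabulate(enc[, g], nbins = K) + pseudocount * K
        } else {
            tab <- matrix(0, K, K)
            idx <- cbind(enc[, g[1]], enc[, g[2]])
            for (r in seq_len(nrow(enc)))
                tab[idx[r, 1], idx[r, 2]] <- tab[idx[r, 1], idx[r, 2]] + 1
            tab <- tab + pseudocount
        }
        tab / sum(tab)
    })
}

## default constraint set
.constraintGroups <- function(w, order = c("order2skip", "order1")) {
    order <- match.arg(order)
    groups <- as.list(seq_len(w))
    if (order == "order2skip" && w >= 2) {
        for (i in seq_len(w - 1)) groups <- c(groups, list(c(i, i + 1L)))
        if (w >= 3)
            for (i in seq_len(w - 2)) groups <- c(groups, list(c(i, i + 2L)))
    }
    groups
}

## transfer-matrix inference over the bandwidth-2 chain.
## potentials: sing = list of numeric(K) (log), pair = K x K log matrices
## keyed "i:j" for j - i in {1, 2}. Returns logZ and all constrained
## marginals (exact).
.chainInfer <- function(sing, pairkey, w, K = 4) {
    S <- lapply(sing, exp)
    getP <- function(i, j) {
        k <- paste(i, j, sep = ":")
        if (!is.null(pairkey[[k]])) exp(pairkey[[k]]) else matrix(1, K, K)
    }
    if (w == 1) {
        p <- S[[1]] / sum(S[[1]])
        return(list(logZ = log(sum(S[[1]])), single = list(p),
                    pairs = list()))
    }
    ## forward over states t_i = (x_i, x_{i+1}), i = 1..w-1
    f <- vector("list", w - 1)
    logscale <- 0
    f1 <- outer(S[[1]], S[[2]]) * getP(1, 2)
    sc <- sum(f1); f[[1]] <- f1 / sc; logscale <- log(sc)
    if (w >= 3) for (i in seq_len(w - 2)) {
        P12 <- getP(i + 1, i + 2)   # (b, c)
        P02 <- getP(i, i + 2)       # (a, c)
        fn <- matrix(0, K, K)
        for (cc in seq_len(K)) {
            ## sum_a f[a,b] * P02[a,cc] -> vector over b
            vb <- colSums(f[[i]] * P02[, cc])
            fn[, cc] <- vb * P12[, cc] * S[[i + 2]][cc]
        }
        sc <- sum(fn)
        f[[i + 1]] <- fn / sc
        logscale <- logscale + log(sc)
    }
    logZ <- logscale  # each step normalized; total mass folded in
    ## backward
    b <- vector("list", w - 1)
    b[[w - 1]] <- matrix(1, K, K)
    if (w >= 3) for (i in rev(seq_len(w - 2))) {
        P12 <- getP(i + 1, i + 2)
        P02 <- getP(i, i + 2)
        bn <- matrix(0, K, K)
        for (a in seq_len(K))
            for (bb in seq_len(K))
                bn[a, bb] <- sum(P02[a, ] * P12[bb, ] * S[[i + 2]] *
                                 b[[i + 1]][bb, ])
        b[[i]] <- bn
    }
    ## adjacent-pair marginals
    adj <- vector("list", w - 1)
    for (i in seq_len(w - 1)) {
        m <- f[[i]] * b[[i]]
        adj[[i]] <- m / sum(m)
    }
    ## skip-one marginals
    skip <- list()
    if (w >= 3) for (i in seq_len(w - 2)) {
        P12 <- getP(i + 1, i + 2)
        P02 <- getP(i, i + 2)
        m <- matrix(0, K, K)  # over (a, c)
        for (a in seq_len(K))
            for (cc in seq_len(K))
                m[a, cc] <- sum(f[[i]][a, ] * P02[a, cc] * P12[, cc] *
                                S[[i + 2]][cc] * b[[i + 1]][, cc])
        skip[[paste(i, i + 2, sep = ":")]] <- m / sum(m)
    }
    single <- vector("list", w)
    for (i in seq_len(w - 1)) single[[i]] <- rowSums(adj[[i]])
    single[[w]] <- colSums(adj[[w - 1]])
    list(logZ = logZ, single = single, adj = adj, skip = skip)
}

.groupMarginal <- function(inf, g) {
    if (length(g) == 1) return(inf$single[[g]])
    if (g[2] - g[1] == 1) return(inf$adj[[g[1]]])
    inf$skip[[paste(g[1], g[2], sep = ":")]]
}

#' Train a maximum-entropy splice-site model
#'
#' Iterative proportional scaling until every constrained marginal
#' matches its (pseudocounted) empirical counterpart within \code{tol};
#' deterministic, no randomness. Model marginals are exact at every
#' step (transfer-matrix recursion), so the fit is the true
#' maximum-entropy distribution for the constraint set.
#'
#' @param sites character vector (or DNAStringSet) of equal-width
#'   windows over ACGT
#' @param kind label, e.g. "donor" (width 9: exon -3..-1 + intron
#'   +1..+6) or "acceptor" (width 23: intron -20..-1 + exon +1..+3)
#' @param constraints "order2skip" (all singletons + adjacent +
#'   skip-one pairs, the default) or "order1" (singletons only, the
#'   independence limit: the fit then equals the positional product of
#'   column frequencies)
#' @param tol convergence tolerance on marginal deviations
#' @param max_iter maximum scaling sweeps
#' @param pseudocount added to every cell of every empirical marginal
#' @param min_sites minimum training sites
#' @return a \code{\linkS4class{MaxEntModel}}
#' @export
trainMaxEnt <- function(sites, kind = "donor",
                        constraints = c("order2skip", "order1"),
                        tol = 1e-4, max_iter = 10000, pseudocount = 0.5,
                        min_sites = 50) {
    constraints <- match.arg(constraints)
    sites <- as.character(sites)
    if (length(sites) < min_sites)
        stop("need at least ", min_sites, " training sites")
    enc <- .encodeSites(sites)
    w <- ncol(enc)
    K <- 4L
    if (kind == "donor" && w == 9) {
        canon <- mean(enc[, 4] == 3 & enc[, 5] == 4)
        if (canon < 0.9)
            warning("fewer than 90% of donor sites are GT at +1/+2")
    }
    if (kind == "acceptor" && w == 23) {
        canon <- mean(enc[, 19] == 1 & enc[, 20] == 3)
        if (canon < 0.9)
            warning("fewer than 90% of acceptor sites are AG at -2/-1")
    }
    groups <- .constraintGroups(w, constraints)
    emp <- .empMarginals(enc, groups, pseudocount, K)

    sing <- rep(list(rep(0, K)), w)
    pairkey <- list()
    dev <- Inf
    it <- 0L
    while (it < max_iter) {
        it <- it + 1L
        for (gi in seq_along(groups)) {
            g <- groups[[gi]]
            inf <- .chainInfer(sing, pairkey, w, K)
            m <- .groupMarginal(inf, g)
            upd <- log(emp[[gi]]) - log(m)
            if (length(g) == 1) {
                sing[[g]] <- sing[[g]] + upd
            } else {
                k <- paste(g[1], g[2], sep = ":")
                old <- if (is.null(pairkey[[k]])) matrix(0, K, K)
                       else pairkey[[k]]
                pairkey[[k]] <- old + upd
            }
        }
        inf <- .chainInfer(sing, pairkey, w, K)
        dev <- max(vapply(seq_along(groups), function(gi)
            max(abs(.groupMarginal(inf, groups[[gi]]) - emp[[gi]])),
            numeric(1)))
        if (dev < tol) break
    }
    if (dev >= tol)
        stop(sprintf(
            "maxent training did not converge in %d sweeps (deviation %.3g)",
            max_iter, dev))
    bg <- tabulate(enc, nbins = K) + pseudocount
    bg <- bg / sum(bg)
    names(bg) <- .DNA4
    pairs <- lapply(names(pairkey), function(k) {
        ij <- as.integer(strsplit(k, ":")[[1]])
        list(pos = ij, logpot = pairkey[[k]])
    })
    new("MaxEntModel", kind = kind, width = as.integer(w),
        alphabet = .DNA4, singleton = sing, pairs = pairs,
        logZ = .chainInfer(sing, pairkey, w, K)$logZ,
        background = bg, trainedOn = length(sites),
        iterations = it, maxDeviation = dev)
}

.pairkeyOf <- function(model) {
    pk <- list()
    for (p in model@pairs)
        pk[[paste(p$pos[1], p$pos[2], sep = ":")]] <- p$logpot
    pk
}

#' Model log-probability of windows
#'
#' @param model a \code{MaxEntModel}
#' @param windows character vector of windows of the model's width
#' @return natural-log probabilities
#' @export
maxEntLogProb <- function(model, windows) {
    enc <- .encodeSites(as.character(windows), model@alphabet)
    if (ncol(enc) != model@width) stop("window width mismatch")
    pk <- .pairkeyOf(model)
    lp <- numeric(nrow(enc))
    for (i in seq_len(model@width)) lp <- lp + model@singleton[[i]][enc[, i]]
    for (k in names(pk)) {
        ij <- as.integer(strsplit(k, ":")[[1]])
        lp <- lp + pk[[k]][cbind(enc[, ij[1]], enc[, ij[2]])]
    }
    lp - model@logZ
}

#' Score windows in bits
#'
#' log2( P_model(x) / P_background(x) ) with an order-0 composition
#' background (the model's training composition unless supplied).
#'
#' @param model a \code{MaxEntModel}
#' @param windows character vector (or DNAStringSet)
#' @param background optional length-4 composition (A,C,G,T)
#' @return numeric scores in bits
#' @export
scoreWindows <- function(model, windows, background = NULL) {
    if (is.null(background)) background <- model@background
    background <- background / sum(background)
    enc <- .encodeSites(as.character(windows), model@alphabet)
    lp <- maxEntLogProb(model, windows)
    lbg <- rowSums(matrix(log(background)[enc], nrow = nrow(enc)))
    setNames((lp - lbg) / log(2), names(windows))
}

#' Enumerated probability table (small widths)
#'
#' Full distribution over the 4^w sequence space; for validation and
#' entropy computations on toy widths.
#'
#' @param model a \code{MaxEntModel} with width <= 10
#' @return named numeric vector summing to 1
#' @export
maxEntProbTable <- function(model) {
    w <- model@width
    if (w > 10) stop("enumeration limited to width <= 10")
    grid <- do.call(expand.grid,
                    rep(list(model@alphabet), w))[, w:1, drop = FALSE]
    seqs <- do.call(paste0, grid)
    p <- exp(maxEntLogProb(model, seqs))
    names(p) <- seqs
    p
}

#' Shannon entropy of an enumerable model (bits)
#' @param model a \code{MaxEntModel} with width <= 10
#' @return entropy in bits
#' @export
modelEntropy <- function(model) {
    p <- maxEntProbTable(model)
    -sum(p * log2(p))
}

#' Extract donor/acceptor windows for introns
#'
#' Donor: last 3 exonic + first 6 intronic bases (9 nt); acceptor:
#' last 20 intronic + first 3 exonic bases (23 nt); strand-aware with
#' reverse complement on the minus strand.
#'
#' @param ann a \code{GenomeAnnotation}
#' @param genome \code{DNAStringSet}
#' @return list(donor, acceptor): named character vectors per intron
#' @export
extractSiteWindows <- function(ann, genome) {
    intr <- introns(ann)
    don <- character(length(intr)); acc <- character(length(intr))
    for (i in seq_along(intr)) {
        ch <- as.character(seqnames(intr)[i])
        s <- start(intr)[i]; e <- end(intr)[i]
        neg <- as.character(strand(intr)[i]) == "-"
        gs <- function(a, b)
            as.character(Biostrings::subseq(genome[[ch]], a, b))
        if (!neg) {
            don[i] <- gs(s - 3, s + 5)
            acc[i] <- gs(e - 19, e + 3)
        } else {
            rc <- function(x) as.character(reverseComplement(DNAString(x)))
            don[i] <- rc(gs(e - 5, e + 3))
            acc[i] <- rc(gs(s - 3, s + 19))
        }
    }
    names(don) <- names(acc) <- mcols(intr)$intron_id
    list(donor = don, acceptor = acc)
}

#' Splice-site pair scores with 2-D binning
#'
#' Scores each intron's donor and acceptor windows, bins the pairs on a
#' \code{n_bins} x \code{n_bins} grid, and summarizes retained vs other
#' introns (mean score shift; one-sided rank test for weaker sites in
#' the retained class).
#'
#' @param donor_scores,acceptor_scores named numeric per intron
#' @param retained logical per intron
#' @param n_bins grid resolution
#' @return list(bins, breaks_donor, breaks_acceptor, mean_shift_donor,
#'   mean_shift_acceptor, p_donor, p_acceptor)
#' @export
pairScores <- function(donor_scores, acceptor_scores, retained,
                       n_bins = 100) {
    stopifnot(length(donor_scores) == length(acceptor_scores),
              length(retained) == length(donor_scores))
    bd <- seq(min(donor_scores), max(donor_scores), length.out = n_bins + 1)
    ba <- seq(min(acceptor_scores), max(acceptor_scores),
              length.out = n_bins + 1)
    ix <- pmin(n_bins, findInterval(donor_scores, bd,
                                    rightmost.closed = TRUE))
    iy <- pmin(n_bins, findInterval(acceptor_scores, ba,
                                    rightmost.closed = TRUE))
    bins <- matrix(0L, n_bins, n_bins)
    for (k in seq_along(ix))
        bins[ix[k], iy[k]] <- bins[ix[k], iy[k]] + 1L
    pd <- if (any(retained) && any(!retained))
        wilcox.test(donor_scores[retained], donor_scores[!retained],
                    alternative = "less", exact = FALSE)$p.value
        else NA_real_
    pa <- if (any(retained) && any(!retained))
        wilcox.test(acceptor_scores[retained], acceptor_scores[!retained],
                    alternative = "less", exact = FALSE)$p.value
        else NA_real_
    list(bins = bins, breaks_donor = bd, breaks_acceptor = ba,
         mean_shift_donor = mean(donor_scores[retained]) -
             mean(donor_scores[!retained]),
         mean_shift_acceptor = mean(acceptor_scores[retained]) -
             mean(acceptor_scores[!retained]),
         p_donor = pd, p_acceptor = pa)
}

#' Serialize / restore a MaxEntModel as JSON
#'
#' @param model a \code{MaxEntModel}
#' @param path file path
#' @export
writeMaxEntModel <- function(model, path) {
    obj <- list(kind = model@kind, width = model@width,
                alphabet = model@alphabet,
                singleton = model@singleton,
                pairs = lapply(model@pairs, function(p)
                    list(pos = p$pos, logpot = as.vector(p$logpot))),
                logZ = model@logZ, background = as.list(model@background),
                trained_on = model@trainedOn,
                iterations = model@iterations,
                max_deviation = model@maxDeviation)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMaxEntModel
#' @export
readMaxEntModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    pairs <- lapply(obj$pairs, function(p)
        list(pos = as.integer(unlist(p$pos)),
             logpot = matrix(as.numeric(unlist(p$logpot)), 4, 4)))
    new("MaxEntModel", kind = obj$kind, width = as.integer(obj$width),
        alphabet = as.character(unlist(obj$alphabet)),
        singleton = lapply(obj$singleton, function(s)
            as.numeric(unlist(s))),
        pairs = pairs, logZ = obj$logZ,
        background = unlist(obj$background),
        trainedOn = as.integer(obj$trained_on),
        iterations = as.integer(obj$iterations),
        maxDeviation = obj$max_deviation)
}
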