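#' @importFrom stats cor kmeans hclust as.dist approx
NULL

#' Cross-species IR profile matrix
#'
#' One row per ortholog group, one column per species, value = the
#' gene IR ratio of the group's gene in that species (NA where the
#' group has no gene or the gene was not scored). Many-to-many groups
#' are collapsed by the maximum IR ratio.
#'
#' @param gene_ir_list named list (per species) of gene tables from
#'   \code{\link{aggregateGeneIR}}
#' @param orthologs data.frame group_id/species/gene_id
#' @return numeric matrix, rownames = group IDs
#' @export
buildProfileMatrix <- function(gene_ir_list, orthologs) {
    species <- names(gene_ir_list)
    groups <- unique(orthologs$group_id)
    m <- matrix(NA_real_, length(groups), length(species),
                dimnames = list(groups, species))
    for (sp in species) {
        o <- orthologs[orthologs$species == sp, , drop = FALSE]
        gi <- gene_ir_list[[sp]]
        ir <- structure(gi$gene_ir_ratio, names = gi$gene_id)
        val <- ir[o$gene_id]
        agg <- tapply(val, o$group_id, function(v)
            if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
        m[names(agg), sp] <- as.numeric(agg)
    }
    m
}

#' Quantile normalization with missing values
#'
#' Forces every column onto the common reference distribution (the
#' across-column mean quantile function, which for complete matrices is
#' the row-wise mean of the sorted columns). Missing values stay
#' missing; ranks are computed over the observed entries of each
#' column. Ties are broken by stable order ("first"), so every complete
#' column's sorted values equal the reference exactly and the transform
#' is exactly idempotent even on tied (e.g. zero-inflated) data.
#'
#' @param m numeric matrix
#' @return normalized matrix of the same shape
#' @export
quantileNormalize <- function(m) {
    stopifnot(is.matrix(m))
    ## reference quantile grid at the (i - 0.5)/n points, so complete
    ## columns map exactly (and renormalization is a fixed point)
    grid <- (seq_len(nrow(m)) - 0.5) / nrow(m)
    qfun <- apply(m, 2, function(col) {
        v <- sort(col[!is.na(col)])
        if (length(v) < 2) return(rep(v[1], length(grid)))
        approx(x = (seq_along(v) - 0.5) / length(v), y = v,
               xout = grid, rule = 2)$y
    })
    ref <- rowMeans(qfun)
    out <- m
    for (j in seq_len(ncol(m))) {
        obs <- which(!is.na(m[, j]))
        if (!length(obs)) next
        r <- rank(m[obs, j], ties.method = "first")
        q <- (r - 0.5) / length(obs)
        out[obs, j] <- approx(x = grid, y = ref, xout = q, rule = 2)$y
    }
    out
}

#' K-means clustering of profile rows
#'
#' Euclidean k-means, best of \code{n_init} seeded restarts; rows with
#' any missing value are dropped.
#'
#' @param m profile matrix
#' @param k number of clusters
#' @param seed RNG seed
#' @param n_init random restarts
#' @return named integer vector of cluster assignments (complete rows)
#' @export
kmeansRows <- function(m, k, seed = 1, n_init = 25) {
    complete <- stats::complete.cases(m)
    mm <- m[complete, , drop = FALSE]
    if (nrow(mm) < k) stop("fewer complete rows than clusters")
    if (nrow(mm) == k)   # one row per cluster
        return(structure(seq_len(k), names = rownames(mm)))
    set.seed(seed)
    fit <- kmeans(mm, centers = k, nstart = n_init, iter.max = 100)
    structure(fit$cluster, names = rownames(mm))
}

#' Hierarchical clustering of species columns
#'
#' Distance = 1 - Pearson correlation (pairwise-complete), average
#' linkage; the dendrogram is also serialized as Newick.
#'
#' @param m profile matrix (columns = species)
#' @return list(hclust, newick)
#' @export
hclusterSpecies <- function(m) {
    cc <- cor(m, use = "pairwise.complete.obs")
    d <- as.dist(1 - cc)
    hc <- hclust(d, method = "average")
    list(hclust = hc,
         newick = ape::write.tree(ape::as.phylo(hc)))
}

#' N-way intersection counts of IR ortholog sets
#'
#' All 2^n - 1 exclusive intersection regions over ortholog groups:
#' region "a&b" counts groups IR in exactly species a and b.
#'
#' @param ir_sets named list of ortholog-group ID vectors (IR groups
#'   per species)
#' @return named integer vector of exclusive region counts
#' @export
vennCounts <- function(ir_sets) {
    n <- length(ir_sets)
    sp <- names(ir_sets)
    univ <- unique(unlist(ir_sets))
    member <- vapply(ir_sets, function(s) univ %in% s,
                     logical(length(univ)))
    if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, sp))
    key <- apply(member, 1, function(r) paste(sp[r], collapse = "&"))
    regions <- unlist(lapply(seq_len(n), function(k)
        utils::combn(sp, k, paste, collapse = "&")))
    out <- setNames(integer(length(regions)), regions)
    tab <- table(key)
    out[names(tab)] <- as.integer(tab)
    out
}

#' Correlation of IR-gene fraction with protein-coding gene count
#'
#' Pearson correlation between the per-species fraction of expressed
#' genes affected by IR and the number of protein-coding genes in the
#' genome, reported to 2 decimal places.
#'
#' @param summaries data.frame with columns \code{fraction_ir_genes}
#'   (percent) and \code{n_pc_genes}
#' @return Pearson r rounded to 2 dp
#' @export
correlateIRComplexity <- function(summaries) {
    stopifnot(nrow(summaries) >= 3)
    round(cor(summaries$fraction_ir_genes, summaries$n_pc_genes,
              method = "pearson"), 2)
}

#' Genomic summary of the five granulocyte study species
#'
#' Protein-coding gene counts per genome and the published fraction of
#' expressed genes affected by IR in granulocytes, for the
#' IR-vs-genome-complexity correlation.
#'
#' @return data.frame species/n_pc_genes/fraction_ir_genes
#' @export
speciesGenomeSummary <- function() {
    data.frame(
        species = c("human", "mouse", "dog", "chicken", "zebrafish"),
        n_pc_genes = c(20296, 22547, 19856, 15508, 25642),
        fraction_ir_genes = c(17.4, 13.6, 18.6, 40.8, 7.8),
        stringsAsFactors = FALSE)
}

#' Write an ortholog table / profile matrix as TSV
#' @param x data.frame or matrix
#' @param path file path
#' @export
writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = is.matrix(x))
    invisible(path)
}
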