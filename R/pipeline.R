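#' Pipeline configuration
#'
#' Layered configuration for the end-to-end analysis: defaults <
#' user-supplied values. Thresholds default to the IR-calling rules
#' (IR ratio >= 0.1, splicing depth >= 4, splicing depth + trimmed
#' intron depth >= 10, expressed at FPKM >= 1).
#'
#' @param ... overrides of the default fields; unknown keys are a
#'   validation error
#' @return list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(...) {
    defaults <- list(
        gtf = NULL, fasta = NULL, coverage = NULL, junctions = NULL,
        bam = NULL, orthologs = NULL, mirnas = NULL,
        ir_ratio_min = 0.1, splice_depth_min = 4, coverage_min = 10,
        fpkm_expressed = 1, trim_frac = 0.05, min_internal_reads = 2,
        synthetic = TRUE, n_genes = 200, n_species = 5,
        n_core = 20, kmeans_k = 4, seed = 1, out_dir = NULL)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(defaults, over)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Validate a pipeline configuration
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return character vector of violations (empty when valid)
#' @export
validateConfig <- function(config) {
    v <- character(0)
    num_pos <- c("ir_ratio_min", "splice_depth_min", "coverage_min",
                 "fpkm_expressed")
    for (f in num_pos)
        if (!is.numeric(config[[f]]) || config[[f]] < 0)
            v <- c(v, paste0(f, " must be a non-negative number"))
    if (config$ir_ratio_min > 1)
        v <- c(v, "ir_ratio_min must be <= 1")
    if (!config$synthetic) {
        for (f in c("gtf", "fasta")) {
            if (is.null(config[[f]]))
                v <- c(v, paste0(f, " required when synthetic = FALSE"))
            else if (!file.exists(config[[f]]))
                v <- c(v, paste0(f, " file not found: ", config[[f]]))
        }
    }
    v
}

.logLine <- function(log, stage, msg) {
    line <- sprintf("%s\t%s\t%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
    if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
    message(line)
}

## stable hash of the configuration for provenance stamping
.configHash <- function(config) {
    s <- paste(names(config),
               vapply(config, function(x) paste(format(x), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
    sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full synthetic end-to-end analysis
#'
#' Simulates a multi-species panel, quantifies IR, characterizes
#' retained introns (features, splice-site strength), analyses 3' UTR
#' miRNA sites and word enrichment, gene-pair architecture,
#' cross-species conservation, and the sponge dose-response; writes
#' every output table plus a JSON report into \code{out_dir}. Stages
#' run in dependency order; a stage failure halts with the stage name;
#' reruns with the same config are identical for deterministic stages.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return named list of stage results (invisibly writes tables when
#'   \code{out_dir} is set)
#' @export
runPipeline <- function(config = pipelineConfig()) {
    viol <- validateConfig(config)
    if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
    out_dir <- config$out_dir
    log <- NULL
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        log <- file.path(out_dir, "pipeline.log")
    }
    stamp <- .configHash(config)
    res <- list(config_hash = stamp, seed = config$seed)
    stage <- function(name, expr) {
        .logLine(log, name, "start")
        r <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        .logLine(log, name, "done")
        r
    }
    emit <- function(x, fname) {
        if (!is.null(out_dir)) writeTSV(x, file.path(out_dir, fname))
    }

    scfg <- simConfig(n_genes = config$n_genes, seed = config$seed)
    panel <- stage("simulate", simulateSpeciesPanel(
        scfg, n_species = config$n_species, n_core = config$n_core))

    gene_ir_list <- list()
    sp1 <- NULL
    for (sp in names(panel$species)) {
        sim <- panel$species[[sp]]
        ev <- stage(paste0("quantify:", sp), {
            ev <- simulateEvidence(sim, scfg)
            calls <- irCalls(sim$annotation, ev$coverage, ev$junctions,
                             trim_frac = config$trim_frac,
                             min_internal_reads = config$min_internal_reads,
                             ir_ratio_min = config$ir_ratio_min,
                             splice_depth_min = config$splice_depth_min,
                             coverage_min = config$coverage_min)
            kbp <- mergedExonicKbp(sim$annotation)
            fpkm <- computeFPKM(ev$gene_counts, kbp, ev$total_reads)
            gi <- aggregateGeneIR(calls, fpkm, config$fpkm_expressed)
            emit(calls, paste0("ir_calls_", sp, ".tsv"))
            emit(gi, paste0("gene_ir_", sp, ".tsv"))
            list(calls = calls, gene_ir = gi, sim = sim)
        })
        gene_ir_list[[sp]] <- ev$gene_ir
        if (is.null(sp1)) sp1 <- ev
    }

    res$features <- stage("features", {
        ft <- intronFeatureTable(sp1$sim$annotation, sp1$sim$genome,
                                 sp1$calls)
        emit(ft, "intron_features.tsv")
        ft
    })

    res$maxent <- stage("maxent", {
        win <- extractSiteWindows(sp1$sim$annotation, sp1$sim$genome)
        ret <- res$features$is_retained
        dm <- trainMaxEnt(win$donor[!ret], kind = "donor")
        am <- trainMaxEnt(win$acceptor[!ret], kind = "acceptor")
        ds <- scoreWindows(dm, win$donor)
        as <- scoreWindows(am, win$acceptor)
        ps <- pairScores(ds, as, ret)
        emit(data.frame(intron_id = names(ds), donor_bits = ds,
                        acceptor_bits = as, retained = ret),
             "splice_scores.tsv")
        ps
    })

    res$mirna <- stage("mirna", {
        utrs <- utr3Sequences(sp1$sim$annotation, sp1$sim$genome)
        sites <- scanSeedSites(utrs, sp1$sim$mirnas)
        ir_genes <- sp1$gene_ir$gene_id[sp1$gene_ir$is_ir_gene]
        counts <- table(factor(sites$gene_id, levels = names(utrs)))
        cmp <- siteCountComparison(
            as.numeric(counts[names(counts) %in% ir_genes]),
            as.numeric(counts[!names(counts) %in% ir_genes]))
        fg <- utrs[names(utrs) %in% ir_genes]
        enr <- wordEnrichment(fg, utrs)
        emit(sites, "seed_sites.tsv")
        emit(utils::head(enr, 50), "word_enrichment.tsv")
        list(site_comparison = cmp, enrichment_top = utils::head(enr, 10))
    })

    res$architecture <- stage("architecture", {
        pairs <- classifyAdjacentPairs(sp1$sim$annotation)
        ir_genes <- sp1$gene_ir$gene_id[sp1$gene_ir$is_ir_gene]
        emit(pairs, "gene_pairs.tsv")
        list(pairs = pairs,
             bidir_ir = bidirectionalFraction(pairs, ir_genes),
             bidir_all = bidirectionalFraction(pairs),
             hist = retainedCountHistogram(sp1$gene_ir))
    })

    res$conservation <- stage("conserve", {
        m <- buildProfileMatrix(gene_ir_list, panel$orthologs)
        mq <- quantileNormalize(m)
        cl <- kmeansRows(mq, config$kmeans_k, seed = config$seed)
        hc <- hclusterSpecies(mq)
        ir_sets <- lapply(names(gene_ir_list), function(sp) {
            o <- panel$orthologs[panel$orthologs$species == sp, ]
            gi <- gene_ir_list[[sp]]
            o$group_id[o$gene_id %in% gi$gene_id[gi$is_ir_gene]]
        })
        names(ir_sets) <- names(gene_ir_list)
        vc <- vennCounts(ir_sets)
        emit(m, "ir_profile_matrix.tsv")
        if (!is.null(out_dir)) {
            writeLines(hc$newick, file.path(out_dir, "species_tree.nwk"))
            jsonlite::write_json(as.list(vc),
                                 file.path(out_dir, "venn_counts.json"),
                                 auto_unbox = TRUE)
        }
        list(matrix = m, clusters = cl, newick = hc$newick, venn = vc)
    })

    res$sponge <- stage("sponge", {
        dr <- spongeDoseResponse(spongeParams())
        emit(dr$curve, "sponge_dose_response.tsv")
        dr
    })

    res$correlation <- correlateIRComplexity(speciesGenomeSummary())
    if (!is.null(out_dir)) {
        report <- list(
            config_hash = stamp, seed = config$seed,
            n_species = length(gene_ir_list),
            fraction_ir = as.list(vapply(gene_ir_list, function(g)
                attr(g, "fraction_ir"), numeric(1))),
            venn_all_species = unname(
                res$conservation$venn[paste(names(gene_ir_list),
                                            collapse = "&")]),
            ir_complexity_r = res$correlation,
            sponge_derepression = res$sponge$derepression_ratio)
        jsonlite::write_json(report, file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(res)
}
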