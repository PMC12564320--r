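#' Validate a pipeline run configuration
#'
#' Reads a JSON configuration, applies defaults and checks paths and
#' thresholds, collecting every problem into one error message. A seed is
#' mandatory: runs must be reproducible by construction even though the
#' analysis stages themselves are deterministic.
#'
#' Recognized fields: `gene_sets` (named map set name -> gene-list file),
#' `background_set` (name of the whole-proteome universe set),
#' `annotate` (list of `{target, annotation}` name pairs), `ladder` (TSV
#' path, optional), `presence`/`splits` (TSV paths), `pai_table`
#' (precomputed gene/pai TSV), `dnds_dir` (FASTA pair directory),
#' `dnds_table` (precomputed gene/species/dN/dS TSV), `di_table`
#' (precomputed gene/DI TSV), `edge_tables` (named map network name ->
#' edge TSV), `mtor_pathway_set`/`mtor_sensitive_set` (set names used for
#' hub classification), `min_conf` (default 0.9), `min_degree` (default
#' 5), `di_combiner` (`"mean"`/`"median"`), `seed` (required integer).
#' Precomputed index tables are first-class inputs so a published
#' supplement can drive the enrichment stage directly, without orthology
#' or alignment data.
#'
#' @param path JSON file path, or a list with the same fields.
#' @return validated config list with defaults filled in.
#' @export
validateConfig <- function(path) {
    cfg <- if (is.character(path)) {
        if (!file.exists(path))
            stop(sprintf("config file not found: %s", path))
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else if (is.list(path)) path else
        stop("'path' must be a file path or a list")
    errs <- character(0)
    if (is.null(cfg$seed))
        errs <- c(errs, "an explicit integer 'seed' is required")
    else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
        errs <- c(errs, "'seed' must be an integer")
    if (is.null(cfg$min_conf)) cfg$min_conf <- 0.9
    if (!is.numeric(cfg$min_conf) || cfg$min_conf < 0 || cfg$min_conf > 1)
        errs <- c(errs, "'min_conf' must lie in [0,1]")
    if (is.null(cfg$min_degree)) cfg$min_degree <- 5L
    if (!is.numeric(cfg$min_degree) || cfg$min_degree < 1)
        errs <- c(errs, "'min_degree' must be a positive integer")
    if (is.null(cfg$di_combiner)) cfg$di_combiner <- "mean"
    if (!cfg$di_combiner %in% c("mean", "median"))
        errs <- c(errs, "'di_combiner' must be 'mean' or 'median'")
    pathFields <- c("ladder", "presence", "splits", "pai_table",
                    "dnds_table", "di_table")
    for (f in pathFields) {
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            errs <- c(errs, sprintf("'%s' file not found: %s", f, cfg[[f]]))
    }
    if (!is.null(cfg$dnds_dir) && !dir.exists(cfg$dnds_dir))
        errs <- c(errs, sprintf("'dnds_dir' not found: %s", cfg$dnds_dir))
    for (f in c("gene_sets", "edge_tables")) {
        if (!is.null(cfg[[f]])) {
            if (is.null(names(cfg[[f]])) || any(!nzchar(names(cfg[[f]]))))
                errs <- c(errs, sprintf("'%s' must be a named map", f))
            miss <- !vapply(cfg[[f]], file.exists, logical(1))
            if (any(miss))
                errs <- c(errs, sprintf("'%s' file(s) not found: %s", f,
                                        paste(unlist(cfg[[f]][miss]),
                                              collapse = ", ")))
        }
    }
    if (length(errs))
        stop(paste(c("invalid configuration:", paste(" -", errs)),
                   collapse = "\n"))
    cfg$seed <- as.integer(cfg$seed)
    cfg$min_degree <- as.integer(cfg$min_degree)
    cfg
}

.stageLog <- function(report, stage, status, detail = "") {
    report$stages[[stage]] <- list(status = status, detail = detail)
    report
}

#' Run the full evolutionary profiling pipeline
#'
#' Executes the available stages in order — gene sets (Venn partition,
#' annotation fractions), phylostratigraphy (PAI assignment), divergence
#' (NG86 dN/dS and DI), enrichment (binned distributions, per-bin
#' chi-square with BH adjustment, set-level mean summary) and network
#' (confidence filtering, degrees, hubs, hub comparison) — writing every
#' result surface as TSV/JSON under `outDir`. Stages whose inputs are
#' absent from the configuration are skipped and recorded in the run
#' report, never silently dropped. Rerunning an identical configuration
#' reproduces byte-identical outputs.
#'
#' @param config validated configuration from [validateConfig()] (or a
#'   path/list, validated on entry).
#' @param outDir output directory (created if missing).
#' @return run report list (manifest with MD5 checksums, stage status,
#'   warnings), also written to `run_report.json`; invisibly.
#' @export
runProfile <- function(config, outDir) {
    cfg <- if (is.list(config) && !is.null(config$seed) &&
               is.integer(config$seed)) config else validateConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    report <- list(stages = list(), warnings = character(0),
                   outputs = character(0))
    emit <- function(df, name) {
        p <- file.path(outDir, name)
        writeTsv(df, p)
        report$outputs <<- c(report$outputs, p)
        p
    }
    ladder <- readLadder(cfg$ladder)

    ## --- gene sets ---------------------------------------------------
    sets <- NULL
    if (!is.null(cfg$gene_sets)) {
        sets <- lapply(names(cfg$gene_sets), function(nm)
            readGeneList(cfg$gene_sets[[nm]], name = nm))
        names(sets) <- names(cfg$gene_sets)
        sizes <- data.frame(set = names(sets),
                            size = vapply(sets, length, integer(1)),
                            stringsAsFactors = FALSE)
        emit(sizes, "gene_set_sizes.tsv")
        vennSets <- sets[setdiff(names(sets), cfg$background_set)]
        if (length(vennSets) >= 2L && length(vennSets) <= 5L)
            emit(vennPartition(unname(vennSets)), "venn_partition.tsv")
        if (!is.null(cfg$annotate)) {
            ann <- do.call(rbind, lapply(cfg$annotate, function(a) {
                af <- annotateFraction(sets[[a$target]], sets[[a$annotation]])
                data.frame(target = a$target, annotation = a$annotation,
                           count = af$count, total = af$total,
                           percent = af$percent, stringsAsFactors = FALSE)
            }))
            emit(ann, "annotation_fractions.tsv")
        }
        report <- .stageLog(report, "geneset", "done",
                            sprintf("%d sets loaded", length(sets)))
    } else report <- .stageLog(report, "geneset", "skipped", "no gene_sets")

    ## --- phylostratigraphy -------------------------------------------
    pai <- NULL
    if (!is.null(cfg$presence) && !is.null(cfg$splits)) {
        pai <- assignPAI(readTsv(cfg$presence), readTsv(cfg$splits), ladder)
        emit(pai, "pai_assignments.tsv")
        report <- .stageLog(report, "phylostrat", "done",
                            sprintf("%d genes assigned", nrow(pai)))
    } else if (!is.null(cfg$pai_table)) {
        pai <- readTsv(cfg$pai_table)
        if (!all(c("gene", "pai") %in% names(pai)))
            stop("pai_table must have columns 'gene' and 'pai'")
        pai$gene <- normalizeId(as.character(pai$gene))
        report <- .stageLog(report, "phylostrat", "done",
                            "precomputed PAI table loaded")
    } else report <- .stageLog(report, "phylostrat", "skipped",
                               "no presence/splits or pai_table")

    ## --- divergence ---------------------------------------------------
    di <- NULL
    if (!is.null(cfg$dnds_dir)) {
        pairTab <- dndsTable(cfg$dnds_dir)
        emit(pairTab, "dnds_pairs.tsv")
        di <- computeDI(pairTab, combiner = cfg$di_combiner)
        emit(di, "divergence_index.tsv")
        report <- .stageLog(report, "divergence", "done",
                            sprintf("%d pairs, %d genes", nrow(pairTab),
                                    nrow(di)))
    } else if (!is.null(cfg$dnds_table)) {
        pairTab <- readDnDsTable(cfg$dnds_table)
        di <- computeDI(pairTab, combiner = cfg$di_combiner)
        emit(di, "divergence_index.tsv")
        report <- .stageLog(report, "divergence", "done",
                            "precomputed dN/dS table combined into DI")
    } else if (!is.null(cfg$di_table)) {
        di <- readTsv(cfg$di_table)
        if (!all(c("gene", "DI") %in% names(di)))
            stop("di_table must have columns 'gene' and 'DI'")
        di$gene <- normalizeId(as.character(di$gene))
        report <- .stageLog(report, "divergence", "done",
                            "precomputed DI table loaded")
    } else report <- .stageLog(report, "divergence", "skipped",
                               "no dN/dS inputs")

    ## --- enrichment ----------------------------------------------------
    if (!is.null(sets) && !is.null(cfg$background_set) &&
        cfg$background_set %in% names(sets) && (!is.null(pai) || !is.null(di))) {
        bgSet <- sets[[cfg$background_set]]
        testSets <- sets[setdiff(names(sets), cfg$background_set)]
        schemes <- list()
        if (!is.null(pai))
            schemes$pai <- list(scheme = paiBinScheme(nStrata(ladder)),
                                values = stats::setNames(pai$pai, pai$gene))
        if (!is.null(di))
            schemes$di <- list(scheme = diBinScheme(),
                               values = stats::setNames(di$DI, di$gene))
        for (ix in names(schemes)) {
            sc <- schemes[[ix]]
            bgVals <- sc$values[names(sc$values) %in% members(bgSet)]
            if (!length(bgVals)) next
            bgBins <- binValues(bgVals, sc$scheme)
            for (nm in names(testSets)) {
                vals <- sc$values[names(sc$values) %in% members(testSets[[nm]])]
                if (!length(vals)) next
                tab <- perBinTest(binValues(vals, sc$scheme), bgBins)
                emit(tab, sprintf("enrichment_%s_%s.tsv", ix, nm))
            }
        }
        emit(summarizeSets(sets, pai = pai, di = di), "set_summary.tsv")
        report <- .stageLog(report, "enrichment", "done",
                            sprintf("background '%s'", cfg$background_set))
    } else report <- .stageLog(report, "enrichment", "skipped",
                               "needs gene sets, background_set and indices")

    ## --- network --------------------------------------------------------
    if (!is.null(cfg$edge_tables)) {
        hubTabs <- list()
        for (nm in names(cfg$edge_tables)) {
            edges <- readEdgeTable(cfg$edge_tables[[nm]])
            g <- filterEdges(edges, minConf = cfg$min_conf)
            el <- igraph::as_edgelist(g)
            emit(data.frame(node_a = el[, 1L], node_b = el[, 2L],
                            stringsAsFactors = FALSE),
                 sprintf("network_%s_edges.tsv", nm))
            deg <- igraph::degree(g)
            nodeTab <- data.frame(node = names(deg),
                                  degree = as.integer(deg),
                                  stringsAsFactors = FALSE)
            nodeTab <- nodeTab[order(-nodeTab$degree, nodeTab$node), ]
            rownames(nodeTab) <- NULL
            emit(nodeTab, sprintf("network_%s_nodes.tsv", nm))
            writeSif(g, file.path(outDir, sprintf("network_%s.sif", nm)))
            report$outputs <- c(report$outputs,
                                file.path(outDir, sprintf("network_%s.sif", nm)))
            hubTabs[[nm]] <- hubGenes(g, minDegree = cfg$min_degree)
            emit(hubTabs[[nm]], sprintf("network_%s_hubs.tsv", nm))
        }
        if (length(hubTabs) == 2L && !is.null(sets) &&
            !is.null(cfg$mtor_pathway_set) && !is.null(cfg$mtor_sensitive_set)) {
            cls <- classifyHubs(hubTabs[[1L]], hubTabs[[2L]],
                                sets[[cfg$mtor_pathway_set]],
                                sets[[cfg$mtor_sensitive_set]])
            emit(cls$table, "hub_comparison.tsv")
            cnt <- data.frame(class = names(cls$counts),
                              count = as.integer(cls$counts),
                              stringsAsFactors = FALSE)
            emit(cnt, "hub_class_counts.tsv")
        }
        report <- .stageLog(report, "network", "done",
                            sprintf("%d network(s)", length(cfg$edge_tables)))
    } else report <- .stageLog(report, "network", "skipped", "no edge_tables")

    report$manifest <- data.frame(
        file = basename(report$outputs),
        md5 = unname(tools::md5sum(report$outputs)),
        stringsAsFactors = FALSE)
    jsonlite::write_json(
        list(stages = report$stages,
             manifest = report$manifest,
             seed = cfg$seed),
        file.path(outDir, "run_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
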