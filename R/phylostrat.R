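#' The default 16-level phylostratum ladder of the human lineage
#'
#' Strata run from "Cellular Organisms" (index 1, root-most) to
#' "Homo sapiens" (index 16, terminal). A gene whose most distant
#' ortholog-bearing lineage split at stratum k receives PAI = k; smaller
#' PAI therefore means a more ancient origin.
#'
#' @return a [PhylostratumLadder-class] with 16 strata.
#' @examples
#' defaultLadder()
#' @export
defaultLadder <- function() {
    new("PhylostratumLadder",
        index = 1:16,
        taxon = c("Cellular Organisms", "Eukaryota", "Metazoa", "Chordata",
                  "Craniata", "Vertebrata", "Euteleostomi", "Mammalia",
                  "Eutheria", "Euarchontoglires", "Primates", "Haplorrhini",
                  "Catarrhini", "Hominidae", "Homo", "Homo sapiens"))
}

#' Read a phylostratum ladder from a two-column TSV
#'
#' Expects columns `index` and `taxon` (header required). Indices must be
#' contiguous ascending from 1 and taxa unique.
#'
#' @param path TSV file path; if `NULL`, the built-in 16-level ladder is
#'   returned.
#' @return a [PhylostratumLadder-class].
#' @export
readLadder <- function(path = NULL) {
    if (is.null(path))
        return(defaultLadder())
    df <- readTsv(path)
    need <- c("index", "taxon")
    if (!all(need %in% names(df)))
        stop("ladder file must have columns 'index' and 'taxon'")
    ord <- order(df$index)
    new("PhylostratumLadder", index = as.integer(df$index[ord]),
        taxon = as.character(df$taxon[ord]))
}

#' Stratum label lookup
#'
#' @param ladder a [PhylostratumLadder-class].
#' @param index integer stratum indices.
#' @return character taxon labels.
#' @export
stratumLabel <- function(ladder, index) {
    stopifnot(is(ladder, "PhylostratumLadder"))
    if (any(index < 1L | index > nStrata(ladder)))
        stop("stratum index out of ladder range")
    ladder@taxon[index]
}

#' Assign phylostratigraphic age indices from ortholog presence
#'
#' Each species in the reference panel is mapped (ahead of time) to the
#' ladder stratum at which its lineage diverges from the human lineage
#' (`split_index`). A gene's PAI is the minimum split index over the
#' species in which it has an ortholog: the most distantly related
#' ortholog-bearing lineage dates the gene's origin. Genes with an empty
#' presence row are excluded (not imputed) and counted in the attached
#' summary.
#'
#' @param presence `data.frame` with columns `gene` and `species` (one row
#'   per gene-species ortholog occurrence), or a list mapping gene to a
#'   character vector of species.
#' @param splits `data.frame` with columns `species` and `split_index`.
#' @param ladder a [PhylostratumLadder-class]; split indices must lie in
#'   its range.
#' @return `data.frame` with columns `gene` and `pai`, one row per gene with
#'   at least one ortholog; attribute `excluded` holds genes dropped for
#'   empty presence.
#' @examples
#' splits <- data.frame(species = c("yeast", "zebrafish"),
#'                      split_index = c(2L, 7L))
#' pres <- data.frame(gene = c("G1", "G1"), species = c("yeast", "zebrafish"))
#' assignPAI(pres, splits)
#' @export
assignPAI <- function(presence, splits, ladder = defaultLadder()) {
    stopifnot(is(ladder, "PhylostratumLadder"))
    if (is.list(presence) && !is.data.frame(presence)) {
        presence <- data.frame(
            gene = rep(names(presence), lengths(presence)),
            species = unlist(presence, use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    need <- c("gene", "species")
    if (!all(need %in% names(presence)))
        stop("presence table must have columns 'gene' and 'species'")
    if (!all(c("species", "split_index") %in% names(splits)))
        stop("splits table must have columns 'species' and 'split_index'")
    if (any(splits$split_index < 1L | splits$split_index > nStrata(ladder)))
        stop("split_index outside ladder range")
    if (anyDuplicated(splits$species))
        stop("duplicate species in splits table")
    unknown <- setdiff(unique(presence$species), splits$species)
    if (length(unknown))
        stop(sprintf("species without split index: %s",
                     paste(sort(unknown), collapse = ", ")))
    si <- stats::setNames(as.integer(splits$split_index), splits$species)
    gene <- normalizeId(as.character(presence$gene))
    pai <- tapply(si[presence$species], gene, min)
    out <- data.frame(gene = names(pai), pai = as.integer(pai),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "excluded") <- character(0)
    out
}

#' PAI distribution of a gene set
#'
#' Counts set members per stratum over the genes that have a PAI
#' assignment; members without an assignment are excluded and reported in
#' the `coverage` attribute.
#'
#' @param assignments `data.frame` from [assignPAI()] (columns `gene`,
#'   `pai`) or any table with those columns.
#' @param geneSet a [GeneSet-class]; if `NULL`, all assigned genes are used.
#' @param ladder a [PhylostratumLadder-class] defining the stratum range.
#' @return `data.frame` with columns `pai`, `taxon`, `count`, `proportion`
#'   (and `percent`, one decimal); counts sum to the number of covered
#'   members.
#' @export
paiDistribution <- function(assignments, geneSet = NULL,
                            ladder = defaultLadder()) {
    stopifnot(is(ladder, "PhylostratumLadder"))
    if (!all(c("gene", "pai") %in% names(assignments)))
        stop("assignments must have columns 'gene' and 'pai'")
    if (!is.null(geneSet)) {
        stopifnot(is(geneSet, "GeneSet"))
        keep <- assignments$gene %in% members(geneSet)
        if (!any(keep))
            stop(sprintf("no overlap between assignments and set '%s'",
                         setName(geneSet)))
        assignments <- assignments[keep, , drop = FALSE]
    }
    k <- nStrata(ladder)
    if (any(assignments$pai < 1L | assignments$pai > k))
        stop("PAI value outside ladder range")
    counts <- tabulate(assignments$pai, nbins = k)
    out <- data.frame(pai = seq_len(k), taxon = ladder@taxon, count = counts,
                      proportion = counts / sum(counts),
                      percent = round(100 * counts / sum(counts), 1),
                      stringsAsFactors = FALSE)
    attr(out, "coverage") <- nrow(assignments)
    out
}

#' Map NCBI-style lineage strings onto ladder split indices
#'
#' Optional helper: given a semicolon-separated lineage string per species
#' (root first), the split index is the deepest ladder taxon named in the
#' lineage. Species whose lineage names no ladder taxon get index 1
#' (only "Cellular Organisms" shared).
#'
#' @param lineages named character vector, species -> lineage string.
#' @param ladder a [PhylostratumLadder-class].
#' @return `data.frame` with columns `species` and `split_index`.
#' @export
lineageToSplits <- function(lineages, ladder = defaultLadder()) {
    stopifnot(is(ladder, "PhylostratumLadder"))
    split_index <- vapply(lineages, function(lin) {
        taxa <- trimws(strsplit(lin, ";", fixed = TRUE)[[1L]])
        hits <- match(taxa, ladder@taxon)
        if (all(is.na(hits))) 1L else max(hits, na.rm = TRUE)
    }, integer(1))
    data.frame(species = names(lineages), split_index = unname(split_index),
               stringsAsFactors = FALSE)
}
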