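#' Normalize a raw gene identifier
#'
#' Gene symbols coming from curated disease databases are matched purely as
#' published symbols: normalization is whitespace trimming plus uppercasing,
#' nothing else (no alias or symbol-history resolution, which would silently
#' change intersection counts between published lists). The operation is
#' idempotent.
#'
#' @param raw character vector of raw symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalizeId(c("mtor ", "TP53"))
#' @export
normalizeId <- function(raw) {
    if (!is.character(raw))
        stop("'raw' must be character")
    out <- toupper(trimws(raw))
    bad <- which(!nzchar(out))
    if (length(bad))
        stop(sprintf("empty gene identifier at position(s): %s",
                     paste(bad, collapse = ", ")))
    ws <- which(grepl("[[:space:]]", out))
    if (length(ws))
        stop(sprintf("internal whitespace in identifier at position(s): %s",
                     paste(ws, collapse = ", ")))
    out
}

#' Construct a GeneSet from symbols
#'
#' Symbols are normalized with [normalizeId()] and deduplicated; the number
#' of duplicates dropped is reported via a message when `quiet = FALSE`.
#'
#' @param name set label (unique within a run).
#' @param symbols character vector of raw symbols.
#' @param source free-text provenance.
#' @param quiet suppress the duplicate-drop message.
#' @return a [GeneSet-class] object.
#' @examples
#' GeneSet("demo", c("TP53", "tp53", "MTOR"))
#' @export
GeneSet <- function(name, symbols, source = "", quiet = TRUE) {
    norm <- normalizeId(symbols)
    dropped <- sum(duplicated(norm))
    if (dropped > 0L && !quiet)
        message(sprintf("GeneSet '%s': dropped %d duplicate symbol(s)",
                        name, dropped))
    new("GeneSet", name = as.character(name), members = unique(norm),
        source = as.character(source))
}

#' Read a gene list file into a GeneSet
#'
#' Accepts one-symbol-per-line plain text or a single-column CSV/TSV.  A
#' header line is auto-detected: if the first token re-occurs nowhere and
#' matches a common header word (`gene`, `symbol`, `gene_symbol`, `id`,
#' case-insensitive) it is dropped.  Symbols are normalized and
#' deduplicated; blank lines are ignored.
#'
#' @param path file path.
#' @param name set label; defaults to the file base name.
#' @param source provenance string; defaults to `path`.
#' @param quiet suppress the duplicate-drop message.
#' @return a [GeneSet-class].
#' @export
readGeneList <- function(path, name = NULL, source = NULL, quiet = TRUE) {
    if (!file.exists(path))
        stop(sprintf("gene list file not found: %s", path))
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    if (is.null(source))
        source <- path
    lines <- readLines(path, warn = FALSE)
    # single-column CSV/TSV: strip a trailing delimiter, take first field
    toks <- trimws(vapply(strsplit(lines, "[,\t]"), function(x)
        if (length(x)) x[[1L]] else "", character(1)))
    toks <- toks[nzchar(toks)]
    if (!length(toks))
        stop(sprintf("no parseable gene symbols in %s", path))
    if (length(toks) > 1L &&
        tolower(toks[1L]) %in% c("gene", "genes", "symbol", "gene_symbol",
                                 "genesymbol", "id", "gene_id"))
        toks <- toks[-1L]
    GeneSet(name, toks, source = source, quiet = quiet)
}

#' Venn partition of 2-5 gene sets
#'
#' Computes the complete disjoint partition of the union of the input sets
#' over all 2^k - 1 membership regions.  Region keys are the participating
#' set names joined with `"&"` in input-set order; empty regions are
#' reported with size 0.  Members within a region are sorted
#' lexicographically for reproducible output.
#'
#' @param sets list of [GeneSet-class] objects (2 to 5, distinct names).
#' @return a `data.frame` with columns `region`, `degree` (number of sets in
#'   the region), `size`, and `members` (comma-joined); the union of the
#'   regions equals the union of the inputs.
#' @examples
#' a <- GeneSet("A", c("TP53", "MTOR"))
#' b <- GeneSet("B", c("MTOR", "EGFR"))
#' vennPartition(list(a, b))
#' @export
vennPartition <- function(sets) {
    if (!is.list(sets) || length(sets) < 2L || length(sets) > 5L)
        stop("'sets' must be a list of 2 to 5 GeneSet objects")
    if (!all(vapply(sets, is, logical(1), class2 = "GeneSet")))
        stop("all elements of 'sets' must be GeneSet objects")
    nms <- vapply(sets, setName, character(1))
    if (anyDuplicated(nms))
        stop("duplicate set names in 'sets'")
    k <- length(sets)
    universe <- sort(unique(unlist(lapply(sets, members))))
    member <- vapply(sets, function(s) universe %in% members(s),
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    # membership pattern per element -> region key
    pattern <- apply(member, 1L, function(row)
        paste(nms[row], collapse = "&"))
    combos <- unlist(lapply(seq_len(k), function(d)
        utils::combn(seq_len(k), d, FUN = function(ix)
            paste(nms[ix], collapse = "&"), simplify = TRUE)))
    degree <- unlist(lapply(seq_len(k), function(d)
        rep(d, choose(k, d))))
    sizes <- integer(length(combos))
    memberStr <- character(length(combos))
    for (i in seq_along(combos)) {
        elems <- universe[pattern == combos[i]]
        sizes[i] <- length(elems)
        memberStr[i] <- paste(elems, collapse = ",")
    }
    data.frame(region = combos, degree = degree, size = sizes,
               members = memberStr, stringsAsFactors = FALSE)
}

#' Pairwise intersection size of two gene sets
#'
#' @param a,b [GeneSet-class] objects.
#' @return integer intersection size.
#' @export
intersectionSize <- function(a, b) {
    stopifnot(is(a, "GeneSet"), is(b, "GeneSet"))
    length(intersect(members(a), members(b)))
}

#' Fraction of a gene set covered by an annotation set
#'
#' The gene-set accounting used to report statements of the form "49.4%
#' (541 out of 1095) of the genes from set X are associated with Y": the
#' count is the intersection size, the fraction its share of the target
#' set, and `percent` that share rounded to one decimal.
#'
#' @param target [GeneSet-class] whose coverage is reported.
#' @param annotation [GeneSet-class] doing the annotating.
#' @return list with `count`, `total`, `fraction` and `percent`
#'   (one-decimal percent).
#' @examples
#' tgt <- GeneSet("t", c("A1", "B1", "C1"))
#' ann <- GeneSet("a", c("B1", "C1", "D1"))
#' annotateFraction(tgt, ann)
#' @export
annotateFraction <- function(target, annotation) {
    stopifnot(is(target, "GeneSet"), is(annotation, "GeneSet"))
    if (length(target) == 0L)
        stop("empty target set")
    count <- length(intersect(members(target), members(annotation)))
    total <- length(target)
    list(count = count, total = total, fraction = count / total,
         percent = pctValue(count, total))
}

#' Deduplicated union of gene sets
#'
#' Used, e.g., to build a combined disease set from two source lists.  When
#' `expectedSize` is given and the union size differs, a warning is issued
#' (published combined-set denominators are not always reconstructible from
#' the source lists alone).
#'
#' @param sets list of [GeneSet-class] objects.
#' @param name label of the combined set.
#' @param expectedSize optional integer; warn when the union size differs.
#' @return a [GeneSet-class].
#' @export
unionSet <- function(sets, name, expectedSize = NULL) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    u <- unique(unlist(lapply(sets, members)))
    if (!is.null(expectedSize) && length(u) != expectedSize)
        warning(sprintf("union '%s' has %d genes, expected %d",
                        name, length(u), expectedSize))
    GeneSet(name, u, source = paste(vapply(sets, setName, character(1)),
                                    collapse = " + "))
}
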