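#' @import methods
NULL

#' GeneSet: a named collection of normalized gene symbols
#'
#' A `GeneSet` holds a unique, uppercase-normalized vector of HGNC-style gene
#' symbols together with a set name and a free-text provenance string.
#' Membership is the only information carried; no ordering semantics are
#' attached beyond the lexicographic order used for reproducible output.
#'
#' @slot name single character label, unique within an analysis run.
#' @slot members character vector of unique normalized symbols.
#' @slot source free-text provenance (file path, database release, ...).
#'
#' @seealso [GeneSet()], [readGeneList()], [vennPartition()]
#' @exportClass GeneSet
setClass("GeneSet",
    representation(name = "character", members = "character",
                   source = "character"),
    prototype(name = NA_character_, members = character(0), source = ""))

setValidity("GeneSet", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (anyDuplicated(object@members))
        msg <- c(msg, "duplicate members after normalization")
    if (length(object@members) && any(object@members != toupper(trimws(object@members))))
        msg <- c(msg, "members must be normalized (uppercase, no flanking whitespace)")
    if (length(object@members) && any(grepl("[[:space:]]", object@members)))
        msg <- c(msg, "members must not contain internal whitespace")
    if (length(msg)) msg else TRUE
})

#' PhylostratumLadder: the ordered taxon ladder used to date gene origin
#'
#' Strata are indexed contiguously from 1 (root-most, "Cellular Organisms")
#' to K (terminal stratum, "Homo sapiens" in the default 16-level ladder).
#' A gene's phylostratigraphic age index (PAI) is a stratum index on this
#' ladder; smaller PAI means older evolutionary origin.
#'
#' @slot index integer vector 1..K, contiguous ascending.
#' @slot taxon character vector of unique stratum labels.
#'
#' @seealso [defaultLadder()], [readLadder()], [assignPAI()]
#' @exportClass PhylostratumLadder
setClass("PhylostratumLadder",
    representation(index = "integer", taxon = "character"))

setValidity("PhylostratumLadder", function(object) {
    msg <- character(0)
    k <- length(object@index)
    if (k == 0L)
        msg <- c(msg, "ladder must have at least one stratum")
    if (length(object@taxon) != k)
        msg <- c(msg, "'index' and 'taxon' must have equal length")
    if (k > 0L && !identical(object@index, seq_len(k)))
        msg <- c(msg, "stratum indices must be contiguous ascending from 1")
    if (anyDuplicated(object@taxon))
        msg <- c(msg, "duplicate taxon labels")
    if (length(msg)) msg else TRUE
})

#' BinScheme: an ordered, exhaustive, exclusive binning of index values
#'
#' Two flavours are used: an integer scheme (one bin per phylostratum, used
#' for PAI) and a divergence-index scheme with a dedicated zero bin,
#' width-0.2 interior bins and an open top bin (`{0}`, `(0,0.2)`,
#' `[0.2,0.4)`, ..., `[0.8,1)`, `[1,Inf)`).
#'
#' @slot type `"integer"` or `"di"`.
#' @slot labels ordered bin labels.
#' @slot breaks numeric breakpoints (integer scheme: the integer values;
#'   di scheme: interior breakpoints of the positive bins).
#'
#' @seealso [paiBinScheme()], [diBinScheme()], [binValues()]
#' @exportClass BinScheme
setClass("BinScheme",
    representation(type = "character", labels = "character",
                   breaks = "numeric"))

setValidity("BinScheme", function(object) {
    msg <- character(0)
    if (!object@type %in% c("integer", "di"))
        msg <- c(msg, "type must be 'integer' or 'di'")
    if (anyDuplicated(object@labels))
        msg <- c(msg, "bin labels must be unique")
    if (length(msg)) msg else TRUE
})

#' NG86Result: Nei-Gojobori counts and distances for one codon-aligned pair
#'
#' Holds the fractional synonymous/nonsynonymous site counts (S, N; averaged
#' over the two sequences), the pathway-averaged observed differences
#' (Sd, Nd), the per-site proportions (pS, pN), the Jukes-Cantor corrected
#' distances (dS, dN) and their ratio omega = dN/dS. `flag` records the
#' boundary cases: `"ok"`, `"no-substitutions"` (identical sequences, omega
#' reported as 0), `"dN-zero"` (only synonymous change, omega = 0),
#' `"undefined-infinite"` (dS = 0 with dN > 0; omega is NA and the pair is
#' excluded from divergence-index averaging) and `"saturated"` (pS or pN at
#' or beyond 3/4, distance undefined).
#'
#' @slot gene,partner identifying labels.
#' @slot S,N,Sd,Nd,pS,pN,dS,dN,omega numeric scalars (NA where undefined).
#' @slot flag single status string.
#' @slot nCodons codon pairs retained after gap/stop/ambiguity filtering.
#' @slot nSkipped codon pairs dropped by that filtering.
#'
#' @seealso [ng86()], [computeDI()]
#' @exportClass NG86Result
setClass("NG86Result",
    representation(gene = "character", partner = "character",
                   S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
                   pS = "numeric", pN = "numeric", dS = "numeric", dN = "numeric",
                   omega = "numeric", flag = "character",
                   nCodons = "integer", nSkipped = "integer"))

setValidity("NG86Result", function(object) {
    msg <- character(0)
    if (!is.na(object@S) && object@S < 0) msg <- c(msg, "S must be >= 0")
    if (!is.na(object@N) && object@N < 0) msg <- c(msg, "N must be >= 0")
    for (sl in c("pS", "pN")) {
        v <- slot(object, sl)
        if (!is.na(v) && (v < 0 || v > 1))
            msg <- c(msg, sprintf("%s must lie in [0,1]", sl))
    }
    if (!is.na(object@dS) && object@dS < 0) msg <- c(msg, "dS must be >= 0")
    if (!is.na(object@dN) && object@dN < 0) msg <- c(msg, "dN must be >= 0")
    if (length(msg)) msg else TRUE
})
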