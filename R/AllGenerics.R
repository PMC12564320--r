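#' Accessors for evoprofiler classes
#'
#' `members()` returns the normalized symbols of a [GeneSet];
#' `setName()` its label; `nStrata()` the number of strata of a
#' [PhylostratumLadder]; `binLabels()` the ordered labels of a [BinScheme];
#' `omega()` the dN/dS ratio of an [NG86Result].
#'
#' @param x the object.
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname accessors
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

#' @rdname accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))

#' @rdname accessors
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("nStrata", "PhylostratumLadder", function(x) length(x@index))

#' @rdname accessors
#' @export
setMethod("binLabels", "BinScheme", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("omega", "NG86Result", function(x) x@omega)

#' @describeIn accessors number of members of a GeneSet.
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s': %d genes", object@name, length(object@members)))
    if (nzchar(object@source)) cat(sprintf(" [%s]", object@source))
    cat("\n")
    if (length(object@members)) {
        shown <- utils::head(sort(object@members), 6L)
        cat("  ", paste(shown, collapse = ", "),
            if (length(object@members) > 6L) ", ..." else "", "\n", sep = "")
    }
    invisible(NULL)
})

setMethod("show", "PhylostratumLadder", function(object) {
    cat(sprintf("PhylostratumLadder with %d strata: %s (1) ... %s (%d)\n",
                length(object@index), object@taxon[1L],
                object@taxon[length(object@taxon)], length(object@index)))
    invisible(NULL)
})

setMethod("show", "BinScheme", function(object) {
    cat(sprintf("BinScheme (%s) with %d bins: %s\n", object@type,
                length(object@labels), paste(object@labels, collapse = " ")))
    invisible(NULL)
})

setMethod("show", "NG86Result", function(object) {
    cat(sprintf("NG86Result %s ~ %s (%d codons, %d skipped)\n",
                object@gene, object@partner, object@nCodons, object@nSkipped))
    cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%.4f dN=%.4f omega=%s [%s]\n",
                object@S, object@N, object@Sd, object@Nd,
                ifelse(is.na(object@dS), NA, object@dS),
                ifelse(is.na(object@dN), NA, object@dN),
                ifelse(is.na(object@omega), "NA", sprintf("%.4f", object@omega)),
                object@flag))
    invisible(NULL)
})

#' Coerce an NG86Result to a one-row data.frame
#'
#' @param x an [NG86Result].
#' @param row.names,optional,... passed through for generic compatibility.
#' @return one-row `data.frame` with the counting and distance fields.
#' @export
as.data.frame.NG86Result <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene = x@gene, partner = x@partner, n_codons = x@nCodons,
               n_skipped = x@nSkipped, S = x@S, N = x@N, Sd = x@Sd, Nd = x@Nd,
               pS = x@pS, pN = x@pN, dS = x@dS, dN = x@dN, omega = x@omega,
               flag = x@flag, stringsAsFactors = FALSE)
}
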