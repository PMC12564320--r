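#' Bin scheme for integer phylostratum ages
#'
#' One bin per stratum, 1..K.
#'
#' @param K number of strata (default 16, the full human-lineage ladder).
#' @return a [BinScheme-class] of type `"integer"`.
#' @export
paiBinScheme <- function(K = 16L) {
    new("BinScheme", type = "integer", labels = as.character(seq_len(K)),
        breaks = as.numeric(seq_len(K)))
}

#' Bin scheme for divergence-index values
#'
#' A dedicated bin for exactly 0 (genes with no nonsynonymous change in any
#' pair), width-0.2 interior bins up to 1, and an open top bin: `{0}`,
#' `(0,0.2)`, `[0.2,0.4)`, `[0.4,0.6)`, `[0.6,0.8)`, `[0.8,1)`, `[1,Inf)`.
#' The 0, 0.2 and 1 edges are the thresholds used when reporting selection
#' regimes; interior edges are a declared convention.
#'
#' @return a [BinScheme-class] of type `"di"`.
#' @export
diBinScheme <- function() {
    new("BinScheme", type = "di",
        labels = c("0", "(0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                   "[0.8,1)", "[1,Inf)"),
        breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1, Inf))
}

#' Bin a vector of index values
#'
#' Assignment is exhaustive and exclusive: every finite non-negative value
#' falls in exactly one bin of the scheme.
#'
#' @param values named (by gene) or unnamed numeric vector; integer strata
#'   for an integer scheme, non-negative reals for the DI scheme.
#' @param scheme a [BinScheme-class].
#' @return `data.frame` with columns `bin`, `count`, `proportion`; attribute
#'   `total` holds the number of values; attribute `assignment` the per-value
#'   bin label.
#' @examples
#' binValues(c(0, 0.1, 1.5), diBinScheme())
#' @export
binValues <- function(values, scheme) {
    stopifnot(is(scheme, "BinScheme"))
    if (!length(values))
        stop("no values to bin")
    bad <- which(!is.finite(values) | values < 0)
    if (length(bad)) {
        who <- if (!is.null(names(values))) names(values)[bad] else bad
        stop(sprintf("negative or non-finite value for: %s",
                     paste(utils::head(who, 5L), collapse = ", ")))
    }
    if (scheme@type == "integer") {
        iv <- as.integer(round(values))
        if (any(abs(values - iv) > 1e-8) || any(iv < 1L) ||
            any(iv > length(scheme@labels))) {
            who <- if (!is.null(names(values))) names(values) else seq_along(values)
            off <- which(abs(values - iv) > 1e-8 | iv < 1L |
                         iv > length(scheme@labels))
            stop(sprintf("value outside integer scheme for: %s",
                         paste(utils::head(who[off], 5L), collapse = ", ")))
        }
        lab <- scheme@labels[iv]
    } else {
        lab <- ifelse(values == 0, scheme@labels[1L],
                      scheme@labels[1L + findInterval(values, scheme@breaks,
                                                      rightmost.closed = FALSE)])
    }
    counts <- table(factor(lab, levels = scheme@labels))
    out <- data.frame(bin = scheme@labels, count = as.integer(counts),
                      proportion = as.integer(counts) / length(values),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- length(values)
    attr(out, "assignment") <- stats::setNames(lab, names(values))
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across one family of per-bin
#' tests (one set, one scheme, one figure panel).
#'
#' @param pvals numeric vector of raw p-values in `[0,1]`.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(pvals) {
    if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Per-bin chi-square enrichment against a background distribution
#'
#' For each bin, the observed split of the gene set into (in-bin,
#' out-of-bin) is compared to the expected split under the background
#' proportions by a one-sample Pearson goodness-of-fit chi-square with one
#' degree of freedom (the set is treated as a draw from the background
#' universe, matching a design where expected numbers are computed from the
#' whole-proteome distribution). Raw p-values are Benjamini-Hochberg
#' adjusted across the testable bins of the scheme; significance stars are
#' `*` p_adj < 0.05, `**` p_adj < 0.01, `***` p_adj < 0.001. Bins with an
#' expected count of zero are reported untestable (`NA` statistics) and
#' excluded from the adjustment family.
#'
#' @param setCounts,backgroundCounts `data.frame`s from [binValues()] over
#'   the same scheme; the background total must be at least the set total.
#' @param correct apply the Yates continuity correction (off by default;
#'   expected counts in tested bins are typically large).
#' @return `data.frame` with per-bin columns `bin`, `observed`,
#'   `proportion_set`, `proportion_background`, `expected`, `chi2`, `p`,
#'   `p_adj`, `stars`, `testable`.
#' @export
perBinTest <- function(setCounts, backgroundCounts, correct = FALSE) {
    if (!identical(setCounts$bin, backgroundCounts$bin))
        stop("set and background use different bin schemes")
    nSet <- sum(setCounts$count)
    nBg <- sum(backgroundCounts$count)
    if (nBg < nSet)
        stop("background total must be at least the set total")
    p0 <- backgroundCounts$count / nBg
    expected <- p0 * nSet
    chi2 <- p <- rep(NA_real_, nrow(setCounts))
    testable <- expected > 0 & (nSet - expected) > 0
    for (i in which(testable)) {
        O <- c(setCounts$count[i], nSet - setCounts$count[i])
        E <- c(expected[i], nSet - expected[i])
        dev <- abs(O - E)
        if (correct) dev <- pmax(dev - 0.5, 0)
        chi2[i] <- sum(dev^2 / E)
        p[i] <- stats::pchisq(chi2[i], df = 1L, lower.tail = FALSE)
    }
    p_adj <- rep(NA_real_, length(p))
    p_adj[testable] <- bhAdjust(p[testable])
    stars <- ifelse(is.na(p_adj), "",
                    ifelse(p_adj < 0.001, "***",
                           ifelse(p_adj < 0.01, "**",
                                  ifelse(p_adj < 0.05, "*", ""))))
    data.frame(bin = setCounts$bin, observed = setCounts$count,
               proportion_set = setCounts$count / nSet,
               proportion_background = p0, expected = expected,
               chi2 = chi2, p = p, p_adj = p_adj, stars = stars,
               testable = testable, stringsAsFactors = FALSE)
}

#' Per-set mean PAI and DI summary
#'
#' One row per gene set with the mean phylostratigraphic age and mean
#' divergence index over the members covered by the respective index
#' tables, plus coverage counts. Means are reported to two decimals in the
#' `mean_pai`/`mean_di` columns (full precision in `mean_pai_raw`/
#' `mean_di_raw`).
#'
#' @param sets list of [GeneSet-class] objects.
#' @param pai `data.frame` with columns `gene`, `pai` (or `NULL`).
#' @param di `data.frame` with columns `gene`, `DI` (or `NULL`).
#' @return `data.frame` with columns `set`, `n_set`, `n_pai`, `mean_pai`,
#'   `n_di`, `mean_di` (and raw-precision companions).
#' @export
summarizeSets <- function(sets, pai = NULL, di = NULL) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    rows <- lapply(sets, function(s) {
        stopifnot(is(s, "GeneSet"))
        m <- members(s)
        pv <- if (!is.null(pai)) pai$pai[pai$gene %in% m] else numeric(0)
        dv <- if (!is.null(di)) di$DI[di$gene %in% m] else numeric(0)
        data.frame(set = setName(s), n_set = length(m),
                   n_pai = length(pv),
                   mean_pai = if (length(pv)) round(mean(pv), 2) else NA_real_,
                   mean_pai_raw = if (length(pv)) mean(pv) else NA_real_,
                   n_di = length(dv),
                   mean_di = if (length(dv)) round(mean(dv), 2) else NA_real_,
                   mean_di_raw = if (length(dv)) mean(dv) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
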