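# Nei-Gojobori (1986) dN/dS on codon alignments, plus the per-gene
# divergence index (DI) combining pairwise omega over Hominidae partners.
#
# Conventions (classic NG86):
#   * fractional site counting: at each codon position the synonymous
#     fraction is (synonymous non-stop neighbors)/(non-stop neighbors);
#     neighbors that would create a stop codon are excluded from both the
#     numerator and the denominator, so every position contributes one full
#     site and s + n = 3 per sense codon;
#   * observed differences are averaged over all substitution pathways
#     between the two codons, discarding pathways that pass through a stop;
#   * proportions are Jukes-Cantor corrected: d = -(3/4) ln(1 - 4p/3).

.ng86env <- new.env(parent = emptyenv())

.geneticCode <- function() {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    gc
}

.ng86tables <- function() {
    if (!is.null(.ng86env$built))
        return(invisible(.ng86env))
    code <- .geneticCode()
    stops <- names(code)[code == "*"]
    sense <- names(code)[code != "*"]
    bases <- c("A", "C", "G", "T")
    # per-codon synonymous site count under the stop-exclusion convention
    s <- vapply(sense, function(cod) {
        ch <- strsplit(cod, "")[[1L]]
        tot <- 0
        for (pos in 1:3) {
            syn <- 0L; counted <- 0L
            for (b in setdiff(bases, ch[pos])) {
                nb <- ch; nb[pos] <- b
                nbc <- paste(nb, collapse = "")
                if (nbc %in% stops) next
                counted <- counted + 1L
                if (code[[nbc]] == code[[cod]]) syn <- syn + 1L
            }
            if (counted > 0L) tot <- tot + syn / counted
        }
        tot
    }, numeric(1))
    nSense <- length(sense)
    SD <- matrix(0, nSense, nSense, dimnames = list(sense, sense))
    ND <- matrix(0, nSense, nSense, dimnames = list(sense, sense))
    FB <- matrix(FALSE, nSense, nSense, dimnames = list(sense, sense))
    for (i in seq_len(nSense)) {
        for (j in seq_len(nSense)) {
            if (i == j) next
            pc <- .pathwayCounts(sense[i], sense[j], code, stops)
            SD[i, j] <- pc$sd; ND[i, j] <- pc$nd; FB[i, j] <- pc$fallback
        }
    }
    .ng86env$code <- code
    .ng86env$stops <- stops
    .ng86env$sense <- sense
    .ng86env$s <- s
    .ng86env$SD <- SD
    .ng86env$ND <- ND
    .ng86env$FB <- FB
    .ng86env$built <- TRUE
    invisible(.ng86env)
}

# pathway-averaged (sd, nd) for one ordered codon pair; enumeration over all
# orderings of the differing positions, discarding stop-crossing pathways
.pathwayCounts <- function(a, b, code, stops) {
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    dpos <- which(ca != cb)
    k <- length(dpos)
    if (k == 0L)
        return(list(sd = 0, nd = 0, fallback = FALSE))
    orders <- .permutations(dpos)
    sdAcc <- ndAcc <- numeric(0)
    for (ord in orders) {
        cur <- ca
        sd <- nd <- 0L
        ok <- TRUE
        for (pos in ord) {
            nxt <- cur
            nxt[pos] <- cb[pos]
            nxtc <- paste(nxt, collapse = "")
            if (nxtc %in% stops) { ok <- FALSE; break }
            curc <- paste(cur, collapse = "")
            if (code[[curc]] == code[[nxtc]]) sd <- sd + 1L else nd <- nd + 1L
            cur <- nxt
        }
        if (ok) { sdAcc <- c(sdAcc, sd); ndAcc <- c(ndAcc, nd) }
    }
    if (!length(sdAcc))   # no stop-free pathway: raw differences count as nd
        return(list(sd = 0, nd = k, fallback = TRUE))
    list(sd = mean(sdAcc), nd = mean(ndAcc), fallback = FALSE)
}

.permutations <- function(x) {
    n <- length(x)
    if (n == 1L) return(list(x))
    out <- list()
    for (i in seq_len(n)) {
        rest <- .permutations(x[-i])
        out <- c(out, lapply(rest, function(r) c(x[i], r)))
    }
    out
}

#' Synonymous/nonsynonymous site counts of sense codons
#'
#' For each codon position, the synonymous fraction is the number of
#' synonymous single-nucleotide neighbors divided by the number of non-stop
#' neighbors at that position (neighbors creating stop codons are excluded
#' from numerator and denominator); `s` is the sum over the three positions
#' and `n = 3 - s`.
#'
#' @param codons character vector of 3-mers over A/C/G/T; stop codons are
#'   rejected.
#' @return `data.frame` with columns `codon`, `s`, `n`.
#' @examples
#' countSites(c("TTT", "ATG", "GCT"))
#' @export
countSites <- function(codons) {
    tb <- .ng86tables()
    codons <- toupper(codons)
    bad <- which(!codons %in% tb$sense)
    if (length(bad))
        stop(sprintf("stop codon or invalid codon: %s",
                     paste(unique(codons[bad]), collapse = ", ")))
    s <- unname(tb$s[codons])
    data.frame(codon = codons, s = s, n = 3 - s, stringsAsFactors = FALSE)
}

#' Pathway-averaged substitution differences between two codons
#'
#' Classifies each nucleotide change along every ordering of the differing
#' positions as synonymous or nonsynonymous, discards orderings that pass
#' through a stop codon, and averages the counts over the remaining
#' pathways (equal pathway weighting).  If no stop-free pathway exists the
#' raw number of differences is attributed to `nd` and `fallback` is set.
#'
#' @param a,b sense codons (3-mers over A/C/G/T).
#' @return list with `sd`, `nd` and logical `fallback`.
#' @examples
#' countDiffs("GCT", "GCA")  # synonymous single change
#' @export
countDiffs <- function(a, b) {
    tb <- .ng86tables()
    a <- toupper(a); b <- toupper(b)
    if (!a %in% tb$sense || !b %in% tb$sense)
        stop("both codons must be valid sense codons")
    pc <- .pathwayCounts(a, b, tb$code, tb$stops)
    if (pc$fallback)
        warning(sprintf("no stop-free pathway between %s and %s; raw differences counted as nonsynonymous", a, b))
    pc
}

.jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
}

#' NG86 dN/dS for one codon-aligned sequence pair
#'
#' Splits the aligned pair into codons, drops codon pairs containing a gap,
#' an ambiguous base or a stop codon in either sequence (counted in
#' `nSkipped`), sums fractional site counts (averaged between the two
#' sequences) and pathway-averaged differences, and Jukes-Cantor corrects
#' the proportions. `omega = dN/dS` when `dS > 0`; identical retained
#' sequences give `omega = 0` with flag `"no-substitutions"`; `dS = 0` with
#' `dN > 0` gives an NA omega with flag `"undefined-infinite"` (excluded
#' from DI averaging); a proportion at or beyond 3/4 flags the result
#' `"saturated"`.
#'
#' @param seqA,seqB aligned nucleotide strings (equal length, multiple of
#'   3; alphabet A/C/G/T/-) or `Biostrings::DNAString` objects.
#' @param gene,partner labels carried into the result.
#' @return an [NG86Result-class].
#' @examples
#' p <- simCodonPair(omega = 0.2, t = 0.05, length = 500, seed = 1)
#' r <- ng86(p$seqA, p$seqB)
#' omega(r)
#' @export
ng86 <- function(seqA, seqB, gene = "gene", partner = "partner") {
    tb <- .ng86tables()
    seqA <- toupper(as.character(seqA))
    seqB <- toupper(as.character(seqB))
    if (nchar(seqA) != nchar(seqB))
        stop("aligned sequences must have equal length")
    if (nchar(seqA) %% 3L != 0L)
        stop("alignment length must be a multiple of 3")
    n <- nchar(seqA) %/% 3L
    if (n == 0L) stop("empty alignment")
    starts <- seq(1L, by = 3L, length.out = n)
    codA <- substring(seqA, starts, starts + 2L)
    codB <- substring(seqB, starts, starts + 2L)
    keep <- codA %in% tb$sense & codB %in% tb$sense
    nSkipped <- sum(!keep)
    codA <- codA[keep]; codB <- codB[keep]
    if (!length(codA))
        stop("no codon retained after gap/stop/ambiguity filtering")
    S <- (sum(tb$s[codA]) + sum(tb$s[codB])) / 2
    N <- 3 * length(codA) - S
    ia <- match(codA, tb$sense); ib <- match(codB, tb$sense)
    idx <- cbind(ia, ib)
    Sd <- sum(tb$SD[idx]); Nd <- sum(tb$ND[idx])
    nFallback <- sum(tb$FB[idx])
    if (nFallback > 0L)
        warning(sprintf("%d codon pair(s) with no stop-free pathway; raw differences counted as nonsynonymous", nFallback))
    pS <- if (S > 0) Sd / S else 0
    pN <- if (N > 0) Nd / N else 0
    dS <- .jc(pS); dN <- .jc(pN)
    # a ratio beyond 1 can arise in tiny samples; it is saturated (>= 3/4)
    # and not a proportion, so it is stored as NA
    if (pS > 1) pS <- NA_real_
    if (pN > 1) pN <- NA_real_
    if (is.na(dS) || is.na(dN)) {
        flag <- "saturated"; om <- NA_real_
    } else if (Sd + Nd == 0) {
        flag <- "no-substitutions"; om <- 0
    } else if (dS == 0 && dN > 0) {
        flag <- "undefined-infinite"; om <- NA_real_
    } else if (dN == 0) {
        flag <- "dN-zero"; om <- 0
    } else {
        flag <- "ok"; om <- dN / dS
    }
    new("NG86Result", gene = as.character(gene),
        partner = as.character(partner),
        S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
        dS = if (is.na(dS)) NA_real_ else dS,
        dN = if (is.na(dN)) NA_real_ else dN,
        omega = om, flag = flag,
        nCodons = length(codA), nSkipped = as.integer(nSkipped))
}

#' Read an aligned ortholog pair from FASTA
#'
#' One file per gene-partner pair, holding exactly two aligned records
#' (human first by convention). The file name convention
#' `gene__species.fasta` supplies the labels when not given explicitly.
#'
#' @param path FASTA file with exactly two aligned records.
#' @param gene,partner labels; parsed from the file name when `NULL`.
#' @return list with `gene`, `partner`, `seqA`, `seqB`.
#' @export
readCodonPair <- function(path, gene = NULL, partner = NULL) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 2L)
        stop(sprintf("expected exactly 2 records in %s, found %d",
                     path, length(ss)))
    base <- sub("\\.[^.]*$", "", basename(path))
    parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
    if (is.null(gene)) gene <- parts[1L]
    if (is.null(partner)) partner <- if (length(parts) > 1L) parts[2L] else "partner"
    list(gene = gene, partner = partner,
         seqA = as.character(ss[[1L]]), seqB = as.character(ss[[2L]]))
}

#' Run NG86 over a directory of aligned pair FASTA files
#'
#' @param dir directory containing `gene__species.fasta` files.
#' @param pattern file name filter.
#' @return `data.frame`, one row per pair, with the [NG86Result-class]
#'   fields.
#' @export
dndsTable <- function(dir, pattern = "\\.fa(sta)?$") {
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    if (!length(files))
        stop(sprintf("no FASTA pair files found in %s", dir))
    rows <- lapply(files, function(f) {
        p <- readCodonPair(f)
        as.data.frame(ng86(p$seqA, p$seqB, gene = p$gene, partner = p$partner))
    })
    do.call(rbind, rows)
}

#' Read a precomputed per-pair dN/dS table
#'
#' TSV with columns `gene`, `species`, `dN`, `dS`; omega and its
#' definedness flags are derived with the same conventions as [ng86()].
#'
#' @param path TSV path.
#' @return `data.frame` with columns `gene`, `partner`, `dN`, `dS`,
#'   `omega`, `flag`.
#' @export
readDnDsTable <- function(path) {
    df <- readTsv(path)
    need <- c("gene", "species", "dN", "dS")
    if (!all(need %in% names(df)))
        stop("dN/dS table must have columns gene, species, dN, dS")
    omega <- rep(NA_real_, nrow(df))
    flag <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        dn <- df$dN[i]; ds <- df$dS[i]
        if (is.na(dn) || is.na(ds)) { flag[i] <- "saturated" }
        else if (dn == 0 && ds == 0) { flag[i] <- "no-substitutions"; omega[i] <- 0 }
        else if (ds == 0) { flag[i] <- "undefined-infinite" }
        else if (dn == 0) { flag[i] <- "dN-zero"; omega[i] <- 0 }
        else { flag[i] <- "ok"; omega[i] <- dn / ds }
    }
    data.frame(gene = normalizeId(as.character(df$gene)),
               partner = as.character(df$species),
               dN = df$dN, dS = df$dS, omega = omega, flag = flag,
               stringsAsFactors = FALSE)
}

#' Combine pairwise omega values into a per-gene divergence index
#'
#' The DI of a gene combines its defined pairwise dN/dS ratios over the
#' available Hominidae partners; the default combiner is the arithmetic
#' mean (a median alternative is provided, since the exact normalization
#' behind published DI values is a convention). Pairs with an undefined
#' omega (`"undefined-infinite"`, `"saturated"`) are excluded; genes with
#' no defined pair are excluded and listed in the `excluded` attribute.
#' DI < 1 is labeled `"stabilizing"`, DI > 1 `"positive"`, DI = 1
#' `"neutral"`.
#'
#' @param pairs `data.frame` with columns `gene`, `omega` (NA where
#'   undefined) and optionally `flag`; e.g. from [dndsTable()] or
#'   [readDnDsTable()].
#' @param combiner `"mean"` (default) or `"median"`.
#' @return `data.frame` with columns `gene`, `n_pairs`, `DI`, `selection`.
#' @examples
#' p <- data.frame(gene = c("G1", "G1", "G1"), omega = c(0.1, 0.2, 0.3))
#' computeDI(p)
#' @export
computeDI <- function(pairs, combiner = c("mean", "median")) {
    combiner <- match.arg(combiner)
    if (!all(c("gene", "omega") %in% names(pairs)))
        stop("pairs must have columns 'gene' and 'omega'")
    comb <- if (combiner == "mean") mean else stats::median
    ok <- !is.na(pairs$omega)
    excluded <- setdiff(unique(pairs$gene), unique(pairs$gene[ok]))
    pairs <- pairs[ok, , drop = FALSE]
    if (!nrow(pairs))
        stop("no gene with a defined pairwise omega")
    di <- tapply(pairs$omega, pairs$gene, comb)
    np <- tapply(pairs$omega, pairs$gene, length)
    out <- data.frame(gene = names(di), n_pairs = as.integer(np),
                      DI = as.numeric(di), stringsAsFactors = FALSE)
    out$selection <- ifelse(out$DI < 1, "stabilizing",
                            ifelse(out$DI > 1, "positive", "neutral"))
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "excluded") <- sort(excluded)
    out
}
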