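# Independent brute-force oracles, deliberately written as plain nested
# loops without any of the package's lookup tables.

.oracleCode <- local({
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    gc
})
.oracleStops <- names(.oracleCode)[.oracleCode == "*"]
.oracleSense <- names(.oracleCode)[.oracleCode != "*"]

# synonymous site count by direct neighbor enumeration
oracleSites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
        syn <- 0; counted <- 0
        for (b in c("A", "C", "G", "T")) {
            if (b == ch[pos]) next
            nb <- ch
            nb[pos] <- b
            nbc <- paste0(nb[1], nb[2], nb[3])
            if (nbc %in% .oracleStops) next
            counted <- counted + 1
            if (.oracleCode[[nbc]] == .oracleCode[[codon]]) syn <- syn + 1
        }
        if (counted > 0) s <- s + syn / counted
    }
    s
}

# hardcoded permutations of up to three positions
.oraclePerms <- function(pos) {
    k <- length(pos)
    if (k == 1) return(list(pos))
    if (k == 2) return(list(pos, pos[c(2, 1)]))
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
}

# pathway-averaged (sd, nd) by walking every ordering explicitly
oracleDiffs <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    dpos <- which(ca != cb)
    if (length(dpos) == 0) return(c(sd = 0, nd = 0))
    sds <- c(); nds <- c()
    for (ord in .oraclePerms(dpos)) {
        cur <- ca
        sd <- 0; nd <- 0; valid <- TRUE
        for (p in ord) {
            nxt <- cur
            nxt[p] <- cb[p]
            curc <- paste(cur, collapse = "")
            nxtc <- paste(nxt, collapse = "")
            if (nxtc %in% .oracleStops) { valid <- FALSE; break }
            if (.oracleCode[[curc]] == .oracleCode[[nxtc]]) sd <- sd + 1
            else nd <- nd + 1
            cur <- nxt
        }
        if (valid) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (length(sds) == 0) return(c(sd = 0, nd = length(dpos)))
    c(sd = mean(sds), nd = mean(nds))
}

# full-alignment S/N/Sd/Nd by looping the two oracles over codons
oraclePairCounts <- function(seqA, seqB) {
    n <- nchar(seqA) %/% 3
    S <- Sd <- Nd <- 0
    kept <- 0
    for (i in seq_len(n)) {
        a <- substr(seqA, 3 * i - 2, 3 * i)
        b <- substr(seqB, 3 * i - 2, 3 * i)
        if (!(a %in% .oracleSense) || !(b %in% .oracleSense)) next
        kept <- kept + 1
        S <- S + (oracleSites(a) + oracleSites(b)) / 2
        d <- oracleDiffs(a, b)
        Sd <- Sd + d[["sd"]]
        Nd <- Nd + d[["nd"]]
    }
    c(S = S, N = 3 * kept - S, Sd = Sd, Nd = Nd)
}

# step-up Benjamini-Hochberg written out longhand
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (r in m:1) {
        v <- min(prev, p[o[r]] * m / r, 1)
        adj[o[r]] <- v
        prev <- v
    }
    adj
}

# random aligned codon pair (sense codons only, a few point differences)
randomCodonAlignment <- function(nCodons, pMut = 0.15) {
    a <- sample(.oracleSense, nCodons, replace = TRUE)
    b <- vapply(a, function(cod) {
        ch <- strsplit(cod, "")[[1]]
        for (pos in 1:3) {
            if (runif(1) < pMut) {
                ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
            }
        }
        out <- paste(ch, collapse = "")
        if (out %in% .oracleStops) cod else out
    }, character(1))
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# brute-force Venn region for one element: which sets contain it
bruteRegion <- function(el, sets) {
    nms <- vapply(sets, setName, character(1))
    inSet <- vapply(sets, function(s) el %in% members(s), logical(1))
    paste(nms[inSet], collapse = "&")
}

randomGeneSets <- function(k, universeSize = 20) {
    universe <- sprintf("G%02d", seq_len(universeSize))
    lapply(seq_len(k), function(i)
        GeneSet(LETTERS[i], sample(universe, sample(3:universeSize, 1))))
}
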