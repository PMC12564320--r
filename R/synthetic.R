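# Seeded synthetic-data generators with ground-truth ledgers. Each
# generator derives everything from (config, seed) through one explicitly
# seeded stream and restores the caller's RNG state, so repeated calls are
# byte-identical and never perturb surrounding code.

#' Synthetic reference species panel for the 16-level ladder
#'
#' A synthetic stand-in for an orthology-database species panel: ~2 species
#' per stratum, each mapped to the ladder stratum at which its lineage
#' diverges from the human lineage. Species names are realistic but the
#' panel is a construction for simulation, not a curated resource.
#'
#' @return `data.frame` with columns `species`, `split_index`.
#' @export
defaultSpeciesPanel <- function() {
    data.frame(
        species = c("Escherichia coli", "Bacillus subtilis",
                    "Saccharomyces cerevisiae", "Arabidopsis thaliana",
                    "Drosophila melanogaster", "Caenorhabditis elegans",
                    "Ciona intestinalis", "Branchiostoma floridae",
                    "Eptatretus burgeri", "Myxine glutinosa",
                    "Petromyzon marinus", "Lethenteron camtschaticum",
                    "Danio rerio", "Gallus gallus",
                    "Ornithorhynchus anatinus", "Monodelphis domestica",
                    "Canis lupus familiaris", "Bos taurus",
                    "Mus musculus", "Rattus norvegicus",
                    "Lemur catta", "Otolemur garnettii",
                    "Carlito syrichta", "Tarsius bancanus",
                    "Macaca mulatta", "Papio anubis",
                    "Pan troglodytes", "Gorilla gorilla gorilla",
                    "Pongo abelii", "Homo neanderthalensis",
                    "Homo sapiens"),
        split_index = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L,
                        7L, 7L, 8L, 8L, 9L, 9L, 10L, 10L, 11L, 11L, 12L,
                        12L, 13L, 13L, 14L, 14L, 14L, 15L, 16L),
        stringsAsFactors = FALSE)
}

#' Planted-age distribution echoing a whole-proteome PAI profile
#'
#' Default stratum probabilities for the presence simulator, shaped like a
#' human proteome-wide age profile: mass concentrated at the Cellular
#' Organisms, Eukaryota and Metazoa strata with a thin tail toward the
#' terminal strata.
#'
#' @return numeric vector of 16 probabilities summing to 1.
#' @export
defaultPaiProbs <- function() {
    p <- c(14.3, 16, 28.6, 4, 2, 3, 6.3, 4, 3, 3.8, 3, 2, 3, 3, 2, 2)
    p / sum(p)
}

#' Simulate an ortholog-presence table with planted ages
#'
#' Each gene draws a planted PAI from `paiProbs`; its presence row then
#' contains at least one panel species at exactly that split index plus a
#' random subset of species with larger split indices (never a smaller
#' one), so the minimum-split rule recovers the planted age exactly.
#'
#' @param nGenes number of genes.
#' @param paiProbs probability per stratum (length = number of strata).
#' @param panel species panel `data.frame` (`species`, `split_index`);
#'   every stratum with positive probability needs at least one species.
#' @param extraProb inclusion probability for each higher-split species.
#' @param seed integer seed.
#' @return list with `presence` (`data.frame` gene, species), `splits`
#'   (the panel), and `ledger` (`data.frame` gene, planted_pai).
#' @export
simPresence <- function(nGenes, paiProbs = defaultPaiProbs(),
                        panel = defaultSpeciesPanel(), extraProb = 0.5,
                        seed = 1L) {
    stopifnot(nGenes >= 1L, abs(sum(paiProbs) - 1) < 1e-8)
    strata <- which(paiProbs > 0)
    missing <- setdiff(strata, unique(panel$split_index))
    if (length(missing))
        stop(sprintf("no panel species at split index: %s",
                     paste(missing, collapse = ", ")))
    withSeed(seed, {
        genes <- sprintf("SYNG%05d", seq_len(nGenes))
        planted <- sample(seq_along(paiProbs), nGenes, replace = TRUE,
                          prob = paiProbs)
        rows <- lapply(seq_len(nGenes), function(i) {
            atLevel <- panel$species[panel$split_index == planted[i]]
            anchor <- if (length(atLevel) == 1L) atLevel else
                sample(atLevel, 1L)
            higher <- panel$species[panel$split_index > planted[i]]
            extra <- higher[stats::runif(length(higher)) < extraProb]
            data.frame(gene = genes[i],
                       species = unique(c(anchor, extra)),
                       stringsAsFactors = FALSE)
        })
        list(presence = do.call(rbind, rows),
             splits = panel[, c("species", "split_index")],
             ledger = data.frame(gene = genes, planted_pai = planted,
                                 stringsAsFactors = FALSE))
    })
}

#' Simulate a codon-aligned ortholog pair at a target dN/dS
#'
#' A random sense-codon ancestor evolves along two independent branches.
#' Substitutions are proposed uniformly over sites and alternative bases
#' (Poisson number with mean `t` per site, i.e. `3 t L` proposals per
#' branch); proposals creating a stop codon are rejected, nonsynonymous
#' proposals are accepted with probability `min(1, omega)`, synonymous ones
#' always. At low divergence the realized dN/dS is close to `omega` by
#' construction. Acceptance/rejection by amino-acid effect keeps the
#' generator transparent and independent of the counting machinery it
#' validates.
#'
#' @param omega target nonsynonymous/synonymous rate ratio (>= 0).
#' @param t expected proposed substitutions per nucleotide site per branch;
#'   must lie in (0, 0.3) to stay far from Jukes-Cantor saturation.
#' @param length number of codons (>= 10).
#' @param seed integer seed.
#' @return list with `seqA`, `seqB` (character), `gene`, `partner`, and
#'   `ledger` (omega, t, length, accepted syn/nonsyn counts per branch).
#' @export
simCodonPair <- function(omega, t, length = 500L, seed = 1L) {
    if (!is.numeric(omega) || omega < 0)
        stop("'omega' must be a non-negative number")
    if (!is.numeric(t) || t <= 0 || t >= 0.3)
        stop("'t' must lie in (0, 0.3)")
    if (length < 10L)
        stop("'length' must be at least 10 codons")
    tb <- .ng86tables()
    bases <- c("A", "C", "G", "T")
    withSeed(seed, {
        anc <- sample(tb$sense, length, replace = TRUE)
        evolve <- function(cods) {
            nProp <- stats::rpois(1L, 3 * t * length)
            accS <- accN <- 0L
            for (k in seq_len(nProp)) {
                ci <- sample.int(length, 1L)
                pos <- sample.int(3L, 1L)
                cod <- strsplit(cods[ci], "")[[1L]]
                alt <- sample(setdiff(bases, cod[pos]), 1L)
                newCod <- cod
                newCod[pos] <- alt
                newC <- paste(newCod, collapse = "")
                if (newC %in% tb$stops) next
                syn <- tb$code[[newC]] == tb$code[[cods[ci]]]
                if (!syn && stats::runif(1L) > min(1, omega)) next
                cods[ci] <- newC
                if (syn) accS <- accS + 1L else accN <- accN + 1L
            }
            list(cods = cods, accS = accS, accN = accN)
        }
        brA <- evolve(anc)
        brB <- evolve(anc)
        list(seqA = paste(brA$cods, collapse = ""),
             seqB = paste(brB$cods, collapse = ""),
             gene = "SYNPAIR", partner = "synthetic",
             ledger = list(omega = omega, t = t, length = length,
                           accepted_syn = brA$accS + brB$accS,
                           accepted_nonsyn = brA$accN + brB$accN))
    })
}

#' Simulate a gene set with a planted bin enrichment
#'
#' Samples `size` genes without replacement from a background universe of
#' per-gene index values so that the expected proportion in `enrichedBin`
#' is the background proportion plus `delta`: the in-bin member count is
#' drawn Binomial(size, p_bg + delta), those members uniformly from the
#' bin, the rest uniformly from the complement.
#'
#' @param backgroundValues named numeric vector (gene -> index value) for
#'   the whole universe.
#' @param scheme a [BinScheme-class].
#' @param enrichedBin label of the bin to enrich.
#' @param delta additive proportion increase (0 = null set).
#' @param size set size.
#' @param seed integer seed.
#' @return list with `set` (a [GeneSet-class]) and `ledger` (enriched bin,
#'   background and target proportions, realized in-bin count).
#' @export
simGeneSet <- function(backgroundValues, scheme, enrichedBin, delta, size,
                       seed = 1L) {
    stopifnot(is(scheme, "BinScheme"), !is.null(names(backgroundValues)))
    if (!enrichedBin %in% scheme@labels)
        stop(sprintf("unknown bin '%s'", enrichedBin))
    bg <- binValues(backgroundValues, scheme)
    assign <- attr(bg, "assignment")
    inBin <- names(backgroundValues)[assign == enrichedBin]
    outBin <- names(backgroundValues)[assign != enrichedBin]
    pBg <- length(inBin) / length(backgroundValues)
    pTarget <- pBg + delta
    if (pTarget < 0 || pTarget > 1)
        stop("delta pushes the target proportion outside [0,1]")
    withSeed(seed, {
        k <- stats::rbinom(1L, size, pTarget)
        if (k > length(inBin) || (size - k) > length(outBin))
            stop("infeasible delta/size for this background")
        chosen <- c(sample(inBin, k), sample(outBin, size - k))
        list(set = GeneSet("synthetic_set", chosen,
                           source = "simGeneSet"),
             ledger = list(enriched_bin = enrichedBin, delta = delta,
                           p_background = pBg, p_target = pTarget,
                           n_in_bin = k, size = size))
    })
}

#' Simulate a STRING-style edge table with planted hubs
#'
#' Qualifying edges (confidence in (0.9, 1], experimental channel) realize
#' a prescribed degree sequence by stub matching with rejection of self
#' loops and parallel edges; noise edges among separate decoy nodes carry
#' either sub-threshold confidence or a non-experimental channel, so the
#' confidence/channel filter recovers exactly the planted graph.
#'
#' @param degrees named integer vector (node -> planted degree); the sum
#'   must be even and the sequence graphical.
#' @param nNoise number of noise edges.
#' @param seed integer seed.
#' @param maxTries stub-matching restarts before giving up.
#' @return list with `edges` (`data.frame` node_a, node_b, confidence,
#'   channels) and `ledger` (planted hub nodes at degree >= 5, qualifying
#'   edge and node counts, the degree sequence).
#' @export
simEdgeTable <- function(degrees, nNoise = 50L, seed = 1L, maxTries = 5000L) {
    stopifnot(!is.null(names(degrees)), all(degrees >= 1L))
    if (!igraph::is_graphical(degrees))
        stop("degree sequence is not graphical")
    nodes <- normalizeId(names(degrees))
    withSeed(seed, {
        edges <- NULL
        for (try in seq_len(maxTries)) {
            stubs <- sample(rep(seq_along(nodes), degrees))
            m <- matrix(stubs, ncol = 2L)
            lo <- pmin(m[, 1L], m[, 2L]); hi <- pmax(m[, 1L], m[, 2L])
            if (any(lo == hi)) next
            if (anyDuplicated(paste(lo, hi))) next
            edges <- cbind(lo, hi)
            break
        }
        if (is.null(edges))
            stop("stub matching failed to realize the degree sequence; try another seed")
        nQ <- nrow(edges)
        qual <- data.frame(node_a = nodes[edges[, 1L]],
                           node_b = nodes[edges[, 2L]],
                           confidence = stats::runif(nQ, 0.905, 1),
                           channels = "experimental,database",
                           stringsAsFactors = FALSE)
        decoys <- sprintf("NOISE%04d", seq_len(max(10L, ceiling(nNoise / 2))))
        noise <- NULL
        if (nNoise > 0L) {
            na <- sample(decoys, nNoise, replace = TRUE)
            nb <- sample(c(nodes, decoys), nNoise, replace = TRUE)
            ok <- na != nb
            na <- na[ok]; nb <- nb[ok]
            lowConf <- stats::runif(length(na)) < 0.5
            noise <- data.frame(
                node_a = na, node_b = nb,
                confidence = ifelse(lowConf,
                                    stats::runif(length(na), 0.15, 0.9),
                                    stats::runif(length(na), 0.905, 1)),
                channels = ifelse(lowConf, "experimental",
                                  "textmining,coexpression"),
                stringsAsFactors = FALSE)
        }
        tab <- rbind(qual, noise)
        tab <- tab[sample(nrow(tab)), , drop = FALSE]
        rownames(tab) <- NULL
        list(edges = tab,
             ledger = list(hubs = sort(nodes[degrees >= 5L]),
                           n_qualifying_edges = nQ,
                           n_qualifying_nodes = length(nodes),
                           degrees = stats::setNames(as.integer(degrees),
                                                     nodes)))
    })
}
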