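#' Read a STRING-style edge table
#'
#' Expects a TSV with two node columns (`node_a`/`node_b`, or
#' `protein1`/`protein2`), a combined confidence column (`confidence`,
#' `combined_score` or `score`; scores on the 0-1000 integer scale are
#' rescaled to 0-1), and evidence channels either as a single `channels`
#' column (comma-separated labels) or as per-channel score columns
#' (`experimental`, `database`, `textmining`, `coexpression`,
#' `neighborhood`, `fusion`, `cooccurrence`; a channel is present when its
#' score is > 0). Node symbols are normalized, node pairs canonicalized
#' (undirected), self-loops dropped and duplicate records collapsed to the
#' first occurrence; malformed rows (confidence outside `[0,1]`, missing
#' node) are skipped. Counts of dropped rows are attached as attributes
#' `n_selfloops`, `n_duplicates`, `n_malformed`.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `node_a`, `node_b`, `confidence`,
#'   `channels` (comma-joined labels).
#' @export
readEdgeTable <- function(path) {
    df <- readTsv(path, check.names = FALSE)
    nmA <- intersect(c("node_a", "protein1", "node1"), names(df))[1]
    nmB <- intersect(c("node_b", "protein2", "node2"), names(df))[1]
    nmC <- intersect(c("confidence", "combined_score", "score"), names(df))[1]
    if (is.na(nmA) || is.na(nmB) || is.na(nmC))
        stop("edge table needs two node columns and a confidence column")
    channelNames <- c("experimental", "database", "textmining", "coexpression",
                      "neighborhood", "fusion", "cooccurrence")
    conf <- as.numeric(df[[nmC]])
    # STRING dialects score on 0-1000 integers; a stray slightly-out-of-range
    # value on the 0-1 scale must stay malformed rather than trigger rescaling
    if (max(conf, na.rm = TRUE) > 1.5 && max(conf, na.rm = TRUE) <= 1000)
        conf <- conf / 1000
    if ("channels" %in% names(df)) {
        channels <- as.character(df$channels)
    } else {
        present <- intersect(channelNames, names(df))
        if (!length(present))
            stop("edge table needs a 'channels' column or per-channel score columns")
        channels <- apply(df[present], 1L, function(row)
            paste(present[as.numeric(row) > 0], collapse = ","))
    }
    a <- trimws(toupper(as.character(df[[nmA]])))
    b <- trimws(toupper(as.character(df[[nmB]])))
    malformed <- !nzchar(a) | !nzchar(b) | is.na(conf) | conf < 0 | conf > 1 |
        grepl("[[:space:]]", a) | grepl("[[:space:]]", b)
    a <- a[!malformed]; b <- b[!malformed]
    conf <- conf[!malformed]; channels <- channels[!malformed]
    selfloop <- a == b
    a <- a[!selfloop]; b <- b[!selfloop]
    conf <- conf[!selfloop]; channels <- channels[!selfloop]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    dup <- duplicated(key)
    out <- data.frame(node_a = lo[!dup], node_b = hi[!dup],
                      confidence = conf[!dup], channels = channels[!dup],
                      stringsAsFactors = FALSE)
    attr(out, "n_malformed") <- sum(malformed)
    attr(out, "n_selfloops") <- sum(selfloop)
    attr(out, "n_duplicates") <- sum(dup)
    out
}

#' Confidence- and channel-filter an edge table into a simple graph
#'
#' Keeps edges whose confidence is strictly greater than `minConf`
#' (switchable to >=) and whose evidence includes the required channel;
#' isolated nodes are dropped (a node exists only through a retained
#' edge).
#'
#' @param edges `data.frame` as returned by [readEdgeTable()].
#' @param minConf confidence threshold (default 0.9).
#' @param requiredChannel evidence channel an edge must carry (default
#'   `"experimental"`); `NULL` disables the channel requirement.
#' @param strict if `TRUE` (default) require confidence > `minConf`, else
#'   >=.
#' @return an undirected simple `igraph` graph with edge attribute
#'   `confidence`.
#' @export
filterEdges <- function(edges, minConf = 0.9,
                        requiredChannel = "experimental", strict = TRUE) {
    need <- c("node_a", "node_b", "confidence", "channels")
    if (!all(need %in% names(edges)))
        stop("edges must have columns node_a, node_b, confidence, channels")
    if (!nrow(edges))
        stop("empty edge list")
    keep <- if (strict) edges$confidence > minConf else edges$confidence >= minConf
    if (!is.null(requiredChannel)) {
        chans <- strsplit(edges$channels, ",", fixed = TRUE)
        keep <- keep & vapply(chans, function(x)
            requiredChannel %in% trimws(x), logical(1))
    }
    kept <- edges[keep, , drop = FALSE]
    if (!nrow(kept)) {
        warning("no edge passes the confidence/channel filter")
        return(igraph::make_empty_graph(directed = FALSE))
    }
    g <- igraph::graph_from_data_frame(
        kept[c("node_a", "node_b", "confidence")], directed = FALSE)
    g <- igraph::simplify(g, edge.attr.comb = "max")
    g
}

#' Hub nodes of a filtered interaction graph
#'
#' @param graph undirected `igraph` graph.
#' @param minDegree hub threshold (default 5).
#' @return `data.frame` with columns `node`, `degree`, sorted by degree
#'   descending then node name; possibly zero rows.
#' @export
hubGenes <- function(graph, minDegree = 5L) {
    if (igraph::vcount(graph) == 0L)
        return(data.frame(node = character(0), degree = integer(0),
                          stringsAsFactors = FALSE))
    deg <- igraph::degree(graph)
    keep <- deg >= minDegree
    out <- data.frame(node = names(deg)[keep], degree = as.integer(deg[keep]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$node), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Compare and classify hub genes from two networks
#'
#' Labels each hub by origin (`first`, `second`, `both`) and by its
#' relation to the mTOR machinery with the precedence pathway member >
#' mTOR-sensitive > neither: a hub in the pathway set is `"pathway"` even
#' if also mTOR-sensitive.
#'
#' @param hubs1,hubs2 `data.frame`s from [hubGenes()] (columns `node`,
#'   `degree`) for the two networks.
#' @param mtorPathway [GeneSet-class] of signaling-pathway members.
#' @param mtorSensitive [GeneSet-class] of mTOR-sensitive genes.
#' @return list with `table` (per-hub `node`, `origin`, `mtor_class`,
#'   degrees) and `counts` (named vector: `common`, `pathway`, `sensitive`,
#'   `neither`, `total`).
#' @export
classifyHubs <- function(hubs1, hubs2, mtorPathway, mtorSensitive) {
    stopifnot(is(mtorPathway, "GeneSet"), is(mtorSensitive, "GeneSet"))
    if (length(mtorPathway) == 0L && length(mtorSensitive) == 0L)
        warning("both annotation sets are empty; all hubs classed 'neither'")
    nodes <- sort(union(hubs1$node, hubs2$node))
    origin <- ifelse(nodes %in% hubs1$node & nodes %in% hubs2$node, "both",
                     ifelse(nodes %in% hubs1$node, "first", "second"))
    mtor <- ifelse(nodes %in% members(mtorPathway), "pathway",
                   ifelse(nodes %in% members(mtorSensitive), "sensitive",
                          "neither"))
    tab <- data.frame(node = nodes, origin = origin, mtor_class = mtor,
                      degree1 = hubs1$degree[match(nodes, hubs1$node)],
                      degree2 = hubs2$degree[match(nodes, hubs2$node)],
                      stringsAsFactors = FALSE)
    counts <- c(common = sum(origin == "both"),
                pathway = sum(mtor == "pathway"),
                sensitive = sum(mtor == "sensitive"),
                neither = sum(mtor == "neither"),
                total = length(nodes))
    list(table = tab, counts = counts)
}

#' Write a filtered graph as an SIF-style edge list
#'
#' Plain three-column text (`node_a`, interaction type, `node_b`) readable
#' by external network viewers.
#'
#' @param graph undirected `igraph` graph.
#' @param path output file.
#' @param interaction interaction label (default `"pp"`).
#' @return the path, invisibly.
#' @export
writeSif <- function(graph, path, interaction = "pp") {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el)) paste(el[, 1L], interaction, el[, 2L]) else character(0)
    writeLines(lines, path)
    invisible(path)
}
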