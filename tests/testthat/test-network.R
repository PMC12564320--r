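writeEdges <- function(df) {
    f <- tempfile(fileext = ".tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}

test_that("edge tables are parsed, canonicalized and range-checked", {
    f <- writeEdges(data.frame(
        node_a = c("TP53", "MTOR", "tp53 ", "EGFR", "BAD"),
        node_b = c("MTOR", "TP53", "mtor", "EGFR", "ROW"),
        confidence = c(0.95, 0.97, 0.93, 0.9, 1.2),
        channels = c("experimental", "experimental,textmining",
                     "database", "experimental", "experimental")))
    ed <- readEdgeTable(f)
    # reversed and renamed duplicates collapse onto one canonical record
    expect_identical(nrow(ed), 1L)
    expect_identical(ed$node_a, "MTOR")
    expect_identical(ed$node_b, "TP53")
    expect_identical(attr(ed, "n_selfloops"), 1L)       # EGFR-EGFR
    expect_identical(attr(ed, "n_malformed"), 1L)       # confidence 1.2
    expect_identical(attr(ed, "n_duplicates"), 2L)
})

test_that("per-channel score columns and 0-1000 scores are understood", {
    f <- writeEdges(data.frame(
        protein1 = c("A1", "B1"), protein2 = c("B1", "C1"),
        combined_score = c(950L, 700L),
        experimental = c(800L, 0L), textmining = c(0L, 900L)))
    ed <- readEdgeTable(f)
    expect_equal(ed$confidence, c(0.95, 0.7))
    expect_identical(ed$channels, c("experimental", "textmining"))
    f2 <- writeEdges(data.frame(x = 1))
    expect_error(readEdgeTable(f2), "node columns")
})

test_that("filtering keeps only high-confidence edges with the required channel", {
    ed <- data.frame(
        node_a = c("A1", "A1", "A1", "B1"),
        node_b = c("B1", "C1", "D1", "C1"),
        confidence = c(0.5, 0.95, 0.95, 0.9),
        channels = c("experimental", "textmining", "experimental,database",
                     "experimental"))
    g <- filterEdges(ed)
    expect_equal(igraph::ecount(g), 1)  # only A1-D1 qualifies
    expect_setequal(igraph::V(g)$name, c("A1", "D1"))
    # 0.9 is excluded under the strict reading, included with strict = FALSE
    g2 <- filterEdges(ed, strict = FALSE)
    expect_equal(igraph::ecount(g2), 2)
    expect_warning(g0 <- filterEdges(ed, minConf = 0.99), "no edge")
    expect_equal(igraph::vcount(g0), 0)
})

test_that("filtering is monotone in the confidence threshold", {
    set.seed(23)
    ed <- data.frame(node_a = sprintf("N%02d", sample(20, 60, TRUE)),
                     node_b = sprintf("N%02d", sample(20, 60, TRUE)),
                     confidence = runif(60),
                     channels = "experimental")
    ed <- ed[ed$node_a != ed$node_b, ]
    counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th)
        igraph::ecount(suppressWarnings(filterEdges(ed, minConf = th))),
        numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("hub extraction follows degree thresholds and ordering", {
    star <- igraph::make_star(7, mode = "undirected", center = 1)
    igraph::V(star)$name <- c("CENTER", sprintf("L%d", 1:6))
    h <- hubGenes(star)
    expect_identical(h$node, "CENTER")
    expect_identical(h$degree, 6L)

    path <- igraph::make_ring(10, circular = FALSE)
    igraph::V(path)$name <- sprintf("P%02d", 1:10)
    expect_identical(nrow(hubGenes(path)), 0L)

    # degree sum = 2|E| and hub nesting across thresholds
    set.seed(29)
    g <- igraph::sample_gnp(40, 0.15)
    igraph::V(g)$name <- sprintf("G%02d", 1:40)
    expect_identical(sum(igraph::degree(g)), 2L * igraph::ecount(g))
    h5 <- hubGenes(g, 5L)$node
    h6 <- hubGenes(g, 6L)$node
    expect_true(all(h6 %in% h5))
})

test_that("hub classification applies the pathway > sensitive > neither precedence", {
    h1 <- data.frame(node = c("A1", "B1", "C1"), degree = c(7L, 6L, 5L))
    h2 <- data.frame(node = c("B1", "C1", "D1"), degree = c(8L, 5L, 9L))
    pw <- GeneSet("pathway", c("B1", "D1"))
    sens <- GeneSet("sensitive", c("B1", "C1"))
    cls <- classifyHubs(h1, h2, pw, sens)
    expect_identical(unname(cls$counts["common"]), 2L)
    tab <- cls$table
    # B1 in both annotation sets -> pathway wins
    expect_identical(tab$mtor_class[tab$node == "B1"], "pathway")
    expect_identical(tab$mtor_class[tab$node == "C1"], "sensitive")
    expect_identical(tab$mtor_class[tab$node == "A1"], "neither")
    expect_identical(tab$origin[tab$node == "A1"], "first")
    expect_identical(tab$origin[tab$node == "D1"], "second")
    expect_identical(tab$origin[tab$node == "B1"], "both")
    expect_warning(classifyHubs(h1, h2, GeneSet("e", character(0)),
                                GeneSet("f", character(0))), "empty")
})

test_that("SIF export writes one line per edge", {
    g <- igraph::graph_from_literal(A - B, B - C)
    f <- tempfile(fileext = ".sif")
    writeSif(g, f)
    expect_identical(readLines(f), c("A pp B", "B pp C"))
})
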