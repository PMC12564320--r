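test_that("DI binning honors the zero bin and the 0.2/1 thresholds", {
    sc <- diBinScheme()
    b <- binValues(c(0, 0.1, 1.5), sc)
    expect_identical(b$count, c(1L, 1L, 0L, 0L, 0L, 0L, 1L))
    # boundary placement: 0.2 opens the second interior bin, 1 the top bin
    b2 <- binValues(c(0.2, 0.1999, 1, 0.9999), sc)
    expect_identical(b2$count[b2$bin == "[0.2,0.4)"], 1L)
    expect_identical(b2$count[b2$bin == "(0,0.2)"], 1L)
    expect_identical(b2$count[b2$bin == "[1,Inf)"], 1L)
    expect_identical(b2$count[b2$bin == "[0.8,1)"], 1L)
    expect_error(binValues(numeric(0), sc), "no values")
    expect_error(binValues(c(G1 = -0.1), sc), "G1")
    expect_error(binValues(c(G2 = NaN), sc), "G2")
})

test_that("binning is exhaustive and exclusive for both schemes", {
    set.seed(3)
    di <- c(rep(0, 5), rexp(200, 3))
    names(di) <- sprintf("g%03d", seq_along(di))
    b <- binValues(di, diBinScheme())
    expect_identical(sum(b$count), length(di))
    asg <- attr(b, "assignment")
    expect_identical(sort(unique(names(asg))), sort(names(di)))

    pai <- sample(1:16, 500, replace = TRUE)
    bp <- binValues(pai, paiBinScheme())
    expect_identical(bp$count, as.integer(tabulate(pai, 16)))
    expect_error(binValues(c(gX = 17), paiBinScheme()), "gX")
})

test_that("BH adjustment matches the longhand step-up and its bounds", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(9)
    for (i in 1:20) {
        p <- runif(sample(1:30, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, oracleBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p))                      # never below raw
        expect_true(all(adj <= pmin(p * length(p), 1))) # never above Bonferroni
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("per-bin chi-square equals the closed-form statistic", {
    set.seed(41)
    bgVals <- sample(1:16, 19478, replace = TRUE,
                     prob = defaultPaiProbs())
    names(bgVals) <- sprintf("B%05d", seq_along(bgVals))
    setVals <- bgVals[sample(length(bgVals), 1000)]
    sc <- paiBinScheme()
    tab <- perBinTest(binValues(setVals, sc), binValues(bgVals, sc))
    nSet <- sum(tab$observed)
    for (i in which(tab$testable)) {
        O <- c(tab$observed[i], nSet - tab$observed[i])
        E <- c(tab$expected[i], nSet - tab$expected[i])
        expect_equal(tab$chi2[i], sum((O - E)^2 / E), tolerance = 1e-12)
        # independent route: stats::chisq.test goodness-of-fit
        ct <- suppressWarnings(stats::chisq.test(
            O, p = c(tab$proportion_background[i],
                     1 - tab$proportion_background[i])))
        expect_equal(tab$chi2[i], unname(ct$statistic), tolerance = 1e-9)
        expect_equal(tab$p[i], ct$p.value, tolerance = 1e-9)
    }
    # statistic is invariant to relabeling in-bin/out-of-bin
    i <- which(tab$testable)[1]
    Osw <- c(nSet - tab$observed[i], tab$observed[i])
    Esw <- c(nSet - tab$expected[i], tab$expected[i])
    expect_equal(tab$chi2[i], sum((Osw - Esw)^2 / Esw), tolerance = 1e-12)
})

test_that("a set distributed exactly like the background is entirely null", {
    counts <- data.frame(bin = as.character(1:4),
                         count = c(10L, 20L, 30L, 40L),
                         proportion = c(0.1, 0.2, 0.3, 0.4))
    bg <- data.frame(bin = as.character(1:4),
                     count = c(100L, 200L, 300L, 400L),
                     proportion = c(0.1, 0.2, 0.3, 0.4))
    tab <- perBinTest(counts, bg)
    expect_true(all(abs(tab$chi2) < 1e-12))
    expect_true(all(tab$p_adj == 1))
    expect_true(all(tab$stars == ""))
})

test_that("a strong published-scale excess is flagged beyond the 0.001 star", {
    # stratum-3 proportion 40.6% in a 1095-gene set vs 28.6% background
    nSet <- 1095L; nBg <- 19478L
    setC <- as.integer(round(c(0.079, 0.05, 0.406, rep(0.465 / 13, 13)) * nSet))
    bgC <- as.integer(round(c(0.143, 0.09, 0.286, rep(0.481 / 13, 13)) * nBg))
    sc <- paiBinScheme()
    mk <- function(cnt) data.frame(bin = sc@labels, count = cnt,
                                   proportion = cnt / sum(cnt))
    tab <- perBinTest(mk(setC), mk(bgC))
    expect_lt(tab$p_adj[tab$bin == "3"], 0.001)
    expect_identical(tab$stars[tab$bin == "3"], "***")
})

test_that("bins with zero expectation are excluded from the BH family", {
    counts <- data.frame(bin = c("a", "b", "c"), count = c(5L, 5L, 0L),
                         proportion = c(0.5, 0.5, 0))
    bg <- data.frame(bin = c("a", "b", "c"), count = c(10L, 90L, 0L),
                     proportion = c(0.1, 0.9, 0))
    tab <- perBinTest(counts, bg)
    expect_false(tab$testable[3])
    expect_true(is.na(tab$p_adj[3]))
    expect_equal(tab$p_adj[tab$testable],
                 bhAdjust(tab$p[tab$testable]))
    expect_error(perBinTest(counts, counts[1:2, ]), "schemes")
})

test_that("set summaries report two-decimal means over covered genes", {
    pai <- data.frame(gene = c("A1", "A2", "A3"), pai = c(2L, 3L, 4L))
    di <- data.frame(gene = c("A1", "A2"), DI = c(0.111, 0.379))
    s1 <- GeneSet("one", "A1")
    s2 <- GeneSet("two", c("A1", "A2", "A3", "MISSING"))
    out <- summarizeSets(list(s1, s2), pai = pai, di = di)
    expect_equal(out$mean_pai[1], 2)
    expect_equal(out$mean_di[1], 0.11)
    expect_equal(out$mean_pai[2], 3)
    expect_identical(out$n_pai[2], 3L)
    expect_identical(out$n_di[2], 2L)
    expect_equal(out$mean_di[2], round(mean(c(0.111, 0.379)), 2))
    none <- summarizeSets(list(GeneSet("zero", "ZZZ")), pai = pai, di = di)
    expect_true(is.na(none$mean_pai))
})
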