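mkExpr <- function(v, scale = "log2") {
    if (is.null(dimnames(v)))
        dimnames(v) <- list(paste0("g", seq_len(nrow(v))),
                            paste0("s", seq_len(ncol(v))))
    ExpressionExperiment(v, scale = scale)
}

test_that("quantile normalization reproduces the hand 2x2 oracle", {
    m <- mkExpr(matrix(c(4, 16, 16, 4), 2, 2), scale = "raw")
    out <- log2QuantileNormalize(m)
    ## log2 -> [[2,4],[4,2]]; both columns already share sorted values
    ## (2,4), so the rank-preserving map leaves them unchanged
    expect_equal(unname(exprs(out)), matrix(c(2, 4, 4, 2), 2, 2))
    expect_identical(exprsScale(out), "log2_quantile")
})

test_that("identical columns are left unchanged by the quantile step", {
    v <- matrix(rep(c(2, 8, 32, 128), 3), 4, 3)
    out <- log2QuantileNormalize(mkExpr(v, "raw"))
    expect_equal(unname(exprs(out)), log2(v))
})

test_that("columns share one sorted multiset and equal means afterwards", {
    set.seed(42)
    v <- matrix(2^runif(60, 2, 12), 15, 4)
    out <- exprs(log2QuantileNormalize(mkExpr(v, "raw")))
    ref <- unname(sort(out[, 1]))
    for (j in 2:4) expect_equal(unname(sort(out[, j])), ref)
    expect_equal(diff(range(colMeans(out))), 0, tolerance = 1e-12)
})

test_that("quantile normalization is idempotent on its own output", {
    set.seed(7)
    v <- matrix(2^runif(40, 2, 12), 10, 4)
    once <- exprs(log2QuantileNormalize(mkExpr(v, "raw")))
    twice <- exprs(log2QuantileNormalize(mkExpr(2^once, "raw")))
    expect_equal(twice, once, tolerance = 1e-12)
})

test_that("normalization rejects bad inputs with informative errors", {
    v <- matrix(c(4, -1, 2, 8), 2, 2,
                dimnames = list(c("gA", "gB"), c("s1", "s2")))
    expect_error(log2QuantileNormalize(mkExpr(v, "raw")), "gB.*s1")
    expect_error(
        log2QuantileNormalize(mkExpr(matrix(1:4, 2, 2), "log2")),
        "already")
    expect_error(ExpressionExperiment(
        matrix(1, 2, 2, dimnames = list(c("g", "g"), c("a", "b")))),
        "duplicate")
})

test_that("per-gene Z-scores match hand arithmetic and center to zero", {
    z <- zscoreByGene(mkExpr(matrix(c(1, 3), 1, 2)))
    expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    set.seed(1)
    v <- matrix(rnorm(50), 10, 5)
    z <- zscoreByGene(mkExpr(v))
    expect_equal(unname(rowSums(z)), rep(0, 10), tolerance = 1e-12)
    ## constant gene: zero row plus a warning
    v[3, ] <- 5
    expect_warning(z <- zscoreByGene(mkExpr(v)), "zero-variance")
    expect_equal(unname(z[3, ]), rep(0, 5))
    expect_identical(attr(z, "zeroVarianceGenes"), "g3")
})

test_that("subtype scoring matches the two-sample hand oracle", {
    v <- matrix(c(1, 2, 5, 8, 3, 6, 1, 2), 4, 2,
                dimnames = list(c("b1", "b2", "c1", "c2"), c("s1", "s2")))
    out <- moffittClassify(mkExpr(v),
                           GeneSignature("BASAL", c("b1", "b2")),
                           GeneSignature("CLASSICAL", c("c1", "c2")))
    expect_equal(out$total_score, c(-4, 4) / sqrt(2), tolerance = 1e-12)
    expect_identical(out$label, c("Classical", "Basal-like"))
})

test_that("a zero total score is labeled Basal-like (boundary rule)", {
    ## symmetric construction: basal and classical z-sums coincide
    v <- matrix(c(1, 1, 3, 3), 2, 2,
                dimnames = list(c("b1", "c1"), c("s1", "s2")))
    out <- moffittClassify(mkExpr(v), GeneSignature("B", "b1"),
                           GeneSignature("C", "c1"))
    expect_equal(out$total_score, c(0, 0))
    expect_identical(out$label, c("Basal-like", "Basal-like"))
})

test_that("classification ignores sample order and unrelated genes", {
    set.seed(9)
    v <- matrix(rnorm(48, 8), 8, 6,
                dimnames = list(c(paste0("b", 1:3), paste0("c", 1:3),
                                  "x1", "x2"),
                                paste0("s", 1:6)))
    basal <- GeneSignature("B", paste0("b", 1:3))
    classical <- GeneSignature("C", paste0("c", 1:3))
    ref <- moffittClassify(mkExpr(v), basal, classical)
    perm <- moffittClassify(mkExpr(v[, c(4, 2, 6, 1, 3, 5)]), basal,
                            classical)
    perm <- perm[match(ref$sample_id, perm$sample_id), ]
    expect_equal(perm$total_score, ref$total_score, tolerance = 1e-12)
    more <- rbind(v, matrix(rnorm(12, 3), 2, 6,
                            dimnames = list(c("y1", "y2"), colnames(v))))
    expect_equal(moffittClassify(mkExpr(more), basal,
                                 classical)$total_score,
                 ref$total_score, tolerance = 1e-12)
})

test_that("missing and absent signature genes are handled", {
    v <- matrix(rnorm(12, 5), 3, 4,
                dimnames = list(c("b1", "b2", "c1"), paste0("s", 1:4)))
    expect_error(moffittClassify(mkExpr(v), GeneSignature("B", "zz"),
                                 GeneSignature("C", "c1")),
                 "no genes")
    expect_message(
        out <- moffittClassify(mkExpr(v),
                               GeneSignature("B", c("b1", "b2", "b9")),
                               GeneSignature("C", "c1")),
        "absent")
    expect_equal(unique(out$n_basal_used), 2L)
    expect_identical(attr(out, "missingGenes"), "b9")
})

test_that("label flips under classical-sign negation only when the score crosses zero", {
    set.seed(13)
    for (i in 1:20) {
        v <- matrix(rnorm(24, 8), 4, 6,
                    dimnames = list(c("b1", "b2", "c1", "c2"),
                                    paste0("s", 1:6)))
        m <- mkExpr(v)
        B <- GeneSignature("B", c("b1", "b2"))
        C <- GeneSignature("C", c("c1", "c2"))
        out <- moffittClassify(m, B, C)
        flipped <- out$z_basal_sum + out$z_classical_sum  # negated C term
        flipLabel <- ifelse(flipped >= 0, "Basal-like", "Classical")
        crossed <- (out$total_score >= 0) != (flipped >= 0)
        expect_identical(flipLabel != out$label, crossed)
    }
})

test_that("correlation ranking recovers exact and inverse relations", {
    sc <- c(s1 = 1, s2 = 2, s3 = 5, s4 = 9)
    v <- rbind(pos = sc, neg = -sc, mid = c(4, 4.5, 4, 5))
    colnames(v) <- names(sc)
    rk <- correlateWithScore(mkExpr(v), sc)
    e <- rankedEntries(rk)
    expect_identical(e$gene_id[1], "pos")
    expect_equal(e$r[1], 1, tolerance = 1e-12)
    expect_identical(e$gene_id[nrow(e)], "neg")
    expect_equal(e$r[nrow(e)], -1, tolerance = 1e-12)
    expect_identical(e$rank, seq_len(3L))
})

test_that("zero-variance genes are excluded from the ranking with a count", {
    sc <- c(s1 = 1, s2 = 2, s3 = 3)
    v <- rbind(a = c(1, 2, 3), flat = c(2, 2, 2), b = c(3, 1, 2))
    colnames(v) <- names(sc)
    rk <- correlateWithScore(mkExpr(v), sc)
    expect_equal(rk@nExcluded, 1L)
    expect_false("flat" %in% rankedEntries(rk)$gene_id)
})

test_that("correlations agree with a brute-force oracle to 1e-12", {
    set.seed(21)
    for (i in 1:50) {
        n <- sample(4:8, 1)
        g <- sample(3:10, 1)
        v <- matrix(rnorm(g * n), g, n,
                    dimnames = list(sprintf("g%02d", seq_len(g)),
                                    paste0("s", seq_len(n))))
        sc <- stats::setNames(rnorm(n), colnames(v))
        e <- rankedEntries(correlateWithScore(mkExpr(v), sc))
        ref <- vapply(e$gene_id, function(gi) bruteforceR(v[gi, ], sc),
                      numeric(1))
        expect_equal(e$r, unname(ref), tolerance = 1e-12)
    }
})

test_that("top/bottom extraction is exact, disjoint and tie-stable", {
    sc <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 5)
    v <- rbind(up = sc, dn = -sc, z2 = c(1, 1, 2, 2), z1 = c(1, 1, 2, 2))
    colnames(v) <- names(sc)
    rk <- correlateWithScore(mkExpr(v), sc)
    tb <- extractTopBottom(rk, k = 1)
    expect_identical(tb, list(top = "up", bottom = "dn"))
    ## tied genes (identical rows): lexicographic gene id wins
    tb2 <- extractTopBottom(rk, k = 2)
    expect_identical(tb2$top, c("up", "z1"))
    expect_length(intersect(tb2$top, tb2$bottom), 0)
    expect_error(extractTopBottom(rk, k = 3), "exceeds half")
})
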