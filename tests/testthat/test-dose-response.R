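test_that("responses are rescaled so the reference-dose mean is 100", {
    pts <- data.frame(dose = c(0.001, 0.001, 1, 10),
                      response = c(1900, 2100, 500, 100))
    out <- normalizeToReference(pts, 0.001)
    expect_equal(out$response, c(95, 105, 25, 5))
    expect_equal(attr(out, "referenceMean"), 2000)
    flat <- data.frame(dose = c(1, 10), response = c(7, 7))
    expect_equal(normalizeToReference(flat, 1)$response, c(100, 100))
    expect_error(normalizeToReference(pts, 99), "not present")
    ## anchoring one curve on another curve's reference wells
    other <- data.frame(dose = 10, response = 200)
    out2 <- normalizeToReference(other, 0.001, referencePoints = pts)
    expect_equal(out2$response, 10)
})

test_that("noise-free 4PL curves are recovered to optimizer precision", {
    d <- 10^seq(-2, 2, length.out = 9)
    y <- responses4PL(d, bottom = 12, top = 98, ec50 = 0.7, hill = -1.4)
    fit <- fit4PL(d, y)
    expect_true(fit@converged)
    expect_equal(ec50(fit), 0.7, tolerance = 1e-6)
    expect_equal(fit@bottom, 12, tolerance = 1e-4)
    expect_equal(fit@top, 98, tolerance = 1e-4)
    expect_equal(fit@hillSlope, -1.4, tolerance = 1e-4)
    ## rising curve (positive hill) recovered equally well
    y2 <- responses4PL(d, 5, 110, 3, 2)
    fit2 <- fit4PL(d, y2)
    expect_equal(ec50(fit2), 3, tolerance = 1e-6)
    expect_gt(fit2@hillSlope, 0)
})

test_that("EC50 recovery is exact across 50 random noise-free curves", {
    set.seed(31)
    for (i in 1:50) {
        ec <- 10^runif(1, -1, 1)
        hill <- sample(c(-1, 1), 1) * runif(1, 0.5, 3)
        bottom <- runif(1, 0, 30)
        top <- runif(1, 70, 120)
        d <- ec * 10^seq(-2, 2, length.out = sample(6:10, 1))
        fit <- fit4PL(d, responses4PL(d, bottom, top, ec, hill))
        expect_equal(ec50(fit), ec, tolerance = 1e-4)
    }
})

test_that("the robust loss beats a dense grid-search oracle", {
    set.seed(5)
    d <- rep(10^seq(-2, 2, length.out = 6), each = 2)
    y <- responses4PL(d, 10, 100, 1, -1) * rlnorm(length(d), 0, 0.08)
    fit <- fit4PL(d, y, fScale = 5)
    ## independent brute force over the 4PL parameter box
    grid <- expand.grid(bottom = seq(0, 30, by = 2),
                        top = seq(80, 120, by = 2),
                        l10 = seq(-1, 1, by = 0.05),
                        hill = seq(-3, 3, by = 0.25))
    soft <- function(r) 25 * sum(2 * (sqrt(1 + (r / 5)^2) - 1))
    best <- Inf
    ld <- log10(d)
    for (i in seq_len(nrow(grid))) {
        p <- as.numeric(grid[i, ])
        mu <- p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - ld) * p[4]))
        v <- soft(y - mu)
        if (v < best) best <- v
    }
    expect_lte(fit@loss, best + 1e-8)
})

test_that("flat data is flagged as hill-unidentifiable, not an error", {
    d <- 10^seq(-2, 2, length.out = 5)
    fit <- fit4PL(d, rep(80, 5))
    expect_false(fit@hillIdentifiable)
    expect_equal(fit@bottom, 80)
    expect_equal(fit@top, 80)
    expect_error(fit4PL(c(1, 2, 3, 0), rep(1, 4)), "> 0")
    expect_error(fit4PL(c(1, 1, 2, 2), 1:4), "4 distinct doses")
})

test_that("EC50 is the dose at the half-maximal response", {
    fit <- new("FourPLFit", bottom = 0, top = 100, log10Ec50 = 2,
               hillSlope = -1, loss = 0, converged = TRUE,
               hillIdentifiable = TRUE, nPoints = 8L)
    expect_equal(ec50(fit), 100)
    ## the fitted curve passes through (EC50, midpoint)
    mid <- fit@bottom + (fit@top - fit@bottom) /
        (1 + 10^((fit@log10Ec50 - log10(ec50(fit))) * fit@hillSlope))
    expect_equal(mid, (fit@top + fit@bottom) / 2)
})

test_that("log-dose AUC matches hand trapezoids and is monotone", {
    flat <- new("FourPLFit", bottom = 100, top = 100, log10Ec50 = 0,
                hillSlope = 0, loss = 0, converged = TRUE,
                hillIdentifiable = FALSE, nPoints = 4L)
    expect_equal(aucLogDose(flat, c(1, 1000)), 300)
    ## linear 100 -> 0 over 2 log10 units, from raw points: area = 100
    pts <- data.frame(dose = c(1, 10, 100), response = c(100, 50, 0))
    expect_equal(aucLogDose(pts), 100)
    ## pointwise-higher curve has strictly larger AUC
    lower <- new("FourPLFit", bottom = 5, top = 90, log10Ec50 = 0.5,
                 hillSlope = -1, loss = 0, converged = TRUE,
                 hillIdentifiable = TRUE, nPoints = 8L)
    higher <- new("FourPLFit", bottom = 15, top = 100, log10Ec50 = 0.5,
                  hillSlope = -1, loss = 0, converged = TRUE,
                  hillIdentifiable = TRUE, nPoints = 8L)
    expect_gt(aucLogDose(higher, c(0.01, 100)),
              aucLogDose(lower, c(0.01, 100)))
})

test_that("fits ignore point order and replicate duplication", {
    set.seed(17)
    d <- 10^seq(-2, 2, length.out = 7)
    y <- responses4PL(d, 10, 100, 0.8, -1.2) * rlnorm(7, 0, 0.05)
    f1 <- fit4PL(d, y)
    perm <- sample(7)
    f2 <- fit4PL(d[perm], y[perm])
    expect_equal(ec50(f2), ec50(f1), tolerance = 1e-6)
    f3 <- fit4PL(rep(d, 2), rep(y, 2))
    expect_equal(ec50(f3), ec50(f1), tolerance = 1e-4)
    expect_equal(f3@loss, 2 * f1@loss, tolerance = 1e-4)
})

test_that("median EC50 error stays below 15% at 5% response noise", {
    set.seed(23)
    errs <- replicate(200, {
        ec <- 10^runif(1, -0.5, 0.5)
        d <- ec * 10^seq(-2, 2, length.out = 7)
        y <- responses4PL(rep(d, 3), 10, 100, ec, -1.2) *
            rlnorm(21, 0, sqrt(log(1 + 0.05^2)))
        abs(ec50(fit4PL(rep(d, 3), y)) - ec) / ec
    })
    expect_lt(median(errs), 0.15)
})

test_that("subtype comparison matches the textbook pooled t-test", {
    sens <- data.frame(sample_id = paste0("s", 1:6),
                       auc = c(5.1, 4.8, 5.4, 3.2, 3.0, 3.5))
    lab <- stats::setNames(rep(c("High", "Low"), each = 3),
                           sens$sample_id)
    out <- compareSubtypes(sens, lab)
    x <- sens$auc[1:3]; y <- sens$auc[4:6]
    sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
    tHand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
    expect_equal(out$t, tHand, tolerance = 1e-12)
    expect_equal(out$p_value, 2 * stats::pt(-abs(tHand), 4),
                 tolerance = 1e-12)
    ## degenerate groups
    same <- data.frame(sample_id = paste0("s", 1:4), auc = rep(2, 4))
    expect_equal(compareSubtypes(same,
        stats::setNames(c("High", "High", "Low", "Low"),
                        same$sample_id))$p_value, 1)
    const <- data.frame(sample_id = paste0("s", 1:4),
                        auc = c(10, 10, 1, 1))
    expect_equal(compareSubtypes(const,
        stats::setNames(c("High", "High", "Low", "Low"),
                        const$sample_id))$p_value, 0)
})

test_that("Spearman correlation reports concordant and reversed ranks", {
    sc <- data.frame(sample_id = paste0("s", 1:5), score = 1:5)
    up <- data.frame(sample_id = paste0("s", 1:5), auc = c(2, 3, 5, 8, 9))
    expect_equal(spearmanNicheVsAuc(sc, up)$rho, 1)
    dn <- data.frame(sample_id = paste0("s", 1:5), auc = rev(up$auc))
    expect_equal(spearmanNicheVsAuc(sc, dn)$rho, -1)
})

test_that("the R-spondin scenario reproduces its designed potencies", {
    cfg <- scenarioConfig(seed = 1, doseCV = 0)
    dr <- generateDoseResponse(cfg, drugs = c("RSPO1", "RSPO3"))
    r1 <- dr[dr$drug == "RSPO1", ]
    r3 <- dr[dr$drug == "RSPO3", ]
    ## both curves anchored on the top RSPO1 dose
    r1n <- normalizeToReference(r1, 1000)
    r3n <- normalizeToReference(r3, 1000, referencePoints = r1)
    e1 <- ec50(fit4PL(r1n$dose, r1n$response))
    e3 <- ec50(fit4PL(r3n$dose, r3n$response))
    expect_equal(e1, 252.5, tolerance = 1e-4)
    expect_equal(e3, 63.89, tolerance = 1e-4)
    expect_lt(e3, e1)
})
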