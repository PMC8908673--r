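#' @importFrom stats rnorm rlnorm runif
NULL

## canonical niche factors of the organoid medium
NICHE_FACTORS <- c("Wnt3a", "RSPO1", "Noggin", "EGF", "FGF10", "A83-01")

## mevalonate-pathway enzymes used as the niche-coupled gene set
MEVALONATE_GENES <- c("HMGCR", "HMGCS1", "MVK", "PMVK", "MVD", "IDI1",
                      "FDPS", "FDFT1", "SQLE", "LSS", "ACAT2", "DHCR7")

#' Build a simulation scenario
#'
#' Constructs a \linkS4class{ScenarioConfig} describing an 8-organoid
#' pancreatic-cancer study: three well differentiated (Grade1) organoid lines
#' with high designed niche-factor dependency and Classical expression
#' subtype, three moderately differentiated (Grade2) lines spanning the
#' subtype boundary, and two poorly differentiated (Grade3) Basal-like lines
#' with low niche dependency. Classical-signature genes are elevated in
#' Classical-designed samples, Basal-signature genes in the complement, and
#' mevalonate-pathway genes increase linearly with the designed niche score.
#' Growth folds make Grade1 lines grow only with niche factors while Grade3
#' lines grow faster in serum; gemcitabine potency decreases (EC50 rises)
#' with niche dependency while simvastatin potency increases; an R-spondin
#' potency scenario carries 4PL truth curves for RSPO1 and RSPO3.
#'
#' All arguments override the defaults; pass \code{samples} as a data.frame
#' with columns \code{sample_id}, \code{grade}, \code{niche_score},
#' \code{subtype}.
#'
#' @param seed integer base seed used by every generator.
#' @param samples study samples and their designed truth (see above).
#' @param nBackgroundGenes unstructured genes in the simulated array.
#' @param signatureSizes named integer vector (basal, classical, mevalonate).
#' @param signatureEffect log2 shift of signature genes in their subtype.
#' @param mevalonateSlope log2 units per unit niche score.
#' @param exprNoiseSd log2 Gaussian noise SD for expression.
#' @param mevalonateNoiseSd noise SD for mevalonate genes; \code{NA} uses
#'   \code{exprNoiseSd}.
#' @param growth per-(grade, medium) expected fold change and replicate CV.
#' @param dropout per-(grade, factor) fold multiplier on factor withdrawal.
#' @param seedingCells,blankLum,perCellSignal luminescence assay calibration.
#' @param nReplicates day-10 wells per sample and condition.
#' @param drugs 4PL truth table (drug, sample_id, bottom, top, ec50, hill,
#'   dose_unit).
#' @param doseGrids named list of dose grids per drug.
#' @param doseCV,doseReplicates response noise CV and replicates per dose.
#' @param imageObjects data.frame (image_id, area_um2) of drawn organoids.
#' @param umPerPixel,imageSize image calibration and side length (pixels).
#' @param stainFractions designed stain-positive percent per grade.
#' @param qpcr Ct truth table (gene, condition, ct_mean, ct_sd).
#' @param qpcrReplicates qPCR replicates.
#' @return a validated \linkS4class{ScenarioConfig}.
#' @examples
#' cfg <- scenarioConfig(seed = 1)
#' cfg
#' @export
scenarioConfig <- function(seed = 1L,
                           samples = NULL,
                           nBackgroundGenes = 5000L,
                           signatureSizes = c(basal = 25L, classical = 25L,
                                              mevalonate = 12L),
                           signatureEffect = 2,
                           mevalonateSlope = 0.5,
                           exprNoiseSd = 0.25,
                           mevalonateNoiseSd = NA_real_,
                           growth = NULL,
                           dropout = NULL,
                           seedingCells = 5000,
                           blankLum = 200,
                           perCellSignal = 50,
                           nReplicates = 9L,
                           drugs = NULL,
                           doseGrids = NULL,
                           doseCV = 0.05,
                           doseReplicates = 3L,
                           imageObjects = NULL,
                           umPerPixel = 2,
                           imageSize = 512L,
                           stainFractions = NULL,
                           qpcr = NULL,
                           qpcrReplicates = 3L) {
    if (is.null(samples))
        samples <- data.frame(
            sample_id = c("PDO565", "PDO571", "PDO585", "PDO573",
                          "PDO578", "PDO580", "PDO497", "PDO501"),
            grade = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
            niche_score = c(6.0, 5.0, 4.5, 2.0, 1.2, 0.9, 0.6, 0.5),
            subtype = c("Classical", "Classical", "Classical", "Classical",
                        "Basal-like", "Basal-like", "Basal-like",
                        "Basal-like"),
            stringsAsFactors = FALSE)
    if (is.null(growth))
        growth <- data.frame(
            grade = rep(1:3, each = 2),
            medium = rep(c("serum", "combined"), 3),
            fold = c(1.0, 7.0,   # Grade1: no serum growth
                     2.0, 5.0,
                     4.5, 5.5),  # Grade3: serum-proficient
            cv = 0.10)
    if (is.null(dropout))
        dropout <- data.frame(
            grade = rep(1:3, times = 6),
            factor = rep(NICHE_FACTORS, each = 3),
            multiplier = c(1.00, 1.00, 1.00,   # Wnt3a: no exogenous-Wnt need
                           0.25, 0.55, 0.95,   # RSPO1
                           0.60, 0.75, 0.95,   # Noggin
                           0.50, 0.60, 0.90,   # EGF
                           0.80, 0.85, 0.95,   # FGF10
                           0.70, 0.80, 0.90))  # A83-01
    if (is.null(drugs)) {
        gemEc50 <- c(PDO565 = 50, PDO571 = 42, PDO585 = 36, PDO573 = 25,
                     PDO578 = 4, PDO580 = 3, PDO497 = 1.6, PDO501 = 1.3)
        simEc50 <- c(PDO565 = 1.2, PDO571 = 1.5, PDO585 = 1.8, PDO573 = 3.5,
                     PDO578 = 14, PDO580 = 18, PDO497 = 28, PDO501 = 32)
        ids <- samples$sample_id
        drugs <- rbind(
            data.frame(drug = "gemcitabine", sample_id = ids, bottom = 10,
                       top = 100,
                       ec50 = unname(gemEc50[ids]), hill = -1.2,
                       dose_unit = "nM", stringsAsFactors = FALSE),
            data.frame(drug = "simvastatin", sample_id = ids, bottom = 15,
                       top = 100,
                       ec50 = unname(simEc50[ids]), hill = -1.0,
                       dose_unit = "uM", stringsAsFactors = FALSE),
            data.frame(drug = c("RSPO1", "RSPO3"), sample_id = "PDO585",
                       bottom = 20, top = c(105, 102),
                       ec50 = c(252.5, 63.89), hill = 1.1,
                       dose_unit = "ng/ml", stringsAsFactors = FALSE))
        drugs <- drugs[drugs$sample_id %in% ids | drugs$drug %in%
                       c("RSPO1", "RSPO3"), , drop = FALSE]
    }
    if (is.null(doseGrids))
        doseGrids <- list(
            gemcitabine = 10^seq(-3, 3, by = 1),          # nM
            simvastatin = 10^seq(-3, 2, by = 1),          # uM
            RSPO1 = 10^seq(0, 3, length.out = 9),         # ng/ml
            RSPO3 = 10^seq(0, 3, length.out = 9))
    if (is.null(imageObjects))
        imageObjects <- data.frame(
            image_id = "well1",
            area_um2 = c(900, 1500, 2000, 2500, 3200, 4500, 6000, 9000))
    if (is.null(stainFractions))
        stainFractions <- data.frame(grade = 1:3,
                                     fraction = c(30, 18, 8))
    if (is.null(qpcr)) {
        conds <- c("2D_SM", "3D_SM", "3D_PDO-CM")
        qpcr <- data.frame(
            gene = rep(c("GAPDH", "RSPO1", "RSPO2", "RSPO3", "RSPO4"),
                       each = 3),
            condition = rep(conds, 5),
            ct_mean = c(18.0, 18.0, 18.0,
                        27.0, 27.0, 27.1,
                        28.0, 28.1, 28.0,
                        27.5, 27.2, 24.5,   # RSPO3 induced by organoid CM
                        29.0, 29.0, 29.05),
            ct_sd = 0.15, stringsAsFactors = FALSE)
    }
    cfg <- new("ScenarioConfig",
        seed = as.integer(seed), samples = samples,
        nBackgroundGenes = as.integer(nBackgroundGenes),
        signatureSizes = vapply(signatureSizes, as.integer, integer(1)),
        signatureEffect = signatureEffect, mevalonateSlope = mevalonateSlope,
        exprNoiseSd = exprNoiseSd, mevalonateNoiseSd = mevalonateNoiseSd,
        growth = growth, dropout = dropout, seedingCells = seedingCells,
        blankLum = blankLum, perCellSignal = perCellSignal,
        nReplicates = as.integer(nReplicates), drugs = drugs,
        doseGrids = doseGrids, doseCV = doseCV,
        doseReplicates = as.integer(doseReplicates),
        imageObjects = imageObjects, umPerPixel = umPerPixel,
        imageSize = as.integer(imageSize), stainFractions = stainFractions,
        qpcr = qpcr, qpcrReplicates = as.integer(qpcrReplicates))
    validObject(cfg)
    cfg
}

## designed per-sample fold change for one medium condition token
designedFold <- function(cfg, sampleId, condition) {
    s <- cfg@samples[cfg@samples$sample_id == sampleId, ]
    if (nrow(s) != 1L) stop("unknown sample: ", sampleId)
    gr <- cfg@growth[cfg@growth$grade == s$grade, ]
    serumFold <- gr$fold[gr$medium == "serum"]
    if (condition == "serum") return(serumFold)
    if (condition == "combined") return(gr$fold[gr$medium == "combined"])
    ## niche fold is anchored to the designed score: score = niche / serum
    nicheFold <- s$niche_score * serumFold
    if (condition == "niche") return(nicheFold)
    if (startsWith(condition, "niche-")) {
        fac <- sub("^niche-", "", condition)
        d <- cfg@dropout[cfg@dropout$grade == s$grade &
                         cfg@dropout$factor == fac, ]
        if (nrow(d) != 1L) stop("no dropout multiplier for factor: ", fac)
        return(nicheFold * d$multiplier)
    }
    stop("unknown condition token: ", condition)
}

## lognormal multiplicative noise with unit mean and given CV
lnormNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a gene-by-sample expression matrix with designed structure
#'
#' Generates raw (linear-scale) intensities for background genes, the two
#' subtype signatures and the mevalonate set. On the log2 scale, a signature
#' gene's mean is its baseline plus \code{signatureEffect} in samples of its
#' designed subtype; a mevalonate gene's mean is baseline +
#' \code{mevalonateSlope} times the sample's designed niche score; background
#' genes carry only gene-specific baselines plus noise.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @return list with \code{expr} (\linkS4class{ExpressionExperiment}, scale
#'   \code{"raw"}, designed truth in \code{colData}), \code{signatures}
#'   (named list of \linkS4class{GeneSignature}: basal, classical,
#'   mevalonate), and \code{truth} (designed subtype and niche score per
#'   sample).
#' @examples
#' sim <- generateExpression(scenarioConfig(seed = 7, nBackgroundGenes = 100))
#' dim(sim$expr)
#' @export
generateExpression <- function(cfg) {
    stopifnot(is(cfg, "ScenarioConfig"))
    set.seed(cfg@seed + 1L)
    sizes <- cfg@signatureSizes
    if (sum(sizes) > cfg@nBackgroundGenes)
        stop("signature sizes exceed the gene universe: ",
             sum(sizes), " signature genes vs ", cfg@nBackgroundGenes,
             " background genes")
    nBg <- cfg@nBackgroundGenes
    bgIds <- sprintf("BG%05d", seq_len(nBg))
    basalIds <- sprintf("BASAL_%03d", seq_len(sizes[["basal"]]))
    classicalIds <- sprintf("CLASSICAL_%03d", seq_len(sizes[["classical"]]))
    nMev <- sizes[["mevalonate"]]
    mevIds <- if (nMev <= length(MEVALONATE_GENES))
        MEVALONATE_GENES[seq_len(nMev)]
    else c(MEVALONATE_GENES,
           sprintf("MEV_%03d", seq_len(nMev - length(MEVALONATE_GENES))))

    smp <- cfg@samples
    nS <- nrow(smp)
    sdBg <- cfg@exprNoiseSd
    sdMev <- if (is.na(cfg@mevalonateNoiseSd)) sdBg else cfg@mevalonateNoiseSd
    isClassical <- smp$subtype == "Classical"

    bgBase <- runif(nBg, 4, 12)
    bg <- matrix(rnorm(nBg * nS, mean = bgBase, sd = sdBg), nrow = nBg)
    bas <- matrix(7 + rnorm(sizes[["basal"]] * nS, sd = sdBg),
                  nrow = sizes[["basal"]])
    bas <- bas + cfg@signatureEffect *
        matrix(rep(as.numeric(!isClassical), each = sizes[["basal"]]),
               nrow = sizes[["basal"]])
    cla <- matrix(7 + rnorm(sizes[["classical"]] * nS, sd = sdBg),
                  nrow = sizes[["classical"]])
    cla <- cla + cfg@signatureEffect *
        matrix(rep(as.numeric(isClassical), each = sizes[["classical"]]),
               nrow = sizes[["classical"]])
    mevMean <- outer(rep(5.5, nMev), cfg@mevalonateSlope * smp$niche_score,
                     "+")
    mev <- mevMean + matrix(rnorm(nMev * nS, sd = sdMev), nrow = nMev)

    log2mat <- rbind(bg, bas, cla, mev)
    rownames(log2mat) <- c(bgIds, basalIds, classicalIds, mevIds)
    colnames(log2mat) <- smp$sample_id

    expr <- ExpressionExperiment(2^log2mat, scale = "raw",
        colData = S4Vectors::DataFrame(
            grade = smp$grade,
            designed_subtype = smp$subtype,
            designed_niche_score = smp$niche_score,
            row.names = smp$sample_id))
    sigs <- list(
        basal = GeneSignature("BASAL", basalIds),
        classical = GeneSignature("CLASSICAL", classicalIds),
        mevalonate = GeneSignature("MEVALONATE", mevIds))
    truth <- data.frame(sample_id = smp$sample_id, grade = smp$grade,
                        designed_subtype = smp$subtype,
                        designed_niche_score = smp$niche_score,
                        stringsAsFactors = FALSE)
    list(expr = expr, signatures = sigs, truth = truth)
}

#' Simulate well-level luminescence growth plates
#'
#' For each sample the generator emits day-0 control wells (the seeded
#' 5,000-cell measurement), day-10 wells for each medium condition (full
#' niche, serum, combined, and single-factor dropouts), and medium-only
#' blank wells. Luminescence is
#' \code{blankLum + cells * perCellSignal}; day-10 cell numbers are the
#' seeded count times the designed fold change times lognormal replicate
#' noise. The designed niche-medium fold is anchored so that
#' fold(niche)/fold(serum) equals the sample's designed niche score.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @param conditions condition tokens to emit (default: niche, serum,
#'   combined and the six single-factor dropouts).
#' @return long-format data.frame with columns \code{sample_id},
#'   \code{condition}, \code{day}, \code{replicate}, \code{luminescence},
#'   \code{is_blank}.
#' @export
generateGrowthPlates <- function(cfg,
        conditions = c("niche", "serum", "combined",
                       paste0("niche-", NICHE_FACTORS))) {
    stopifnot(is(cfg, "ScenarioConfig"))
    set.seed(cfg@seed + 2L)
    out <- list()
    day0Lum <- cfg@blankLum + cfg@seedingCells * cfg@perCellSignal
    for (sid in cfg@samples$sample_id) {
        out[[length(out) + 1L]] <- data.frame(
            sample_id = sid, condition = "control", day = 0L,
            replicate = 1:3, luminescence = day0Lum, is_blank = FALSE)
        for (cond in conditions) {
            fold <- designedFold(cfg, sid, cond)
            gr <- cfg@samples$grade[cfg@samples$sample_id == sid]
            cv <- cfg@growth$cv[cfg@growth$grade == gr][1]
            cells <- cfg@seedingCells * fold *
                lnormNoise(cfg@nReplicates, cv)
            out[[length(out) + 1L]] <- data.frame(
                sample_id = sid, condition = cond, day = 10L,
                replicate = seq_len(cfg@nReplicates),
                luminescence = cfg@blankLum + cells * cfg@perCellSignal,
                is_blank = FALSE)
        }
    }
    ## medium-only blanks, shared across samples
    blanks <- expand.grid(condition = c("control", conditions),
                          replicate = 1:3, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
        sample_id = "blank", condition = blanks$condition, day = 10L,
        replicate = blanks$replicate, luminescence = cfg@blankLum,
        is_blank = TRUE)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## truth-curve response of the configured 4PL for one drug/sample row
truth4PL <- function(row, dose) {
    row$bottom + (row$top - row$bottom) /
        (1 + 10^((log10(row$ec50) - log10(dose)) * row$hill))
}

#' Simulate dose-response viability wells from the configured 4PL truths
#'
#' Each (drug, sample) pair draws replicate responses at every dose of the
#' drug's grid from its truth curve, with multiplicative lognormal noise of
#' CV \code{doseCV}. The R-spondin potency scenario (RSPO1/RSPO3 truth
#' curves for a Grade1 line) is part of the default configuration.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @param drugs subset of drugs to generate (default: all configured).
#' @return long-format data.frame with columns \code{drug},
#'   \code{sample_id}, \code{dose}, \code{dose_unit}, \code{replicate},
#'   \code{response}.
#' @export
generateDoseResponse <- function(cfg, drugs = unique(cfg@drugs$drug)) {
    stopifnot(is(cfg, "ScenarioConfig"))
    set.seed(cfg@seed + 3L)
    out <- list()
    tab <- cfg@drugs[cfg@drugs$drug %in% drugs, , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        grid <- cfg@doseGrids[[row$drug]]
        if (is.null(grid)) stop("no dose grid for drug: ", row$drug)
        mu <- truth4PL(row, grid)
        for (rep in seq_len(cfg@doseReplicates)) {
            out[[length(out) + 1L]] <- data.frame(
                drug = row$drug, sample_id = row$sample_id, dose = grid,
                dose_unit = row$dose_unit, replicate = rep,
                response = mu * lnormNoise(length(grid), cfg@doseCV))
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## rasterize one filled ellipse of the target pixel area; returns logical mask
ellipseMask <- function(size, cx, cy, areaPx, aspect, theta) {
    a <- sqrt(areaPx / (pi * aspect))
    b <- aspect * a
    x <- matrix(rep(seq_len(size), each = size), nrow = size) - cx
    y <- matrix(rep(seq_len(size), times = size), nrow = size) - cy
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    (xr / a)^2 + (yr / b)^2 <= 1
}

#' Simulate calibrated organoid and stain images with ground truth
#'
#' Organoid images contain non-overlapping bright ellipses of the configured
#' areas (um^2) on a dark background; placement uses a jittered grid so
#' objects never touch. Stain images contain the configured percentage of
#' bright (stain-positive) pixels. Ground truth (drawn pixel areas, designed
#' positive fractions) is returned next to the pixel data so downstream
#' quantification can be checked without re-deriving it.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @return list with \code{organoid}: per image id a list of \code{pixels}
#'   (matrix in [0,1]), \code{um_per_pixel} and \code{truth} (data.frame of
#'   designed and drawn areas); and \code{stain}: per grade a list of
#'   \code{pixels} and \code{truth_fraction} (exact percent of bright
#'   pixels).
#' @export
generateImages <- function(cfg) {
    stopifnot(is(cfg, "ScenarioConfig"))
    set.seed(cfg@seed + 4L)
    size <- cfg@imageSize
    ump <- cfg@umPerPixel
    organoid <- list()
    for (img in unique(cfg@imageObjects$image_id)) {
        areas <- cfg@imageObjects$area_um2[cfg@imageObjects$image_id == img]
        pix <- matrix(0.08, size, size)
        nObj <- length(areas)
        ## jittered grid placement: cells large enough that objects never touch
        nCell <- ceiling(sqrt(nObj))
        cw <- size / nCell
        cells <- sample(nCell^2, nObj)
        drawn <- numeric(nObj)
        for (k in seq_len(nObj)) {
            ci <- (cells[k] - 1) %% nCell
            cj <- (cells[k] - 1) %/% nCell
            areaPx <- areas[k] / ump^2
            rmax <- sqrt(areaPx / pi / 0.7)  # widest semi-axis
            lo <- rmax + 2
            cx <- ci * cw + runif(1, lo, max(cw - lo, lo))
            cy <- cj * cw + runif(1, lo, max(cw - lo, lo))
            m <- ellipseMask(size, cx, cy, areaPx, runif(1, 0.7, 1),
                             runif(1, 0, pi))
            pix[m] <- 0.85
            drawn[k] <- sum(m)
        }
        pix <- pix + matrix(rnorm(size^2, sd = 0.02), size, size)
        pix[pix < 0] <- 0; pix[pix > 1] <- 1
        organoid[[img]] <- list(
            pixels = pix, um_per_pixel = ump,
            truth = data.frame(area_um2 = areas,
                               drawn_area_um2 = drawn * ump^2))
    }
    stain <- list()
    for (i in seq_len(nrow(cfg@stainFractions))) {
        gr <- cfg@stainFractions$grade[i]
        frac <- cfg@stainFractions$fraction[i]
        nPos <- round(frac / 100 * size^2)
        pix <- matrix(0.1, size, size)
        pix[sample(size^2, nPos)] <- 0.9
        stain[[paste0("grade", gr)]] <- list(
            pixels = pix, um_per_pixel = ump,
            truth_fraction = 100 * nPos / size^2)
    }
    list(organoid = organoid, stain = stain)
}

#' Simulate a qPCR Ct table
#'
#' Replicate Ct values are drawn Normal(\code{ct_mean}, \code{ct_sd}) for
#' every configured gene and condition, including the reference gene.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct}.
#' @export
generateQpcr <- function(cfg) {
    stopifnot(is(cfg, "ScenarioConfig"))
    set.seed(cfg@seed + 5L)
    tab <- cfg@qpcr
    n <- cfg@qpcrReplicates
    out <- tab[rep(seq_len(nrow(tab)), each = n),
               c("gene", "condition"), drop = FALSE]
    out$replicate <- rep(seq_len(n), nrow(tab))
    out$ct <- rnorm(nrow(out),
                    mean = rep(tab$ct_mean, each = n),
                    sd = rep(tab$ct_sd, each = n))
    rownames(out) <- NULL
    out
}

#' Designed ground truth of a scenario
#'
#' Collects everything downstream checks compare against: designed subtype
#' and niche score per sample, the median-split High/Low niche membership
#' implied by the designed scores, the drug truth table, and the designed
#' log-dose AUC of every truth curve over its dose grid.
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @return list of truth tables.
#' @export
scenarioTruth <- function(cfg) {
    smp <- cfg@samples
    med <- stats::median(smp$niche_score)
    niche <- data.frame(sample_id = smp$sample_id,
                        designed_niche_score = smp$niche_score,
                        designed_subtype = smp$subtype,
                        niche_class = ifelse(smp$niche_score > med,
                                             "High", "Low"),
                        stringsAsFactors = FALSE)
    dr <- cfg@drugs
    dr$designed_auc <- vapply(seq_len(nrow(dr)), function(i) {
        grid <- cfg@doseGrids[[dr$drug[i]]]
        lg <- seq(log10(min(grid)), log10(max(grid)), length.out = 513)
        y <- truth4PL(dr[i, ], 10^lg)
        sum((y[-1] + y[-length(y)]) / 2 * diff(lg))
    }, numeric(1))
    list(samples = niche, drugs = dr,
         stain_fractions = cfg@stainFractions)
}
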