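#' @importFrom utils packageVersion modifyList
NULL

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(
        paste0("ScenarioConfig: %d samples (grades %s), %d background",
               " genes, seed %d\n"),
        nrow(object@samples),
        paste(object@samples$grade, collapse = "/"),
        object@nBackgroundGenes, object@seed))
})

defaultRunParams <- function() list(
    k = 1000L,
    nichePolicy = "median",
    nicheThreshold = NULL,
    includeSamples = NULL,
    referenceDose = list(gemcitabine = 0.001, simvastatin = 0.001),
    minAreaUm2 = 2000,
    qpcrTargets = c("RSPO1", "RSPO2", "RSPO3", "RSPO4"),
    qpcrRef = "GAPDH",
    qpcrBaseline = "2D_SM")

#' Run the full organoid study pipeline
#'
#' Orchestrates simulate (optional) -> expression normalization and
#' subtyping -> niche-dependency scoring -> correlation ranking ->
#' dose-response fitting and subtype comparison -> image quantification ->
#' qPCR quantification. Stages communicate through files under
#' \code{outDir}; each stage runs only when its inputs are present, records
#' success or failure, and a failed stage skips its dependents. The whole
#' run is deterministic given the seed.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer; seeds the simulator.}
#'     \item{outDir}{output directory.}
#'     \item{simulate}{optional list of \code{\link{scenarioConfig}}
#'       arguments; when present, all inputs are generated.}
#'     \item{inputs}{paths: \code{expression}, \code{signatures} (GMT with
#'       sets BASAL and CLASSICAL), \code{growth}, \code{dose},
#'       \code{imagesDir}, \code{qpcr}; any subset.}
#'     \item{params}{analysis parameters overriding
#'       \code{k = 1000}, \code{nichePolicy = "median"},
#'       \code{referenceDose} per drug, \code{minAreaUm2 = 2000}, qPCR
#'       target/reference/baseline.}
#'   }
#' @return the study report (list), invisibly also written to
#'   \code{outDir/report.json}: per-stage status, subtype scores, niche
#'   scores, drug sensitivities, group comparisons, ranking summary, and
#'   provenance (seed, package version, parameters).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outDir <- if (is.null(config$outDir)) tempfile("nichescreen_run")
        else config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    params <- modifyList(defaultRunParams(),
                         if (is.null(config$params)) list()
                         else config$params)
    inputs <- if (is.null(config$inputs)) list() else config$inputs

    report <- list(
        provenance = list(
            package = "NicheScreen",
            version = as.character(packageVersion("NicheScreen")),
            seed = seed,
            params = params),
        stages = list())
    failed <- character(0)

    runStage <- function(name, deps, fun) {
        if (length(intersect(deps, failed))) {
            report$stages[[name]] <<- list(status = "skipped",
                reason = paste("upstream failure:",
                               paste(intersect(deps, failed),
                                     collapse = ", ")))
            failed <<- c(failed, name)
            return(NULL)
        }
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(fun(), error = function(e) e)
        el <- round(proc.time()[["elapsed"]] - t0, 3)
        if (inherits(res, "error")) {
            report$stages[[name]] <<- list(status = "failed",
                error = conditionMessage(res), seconds = el)
            failed <<- c(failed, name)
            NULL
        } else {
            report$stages[[name]] <<- list(status = "ok", seconds = el)
            res
        }
    }

    ## -- simulate -----------------------------------------------------
    if (!is.null(config$simulate)) {
        simDir <- file.path(outDir, "simulated")
        runStage("simulate", character(0), function() {
            args <- config$simulate
            args$seed <- seed
            cfg <- do.call(scenarioConfig, args)
            simulateScenario(cfg, simDir)
        })
        if (!"simulate" %in% failed)
            inputs <- modifyList(list(
                expression = file.path(simDir, "expression.tsv"),
                signatures = file.path(simDir, "signatures.gmt"),
                growth = file.path(simDir, "growth.csv"),
                dose = file.path(simDir, "dose_response.csv"),
                imagesDir = file.path(simDir, "images"),
                qpcr = file.path(simDir, "qpcr.csv")), inputs)
    }

    norm <- NULL
    ## -- expression subtyping -----------------------------------------
    if (!is.null(inputs$expression) && !is.null(inputs$signatures)) {
        res <- runStage("expression", "simulate", function() {
            expr <- readExpressionTsv(inputs$expression, scale = "raw")
            sigs <- readGmt(inputs$signatures)
            if (!all(c("BASAL", "CLASSICAL") %in% names(sigs)))
                stop("signature GMT must contain sets BASAL and CLASSICAL")
            nm <- log2QuantileNormalize(expr)
            scores <- moffittClassify(nm, sigs$BASAL, sigs$CLASSICAL)
            write.table(scores, file.path(outDir, "subtype_scores.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            list(norm = nm, scores = scores)
        })
        if (!is.null(res)) {
            norm <- res$norm
            report$subtype_scores <- res$scores
        }
    }

    ## -- growth / niche dependency ------------------------------------
    nicheScores <- NULL
    if (!is.null(inputs$growth)) {
        nicheScores <- runStage("niche", "simulate", function() {
            rec <- readGrowthCsv(inputs$growth)
            samples <- params$includeSamples
            sc <- nicheDependencyScores(rec, samples = samples)
            sc <- assignNicheSubtype(sc, policy = params$nichePolicy,
                                     threshold = params$nicheThreshold)
            write.table(sc, file.path(outDir, "niche_scores.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            sc
        })
        report$niche_scores <- nicheScores
    }

    ## -- correlation ranking ------------------------------------------
    if (!is.null(inputs$expression) && !is.null(inputs$signatures) &&
        !is.null(inputs$growth)) {
        res <- runStage("correlate", c("expression", "niche"), function() {
            sc <- stats::setNames(nicheScores$score, nicheScores$sample_id)
            rk <- correlateWithScore(norm, sc)
            tb <- extractTopBottom(rk, k = min(params$k,
                nrow(rankedEntries(rk)) %/% 2))
            write.table(rankedEntries(rk),
                        file.path(outDir, "correlation_ranking.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            list(nRanked = nrow(rankedEntries(rk)),
                 nExcluded = rk@nExcluded,
                 top = tb$top, bottom = tb$bottom)
        })
        if (!is.null(res))
            report$correlation <- list(
                n_ranked = res$nRanked, n_excluded = res$nExcluded,
                k = length(res$top),
                top = res$top, bottom = res$bottom)
    }

    ## -- dose response -------------------------------------------------
    if (!is.null(inputs$dose)) {
        res <- runStage("dose_response", c("simulate"), function() {
            d <- readDoseResponseCsv(inputs$dose)
            out <- list()
            for (drug in unique(d$drug)) {
                dd <- d[d$drug == drug, , drop = FALSE]
                refDose <- params$referenceDose[[drug]]
                sens <- fitDoseResponse(dd, referenceDose = refDose)
                out[[drug]] <- sens
            }
            allSens <- do.call(rbind, out)
            rownames(allSens) <- NULL
            write.table(allSens, file.path(outDir, "drug_sensitivity.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            out
        })
        if (!is.null(res)) {
            report$drug_sensitivity <- do.call(rbind, unname(res))
            ## subtype comparisons need the niche labels
            if (!is.null(nicheScores)) {
                labels <- stats::setNames(nicheScores$subtype,
                                          nicheScores$sample_id)
                cmp <- list()
                for (drug in names(res)) {
                    sens <- res[[drug]]
                    sens <- sens[sens$sample_id %in% names(labels), ,
                                 drop = FALSE]
                    if (length(unique(labels[sens$sample_id])) == 2L &&
                        nrow(sens) >= 4L) {
                        ttest <- compareSubtypes(sens,
                                                 labels[sens$sample_id])
                        rho <- spearmanNicheVsAuc(nicheScores, sens)
                        cmp[[drug]] <- list(t_test = ttest,
                                            spearman = rho)
                    }
                }
                report$group_comparisons <- cmp
            }
        }
    }

    ## -- imaging --------------------------------------------------------
    if (!is.null(inputs$imagesDir)) {
        res <- runStage("imaging", "simulate", function() {
            tifs <- list.files(inputs$imagesDir, pattern = "\\.tiff?$",
                               full.names = TRUE)
            rows <- lapply(tifs, function(p) {
                im <- readCalibratedImage(p)
                isStain <- grepl("^stain_", basename(p))
                if (isStain)
                    data.frame(image = basename(p), type = "stain",
                               organoid_count = NA_integer_,
                               total_area_um2 = NA_real_,
                               positive_fraction =
                                   stainPositiveFraction(im$pixels))
                else {
                    seg <- applyAreaFilter(
                        segmentObjects(im$pixels, im$um_per_pixel),
                        params$minAreaUm2)
                    data.frame(image = basename(p), type = "organoid",
                               organoid_count = organoidCount(seg),
                               total_area_um2 = totalAreaUm2(seg),
                               positive_fraction = NA_real_)
                }
            })
            tab <- do.call(rbind, rows)
            write.table(tab, file.path(outDir, "image_quant.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            tab
        })
        report$image_quant <- res
    }

    ## -- qPCR -----------------------------------------------------------
    if (!is.null(inputs$qpcr)) {
        res <- runStage("qpcr", "simulate", function() {
            ct <- readCtCsv(inputs$qpcr)
            targets <- intersect(params$qpcrTargets, unique(ct$gene))
            folds <- do.call(rbind, lapply(targets, function(g)
                deltaDeltaCt(ct, g, params$qpcrRef, params$qpcrBaseline)))
            write.table(folds, file.path(outDir, "qpcr_folds.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            folds
        })
        report$qpcr_folds <- res
    }

    report$failed_stages <- failed
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns", null = "null")
    invisible(report)
}
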