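#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Read / write a genes-by-samples expression TSV
#'
#' Plain tab-separated format: first column \code{gene_id}, remaining
#' columns one per sample, header row of sample ids.
#'
#' @param path file path.
#' @param scale normalization state to stamp on the container when reading.
#' @return \code{readExpressionTsv}: an
#'   \linkS4class{ExpressionExperiment}.
#' @export
readExpressionTsv <- function(path, scale = "raw") {
    d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    ExpressionExperiment(m, scale = scale)
}

#' @rdname readExpressionTsv
#' @param expr an \linkS4class{ExpressionExperiment}.
#' @export
writeExpressionTsv <- function(expr, path) {
    v <- exprs(expr)
    d <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path file path.
#' @return \code{readGmt}: named list of \linkS4class{GeneSignature}s.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
        out[[f[1]]] <- GeneSignature(f[1], f[-(1:2)])
    }
    out
}

#' @rdname readGmt
#' @param signatures list of \linkS4class{GeneSignature}s.
#' @export
writeGmt <- function(signatures, path) {
    lines <- vapply(signatures, function(s)
        paste(c(s@name, "na", s@genes), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write long-format growth, dose-response and Ct tables
#'
#' Thin CSV wrappers that validate the column contract on read.
#'
#' @param path file path.
#' @return the validated data.frame.
#' @export
readGrowthCsv <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    d$is_blank <- as.logical(d$is_blank)
    checkGrowthRecords(d)
}

#' @rdname readGrowthCsv
#' @param records the table to write.
#' @export
writeGrowthCsv <- function(records, path) {
    write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname readGrowthCsv
#' @export
readDoseResponseCsv <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("drug", "sample_id", "dose", "replicate", "response")
    if (!all(need %in% names(d)))
        stop("dose-response CSV needs columns: ",
             paste(need, collapse = ", "))
    if (any(d$dose <= 0)) stop("doses must be positive")
    d
}

#' @rdname readGrowthCsv
#' @export
writeDoseResponseCsv <- function(records, path) {
    write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname readGrowthCsv
#' @export
readCtCsv <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("gene", "condition", "replicate", "ct")
    if (!all(need %in% names(d)))
        stop("Ct CSV needs columns: ", paste(need, collapse = ", "))
    d
}

#' @rdname readGrowthCsv
#' @export
writeCtCsv <- function(records, path) {
    write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write a calibrated grayscale image
#'
#' The image is a TIFF; the calibration lives in a YAML sidecar
#' (\code{<image>.yaml}) with key \code{um_per_pixel}.
#'
#' @param path TIFF path.
#' @return \code{readCalibratedImage}: list with \code{pixels} (matrix)
#'   and \code{um_per_pixel}.
#' @export
readCalibratedImage <- function(path) {
    pix <- tiff::readTIFF(path)
    if (length(dim(pix)) == 3L) pix <- pix[, , 1]
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
        stop("calibration sidecar not found: ", sidecar)
    cal <- yaml::read_yaml(sidecar)
    list(pixels = pix, um_per_pixel = cal$um_per_pixel)
}

#' @rdname readCalibratedImage
#' @param pixels intensity matrix in [0, 1].
#' @param umPerPixel calibration to record in the sidecar.
#' @export
writeCalibratedImage <- function(pixels, umPerPixel, path) {
    tiff::writeTIFF(pixels, path, bits.per.sample = 16L)
    yaml::write_yaml(list(um_per_pixel = umPerPixel),
                     paste0(path, ".yaml"))
    invisible(path)
}

#' Write every simulated input of a scenario to a directory
#'
#' Runs all five generators and writes: \code{expression.tsv},
#' \code{signatures.gmt}, \code{growth.csv}, \code{dose_response.csv},
#' \code{qpcr.csv}, \code{images/*.tif} with YAML calibration sidecars,
#' and \code{truth.json} (the designed ground truth from
#' \code{\link{scenarioTruth}}).
#'
#' @param cfg a \linkS4class{ScenarioConfig}.
#' @param outDir output directory (created if absent).
#' @return invisibly, the list of written paths.
#' @export
simulateScenario <- function(cfg, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    ex <- generateExpression(cfg)
    paths <- c(
        expression = writeExpressionTsv(ex$expr,
            file.path(outDir, "expression.tsv")),
        signatures = writeGmt(ex$signatures,
            file.path(outDir, "signatures.gmt")),
        growth = writeGrowthCsv(generateGrowthPlates(cfg),
            file.path(outDir, "growth.csv")),
        dose = writeDoseResponseCsv(generateDoseResponse(cfg),
            file.path(outDir, "dose_response.csv")),
        qpcr = writeCtCsv(generateQpcr(cfg),
            file.path(outDir, "qpcr.csv")))
    imgs <- generateImages(cfg)
    for (nm in names(imgs$organoid))
        writeCalibratedImage(imgs$organoid[[nm]]$pixels,
            imgs$organoid[[nm]]$um_per_pixel,
            file.path(imgDir, paste0(nm, ".tif")))
    for (nm in names(imgs$stain))
        writeCalibratedImage(imgs$stain[[nm]]$pixels,
            imgs$stain[[nm]]$um_per_pixel,
            file.path(imgDir, paste0("stain_", nm, ".tif")))
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(scenarioTruth(cfg), truthPath, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    invisible(c(paths, truth = truthPath, images = imgDir))
}
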