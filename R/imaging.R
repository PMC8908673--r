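#' @importFrom EBImage otsu fillHull bwlabel Image
NULL

## rescale any intensity matrix to [0, 1]; constant images map to 0
unitScale <- function(pixels) {
    rng <- range(pixels)
    if (diff(rng) == 0) return(pixels * 0)
    (pixels - rng[1]) / diff(rng)
}

## merge label ids that touch diagonally so components are 8-connected
## (EBImage::bwlabel is 4-connected)
merge8Connectivity <- function(lab) {
    nr <- nrow(lab); nc <- ncol(lab)
    if (max(lab) < 2L) return(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) return(lab)
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    dense <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0] <- dense[lab[lab > 0]]
    out
}

#' Segment bright objects in a calibrated image
#'
#' Global Otsu thresholding on the intensity-rescaled image, hole filling,
#' and 8-connected component labeling; each object's area is its pixel
#' count times \code{umPerPixel^2}. Border-touching objects are retained
#' but flagged. Empty or constant images yield zero objects.
#'
#' @param pixels 2-D numeric intensity matrix (any positive scale; the
#'   threshold is computed after rescaling to [0, 1], so segmentation is
#'   invariant to multiplying intensities by a positive constant).
#' @param umPerPixel micrometers per pixel (> 0).
#' @param threshold optional fixed threshold on the [0, 1] rescaled
#'   intensities; default is Otsu's method.
#' @return an \linkS4class{OrganoidSegmentation} with no area filter
#'   applied (\code{thresholdUm2 = 0}).
#' @examples
#' img <- matrix(0, 40, 40); img[10:20, 10:20] <- 1
#' seg <- segmentObjects(img, umPerPixel = 2)
#' objectAreas(seg)
#' @export
segmentObjects <- function(pixels, umPerPixel, threshold = NULL) {
    stopifnot(is.matrix(pixels), umPerPixel > 0)
    u <- unitScale(pixels)
    if (all(u == 0)) {
        return(new("OrganoidSegmentation",
                   labels = matrix(0L, nrow(pixels), ncol(pixels)),
                   areasUm2 = numeric(0), umPerPixel = umPerPixel,
                   thresholdUm2 = 0, borderTouching = logical(0)))
    }
    if (is.null(threshold))
        threshold <- otsu(Image(u), range = c(0, 1))
    bin <- u > threshold
    filled <- fillHull(Image(bin))
    lab <- bwlabel(filled)
    lab <- merge8Connectivity(matrix(as.integer(lab), nrow(pixels)))
    nObj <- max(lab)
    if (nObj == 0L)
        return(new("OrganoidSegmentation", labels = lab,
                   areasUm2 = numeric(0), umPerPixel = umPerPixel,
                   thresholdUm2 = 0, borderTouching = logical(0)))
    areas <- tabulate(lab[lab > 0], nbins = nObj) * umPerPixel^2
    names(areas) <- seq_len(nObj)
    borderLabs <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
    new("OrganoidSegmentation", labels = lab, areasUm2 = areas,
        umPerPixel = umPerPixel, thresholdUm2 = 0,
        borderTouching = seq_len(nObj) %in% borderLabs)
}

#' Apply the minimum-area organoid rule
#'
#' Objects with area greater than or equal to the threshold (inclusive, per
#' the "2000 um^2 and more" rule) are kept as organoids; smaller objects
#' are removed from the label map and the count/total-area summaries.
#'
#' @param seg an \linkS4class{OrganoidSegmentation}.
#' @param thresholdUm2 minimum organoid area in um^2 (default 2000).
#' @return a filtered \linkS4class{OrganoidSegmentation}.
#' @export
applyAreaFilter <- function(seg, thresholdUm2 = 2000) {
    stopifnot(is(seg, "OrganoidSegmentation"))
    keep <- seg@areasUm2 >= thresholdUm2
    lab <- seg@labels
    if (any(!keep)) {
        drop <- as.integer(names(seg@areasUm2)[!keep])
        lab[lab %in% drop] <- 0L
    }
    new("OrganoidSegmentation", labels = lab,
        areasUm2 = seg@areasUm2[keep], umPerPixel = seg@umPerPixel,
        thresholdUm2 = thresholdUm2,
        borderTouching = seg@borderTouching[keep])
}

#' @rdname organoidCount
#' @export
setMethod("organoidCount", "OrganoidSegmentation",
    function(object) length(object@areasUm2))

#' @rdname totalAreaUm2
#' @export
setMethod("totalAreaUm2", "OrganoidSegmentation",
    function(object) sum(object@areasUm2))

#' @rdname objectAreas
#' @export
setMethod("objectAreas", "OrganoidSegmentation",
    function(object) object@areasUm2)

setMethod("show", "OrganoidSegmentation", function(object) {
    cat(sprintf(
        paste0("OrganoidSegmentation: %d object(s) >= %g um^2, total area",
               " %.1f um^2 (%d border-touching)\n"),
        organoidCount(object), object@thresholdUm2, totalAreaUm2(object),
        sum(object@borderTouching)))
})

#' Stain-positive area fraction of an image
#'
#' Percentage of pixels above the stain threshold (fixed, or Otsu on the
#' rescaled intensities by default), e.g. the alpha-SMA-positive stromal
#' fraction of a tissue section.
#'
#' @param pixels 2-D numeric intensity matrix.
#' @param threshold optional fixed threshold on the [0, 1] rescaled
#'   intensities; default Otsu. An all-positive (constant bright) image
#'   returns 100.
#' @return percentage in [0, 100].
#' @export
stainPositiveFraction <- function(pixels, threshold = NULL) {
    stopifnot(is.matrix(pixels))
    rng <- range(pixels)
    if (diff(rng) == 0)
        return(if (rng[1] > 0) 100 else 0)
    u <- unitScale(pixels)
    if (is.null(threshold)) threshold <- otsu(Image(u), range = c(0, 1))
    100 * sum(u > threshold) / length(u)
}
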