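# Object-based colocalization of two-channel z-stacks: segment each slice
# into objects, then measure the fraction of particle-object pixels that
# overlap organelle objects.
#
# Segmentation is deliberately simple and fully parameterized (Gaussian
# smoothing, Otsu threshold, 8-connected components, minimum object size);
# all parameters are recorded in the mask provenance.

#' Segment a slice into labeled objects
#'
#' Gaussian-smooths the image, thresholds it by Otsu's criterion, labels
#' 8-connected components and removes components smaller than `min_size`
#' pixels. Components must additionally rise significantly above the
#' robust background level (peak smoothed intensity at least
#' `signif_k` robust standard deviations above the median): Otsu's
#' criterion always splits an image, so on an object-free pure-noise
#' channel it would otherwise fabricate foreground. A constant
#' (degenerate) image yields an empty mask with a warning.
#'
#' @param img Numeric matrix of finite, non-negative intensities.
#' @param min_size Minimum object size in pixels.
#' @param sigma_smooth Gaussian smoothing sd in pixels; `0` disables
#'   smoothing.
#' @param signif_k Background-significance cutoff in robust (MAD-based)
#'   standard deviations of the smoothed image.
#' @return An integer label matrix of class `label_mask` (0 = background,
#'   objects numbered contiguously from 1), with attribute `provenance`
#'   recording the threshold and parameters.
#' @export
segment_objects <- function(img, min_size = 4, sigma_smooth = 1,
                            signif_k = 10) {
  if (!is.matrix(img) || !all(is.finite(img)))
    stop("img must be a finite numeric matrix")
  if (diff(range(img)) == 0) {
    warning("constant image: returning empty mask")
    return(new_label_mask(matrix(0L, nrow(img), ncol(img)),
                          threshold = NA_real_, min_size = min_size,
                          sigma_smooth = sigma_smooth,
                          signif_k = signif_k))
  }
  # scale to [0, 1] for EBImage
  lo <- min(img)
  sc <- (img - lo) / (max(img) - lo)
  smoothed <- if (sigma_smooth > 0)
    as.matrix(EBImage::gblur(EBImage::Image(sc), sigma = sigma_smooth))
  else sc
  thr <- EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1))
  bw <- smoothed > thr
  if (!any(bw)) {
    warning("no foreground after thresholding: returning empty mask")
    return(new_label_mask(matrix(0L, nrow(img), ncol(img)),
                          threshold = thr, min_size = min_size,
                          sigma_smooth = sigma_smooth,
                          signif_k = signif_k))
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw)) # 8-connectivity
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  # robust background significance: peaks must clear median + k * mad
  peak_cut <- stats::median(smoothed) + signif_k * stats::mad(smoothed)
  peaks <- vapply(seq_along(sizes), function(k)
    max(smoothed[lab == k]), numeric(1))
  keep <- which(sizes >= min_size & peaks >= peak_cut)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  new_label_mask(out, threshold = thr, min_size = min_size,
                 sigma_smooth = sigma_smooth, signif_k = signif_k)
}

new_label_mask <- function(labels, threshold, min_size, sigma_smooth,
                           signif_k) {
  structure(labels, class = c("label_mask", class(matrix())),
            provenance = list(threshold = as.numeric(threshold),
                              min_size = min_size,
                              sigma_smooth = sigma_smooth,
                              signif_k = signif_k))
}

#' Object-overlap colocalization fraction
#'
#' Number of pixels covered by both particle and organelle objects, divided
#' by the total pixel area occupied by particle objects. Defined as 0 when
#' the particle mask is empty (with a warning).
#'
#' @param particle_mask,organelle_mask Label matrices (or logical/integer
#'   matrices where values > 0 are foreground) of identical shape.
#' @return Fraction in `[0, 1]`.
#' @export
coloc_fraction <- function(particle_mask, organelle_mask) {
  if (!identical(dim(particle_mask), dim(organelle_mask)))
    stop("mask shapes differ")
  p <- particle_mask > 0
  o <- organelle_mask > 0
  np <- sum(p)
  if (np == 0L) {
    warning("empty particle mask: fraction defined as 0")
    return(0)
  }
  sum(p & o) / np
}

#' Per-slice colocalization of a two-channel stack
#'
#' Segments each z-slice of both channels and measures the per-slice
#' overlap fraction of particle objects with organelle objects.
#'
#' @param particle,organelle 3-D arrays (x, y, z) or matrices (single
#'   slice) of matching shape.
#' @param min_size,sigma_smooth Segmentation parameters, see
#'   [segment_objects()].
#' @return data.frame with columns `slice` and `fraction`; attribute
#'   `aggregate` is the arithmetic mean over slices.
#' @export
coloc_stack <- function(particle, organelle, min_size = 4,
                        sigma_smooth = 1) {
  particle <- as_stack(particle)
  organelle <- as_stack(organelle)
  if (!identical(dim(particle), dim(organelle)))
    stop("unpaired stacks: shapes differ")
  nz <- dim(particle)[3]
  fr <- vapply(seq_len(nz), function(k) {
    pm <- segment_objects(particle[, , k], min_size, sigma_smooth)
    om <- segment_objects(organelle[, , k], min_size, sigma_smooth)
    suppressWarnings(coloc_fraction(pm, om))
  }, numeric(1))
  out <- data.frame(slice = seq_len(nz), fraction = fr)
  attr(out, "aggregate") <- mean(fr)
  out
}

as_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("expected a matrix or 3-D array")
  x
}

#' Aggregate colocalization across cells and replicates
#'
#' Aggregation order is slice -> cell -> replicate: slice fractions are
#' averaged per cell, cell means averaged per replicate, and replicate
#' means summarized per timepoint as mean +/- s.e.m. across independent
#' replicates.
#'
#' @param pairs A list of stack pairs, each `list(particle =, organelle =)`
#'   (3-D arrays or matrices).
#' @param meta data.frame with one row per pair: columns `cell`,
#'   `replicate`, and optionally `timepoint`.
#' @param min_size,sigma_smooth Segmentation parameters.
#' @return A list of class `coloc_result`: `slices` (per slice), `cells`
#'   (per-cell means), `summary` (per timepoint: mean, sem, n replicates).
#' @export
summarize_coloc <- function(pairs, meta, min_size = 4, sigma_smooth = 1) {
  if (length(pairs) != nrow(meta))
    stop("meta must have one row per stack pair")
  if (!all(c("cell", "replicate") %in% names(meta)))
    stop("meta needs columns cell and replicate")
  if (is.null(meta$timepoint)) meta$timepoint <- 0
  slices <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    df <- coloc_stack(pairs[[i]]$particle, pairs[[i]]$organelle,
                      min_size, sigma_smooth)
    cbind(meta[i, c("cell", "replicate", "timepoint")], df,
          row.names = NULL)
  }))
  cells <- stats::aggregate(fraction ~ cell + replicate + timepoint,
                            data = slices, FUN = mean)
  reps <- stats::aggregate(fraction ~ replicate + timepoint, data = cells,
                           FUN = mean)
  summ <- do.call(rbind, lapply(split(reps, reps$timepoint), function(d) {
    data.frame(timepoint = d$timepoint[1], mean = mean(d$fraction),
               sem = stats::sd(d$fraction) / sqrt(nrow(d)),
               n_replicates = nrow(d))
  }))
  rownames(summ) <- NULL
  structure(list(slices = slices, cells = cells, summary = summ),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Object-based colocalization summary (mean +/- s.e.m. across replicates)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read / write multi-page TIFF z-stacks
#'
#' @param path TIFF file path.
#' @return `read_stack`: a 3-D numeric array (rows, cols, slices).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  simplify2array(pages)
}

#' @rdname read_stack
#' @param stack 3-D numeric array with values in `[0, 1]` (rescaled if not).
#' @export
write_stack <- function(stack, path) {
  stack <- as_stack(stack)
  if (max(stack) > 1 || min(stack) < 0)
    stack <- (stack - min(stack)) / max(1e-12, diff(range(stack)))
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
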