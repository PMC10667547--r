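#' Normalize a saliency map to \[0, 1\] per image
#'
#' Min-max rescaling `(v - min) / (max - min)` so that 1 marks the most
#' salient pixel of each image. Constant maps carry no ordering information;
#' they are returned as all zeros with attribute `degenerate = TRUE`.
#'
#' @param x Numeric matrix of saliency values (finite).
#' @return Numeric matrix in \[0, 1\] with attributes `normalized = TRUE`
#'   and, for constant input, `degenerate = TRUE`.
#' @export
normalize_saliency <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("saliency must be a numeric matrix")
  if (any(!is.finite(x))) stop("saliency map contains NaN or infinite values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- matrix(0, nrow(x), ncol(x))
    attr(out, "degenerate") <- TRUE
  } else {
    out <- (x - rng[1]) / (rng[2] - rng[1])
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Dice's similarity coefficient between two pixel sets
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)`, the standard overlap
#' measure between a thresholded area of interest and a segmented lesion:
#' 1 is total overlap, 0 is disjoint sets.
#'
#' @param a,b Logical (or 0/1) matrices of identical shape.
#' @return DSC in \[0, 1\]. Both sets empty is undefined and raises an
#'   error rather than returning a number.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a != 0)
  nb <- sum(b != 0)
  if (na + nb == 0) stop("DSC undefined: both pixel sets are empty")
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Optimal-threshold area of interest for one saliency map
#'
#' Finds the saliency threshold that maximizes Dice overlap between the
#' supra-threshold area of interest `{p : s(p) >= tau}` and the lesion
#' mask. The search is exact over all distinct saliency values: pixels are
#' sorted by descending saliency and DSC at prefix length k is
#' `2 TP(k) / (k + |B|)`, with candidate cuts only at boundaries between
#' distinct values (pixels with equal saliency enter or leave together).
#' Among DSC-maximizing thresholds the largest is returned (the smallest,
#' most specific area of interest). The achieved maximum DSC is an upper
#' bound on how lesion-localized the map can appear at any threshold.
#'
#' @param map Normalized saliency matrix (values in \[0, 1\]).
#' @param mask Logical lesion mask of the same shape, nonempty.
#' @return An object of class `aoi`: list with `pixels` (logical matrix),
#'   `threshold` and `dsc`.
#' @export
optimal_aoi <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) {
    stop("saliency map and mask shapes differ")
  }
  nb <- sum(mask != 0)
  if (nb == 0) stop("DSC undefined against an empty lesion mask")
  v <- as.vector(map)
  if (any(!is.finite(v))) stop("saliency map contains NaN or infinite values")
  if (min(v) < 0 || max(v) > 1) {
    stop("saliency map is not normalized to [0, 1]; call normalize_saliency()")
  }
  m <- as.vector(mask != 0)

  o <- order(v, decreasing = TRUE)
  vs <- v[o]
  tp <- cumsum(m[o])
  # last index of each run of equal values = feasible prefix lengths
  idx <- c(which(diff(vs) != 0), length(vs))
  d <- 2 * tp[idx] / (idx + nb)
  j <- which.max(d) # first max in descending value order = largest threshold
  tau <- vs[idx[j]]
  structure(
    list(pixels = matrix(v >= tau, nrow(map), ncol(map)),
         threshold = tau, dsc = d[j]),
    class = "aoi"
  )
}

#' @export
print.aoi <- function(x, ...) {
  cat(sprintf(
    "Area of interest: %d pixels at threshold %.4g, DSC = %.4f\n",
    sum(x$pixels), x$threshold, x$dsc
  ))
  invisible(x)
}

#' Should an image enter the overlap analysis?
#'
#' Images whose lesions could not be segmented (mask absent, e.g. a lesion
#' conspicuous from only one mammographic view) or whose mask is empty are
#' excluded from the overlap analysis; they remain in detection evaluation.
#'
#' @param mask A lesion mask matrix, or `NULL` when no segmentation exists.
#' @return `TRUE` if the image has a usable (nonempty) mask.
#' @export
include_image <- function(mask) {
  !is.null(mask) && sum(mask != 0) > 0
}

#' Summarize per-image DSC values
#'
#' Median and interquartile range (Q3 - Q1) of the per-image optimal-
#' threshold DSC values, using linear-interpolation quantiles
#' ([stats::quantile()] type 7). Per-image values are retained.
#'
#' @param dscs Numeric vector of per-image DSC values (nonempty).
#' @param image_id,threshold Optional parallel vectors retained in the
#'   per-image table.
#' @return Object of class `overlap_summary`: `n_images`, `median_dsc`,
#'   `iqr_dsc`, `per_image` data frame.
#' @export
summarize_dsc <- function(dscs, image_id = NULL, threshold = NULL) {
  if (length(dscs) == 0) stop("no DSC values to summarize")
  if (any(!is.finite(dscs))) stop("non-finite DSC values")
  q <- stats::quantile(dscs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  per <- data.frame(
    image_id = if (is.null(image_id)) paste0("img", seq_along(dscs))
               else as.character(image_id),
    threshold = if (is.null(threshold)) NA_real_ else threshold,
    dsc = dscs,
    stringsAsFactors = FALSE
  )
  structure(
    list(n_images = length(dscs), median_dsc = q[2], iqr_dsc = q[3] - q[1],
         per_image = per),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "Saliency-lesion overlap over %d images: median DSC %.3f (IQR %.3f)\n",
    x$n_images, x$median_dsc, x$iqr_dsc
  ))
  invisible(x)
}

#' @export
summary.overlap_summary <- function(object, ...) {
  print(object)
  cat("Per-image DSC quartiles:\n")
  print(stats::quantile(object$per_image$dsc, type = 7))
  invisible(object)
}

#' Run the overlap analysis over a set of images
#'
#' For each lesion-bearing image, reads its mask and the system's saliency
#' map, normalizes the map, extracts the optimal-threshold area of interest
#' and records the DSC. Images without a usable mask are counted as
#' excluded, mirroring the accounting of segmentations that could not be
#' produced.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param saliency_dir Directory with one saliency file per image, named
#'   `<image_id>.png` (or `.tif`/`.csv`).
#' @param logfile Optional log file for exclusion messages.
#' @return Object of class `overlap_summary` with extra fields
#'   `n_excluded` and `excluded_ids`.
#' @export
saliency_overlap <- function(manifest, saliency_dir, logfile = NULL) {
  lesion_rows <- manifest[manifest$has_lesion == 1, , drop = FALSE]
  ids <- character(0); taus <- numeric(0); ds <- numeric(0)
  excluded <- character(0)
  missing_sal <- character(0)
  for (i in seq_len(nrow(lesion_rows))) {
    row <- lesion_rows[i, ]
    mask <- if (nzchar(row$mask)) read_mask(row$mask) else NULL
    if (!include_image(mask)) {
      excluded <- c(excluded, row$image_id)
      salovlap_log(sprintf("image %s excluded from overlap (no usable mask)",
                           row$image_id), logfile, verbose = FALSE)
      next
    }
    sal_path <- find_resource(saliency_dir, row$image_id)
    if (is.null(sal_path)) {
      missing_sal <- c(missing_sal, row$image_id)
      next
    }
    sal <- read_saliency(sal_path,
                         record = list(height = row$height, width = row$width))
    aoi <- optimal_aoi(normalize_saliency(sal), mask)
    ids <- c(ids, row$image_id)
    taus <- c(taus, aoi$threshold)
    ds <- c(ds, aoi$dsc)
  }
  if (length(missing_sal)) {
    stop("missing saliency map(s) for lesion image(s): ",
         paste(missing_sal, collapse = ", "))
  }
  if (length(ds) == 0) {
    stop("no images with usable masks entered the overlap analysis; ",
         "see the exclusion log")
  }
  out <- summarize_dsc(ds, image_id = ids, threshold = taus)
  out$n_excluded <- length(excluded)
  out$excluded_ids <- excluded
  out
}

find_resource <- function(dir, image_id) {
  for (ext in c("png", "tif", "tiff", "csv", "tsv", "txt")) {
    p <- file.path(dir, paste0(image_id, ".", ext))
    if (file.exists(p)) return(p)
  }
  NULL
}
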