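#' Read a binary lesion mask from a grayscale image file
#'
#' Masks are single-channel grayscale PNG or TIFF images. Any pixel with a
#' value strictly greater than zero is part of the lesion; this makes the
#' reader robust to 8-bit vs 16-bit exports of binary contours. Matrices are
#' row-major with the origin at the top-left corner.
#'
#' @param path Path to a single-channel 8- or 16-bit grayscale PNG or TIFF.
#' @return A logical matrix (`TRUE` = lesion pixel) with attribute `count`
#'   holding the number of lesion pixels.
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  mask <- img > 0
  attr(mask, "count") <- sum(mask)
  mask
}

#' Write a binary lesion mask as an 8-bit grayscale PNG
#'
#' Lesion pixels are written as 255, background as 0, so a write/read
#' round-trip reproduces the lesion pixel set exactly.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param path Output path; format is always PNG.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.numeric(mask != 0), nrow = nrow(mask))
  png::writePNG(m, target = path)
  invisible(path)
}

#' Read a saliency map
#'
#' Accepts single-channel grayscale images (8/16-bit PNG or TIFF; integer
#' pixel values are mapped to reals by dividing by the format's maximum) or
#' a plain-text dense numeric matrix (`.csv`/`.tsv`/`.txt`, no header) for
#' maps that never passed through an image format.
#'
#' @param path Path to the saliency file.
#' @param record Optional list with `height` and `width`; if given, the map's
#'   shape is checked against it and a mismatch is an error.
#' @return A numeric matrix with attribute `normalized` (`TRUE` when all
#'   values already lie in \[0, 1\]).
#' @export
read_saliency <- function(path, record = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else ""
    x <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    dimnames(x) <- NULL
    if (!is.numeric(x)) stop("saliency array file is not numeric: ", path)
  } else {
    x <- read_gray_image(path)
  }
  if (any(!is.finite(x))) {
    stop("saliency map contains NaN or infinite values: ", path)
  }
  if (!is.null(record)) {
    if (nrow(x) != record$height || ncol(x) != record$width) {
      stop(sprintf(
        "saliency shape %dx%d does not match declared image record %dx%d (%s)",
        nrow(x), ncol(x), record$height, record$width, path
      ))
    }
  }
  attr(x, "normalized") <- min(x) >= 0 && max(x) <= 1
  x
}

# Read a single-channel grayscale PNG/TIFF as a numeric matrix in [0, 1]
# (the png/tiff readers divide by the format maximum). Multi-channel input
# is a format error, not silently collapsed.
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': ", path)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      stop("expected a single-channel grayscale image, got ",
           dim(img)[3], " channels: ", path)
    }
  }
  img
}

#' Read a per-image detection score table
#'
#' @param path CSV with header columns `image_id`, `woman_id`, `label`,
#'   `score`. Labels are matched case-insensitively after trimming and must
#'   be `case` or `control`; `image_id` must be unique; scores must be
#'   finite.
#' @return A data frame with columns `image_id`, `woman_id`,
#'   `label` (factor with levels `case`, `control`), `score`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "woman_id", "label", "score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("scores CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  lab <- tolower(trimws(df$label))
  bad <- setdiff(unique(lab), c("case", "control"))
  if (length(bad)) {
    stop("unknown label token(s) in scores CSV: ", paste(bad, collapse = ", "))
  }
  dup <- df$image_id[duplicated(df$image_id)]
  if (length(dup)) {
    stop("duplicate image_id in scores CSV: ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(df$score))) stop("non-finite score in scores CSV")
  data.frame(
    image_id = as.character(df$image_id),
    woman_id = as.character(df$woman_id),
    label = factor(lab, levels = c("case", "control")),
    score = as.numeric(df$score),
    stringsAsFactors = FALSE
  )
}

#' Read a cohort table
#'
#' @param path CSV with header columns `woman_id`, `status` (`case` or
#'   `control`), `birth_year`, `screening_year`, `system`, `cancer_type`
#'   (empty for controls).
#' @return A validated data frame with those columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cancer_type = "character"))
  need <- c("woman_id", "status", "birth_year", "screening_year",
            "system", "cancer_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df$status <- tolower(trimws(df$status))
  df$cancer_type[is.na(df$cancer_type)] <- ""
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad)) stop("unknown status token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$woman_id)) stop("duplicate woman_id in cohort table")
  if (any(df$screening_year < df$birth_year)) {
    stop("screening_year earlier than birth_year for some records")
  }
  has_type <- nzchar(df$cancer_type)
  if (any(has_type & df$status != "case")) {
    stop("cancer_type present for non-case records")
  }
  if (any(!has_type & df$status == "case")) {
    stop("cancer_type missing for some case records")
  }
  invisible(df)
}

#' Read a dataset manifest and fail fast on unresolvable resources
#'
#' The manifest is a CSV with one row per image: `image_id`, `woman_id`,
#' `laterality` (`left`/`right`), `view` (`CC`/`MLO`), `height`, `width`,
#' `has_lesion` (0/1), and `mask` (path of the lesion mask relative to the
#' manifest's directory; empty when no segmentation exists). Every non-empty
#' mask path must resolve before analysis starts.
#'
#' @param path Manifest CSV path.
#' @return Data frame of image records; mask paths resolved to absolute.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mask = "character"))
  need <- c("image_id", "woman_id", "laterality", "view",
            "height", "width", "has_lesion", "mask")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$image_id)) stop("duplicate image_id in manifest")
  if (any(df$height < 1 | df$width < 1)) stop("non-positive image dimensions")
  bad_lat <- setdiff(unique(df$laterality), c("left", "right"))
  if (length(bad_lat)) stop("unknown laterality: ", paste(bad_lat, collapse = ", "))
  bad_view <- setdiff(unique(df$view), c("CC", "MLO"))
  if (length(bad_view)) stop("unknown view: ", paste(bad_view, collapse = ", "))
  root <- dirname(normalizePath(path))
  df$mask[is.na(df$mask)] <- ""
  has_mask <- nzchar(df$mask)
  df$mask[has_mask] <- file.path(root, df$mask[has_mask])
  unresolved <- df$mask[has_mask][!file.exists(df$mask[has_mask])]
  if (length(unresolved)) {
    stop("manifest references missing mask file(s): ",
         paste(unresolved, collapse = ", "))
  }
  df
}

#' Write the per-system report as CSV and JSON
#'
#' The CSV mirrors the layout of a detection-and-saliency results table:
#' one row per system with the AUC, its 95% CI (en-dash separated), and the
#' median DSC with the IQR in parentheses. AUC and CI bounds are printed
#' with 3 decimals; DSC as a proportion with 3 decimals. The JSON carries
#' the raw unrounded values.
#'
#' @param rows Data frame with columns `system`, `auc`, `ci_low`, `ci_high`,
#'   `significant`, `median_dsc`, `iqr_dsc`, `n_overlap_images`,
#'   `n_excluded_images`, `n_images`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `rows`, invisibly.
#' @export
write_report <- function(rows, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    header <- "system,auc,ci_95,dsc_iqr"
    lines <- character(0)
    if (nrow(rows) > 0) {
      lines <- sprintf(
        "%s,%.3f,%.3f–%.3f,%.3f (%.3f)",
        rows$system, rows$auc, rows$ci_low, rows$ci_high,
        rows$median_dsc, rows$iqr_dsc
      )
    }
    writeLines(c(header, lines), csv_path, useBytes = TRUE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rows, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(rows)
}

#' Read a report back from its JSON serialization
#'
#' @param json_path Path written by [write_report()].
#' @return The report rows as a data frame.
#' @export
read_report <- function(json_path) {
  as.data.frame(jsonlite::read_json(json_path, simplifyVector = TRUE))
}

#' Read a plain-text key-value run configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Values that parse as
#' numbers are returned numeric; `true`/`false` become logical;
#' comma-separated values become character vectors.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- trimws(kv[2])
    val <- trimws(kv[3])
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl(",", val, fixed = TRUE)) {
    return(trimws(strsplit(val, ",", fixed = TRUE)[[1]]))
  }
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Append a timestamped message to a run log
#'
#' @param msg Message string.
#' @param logfile Optional path; when `NULL` the message goes to stderr.
#' @param verbose When `FALSE`, nothing is emitted to the console (file
#'   logging still happens).
#' @return `msg`, invisibly.
#' @export
salovlap_log <- function(msg, logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  if (verbose && is.null(logfile)) message(line)
  invisible(msg)
}
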