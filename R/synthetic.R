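#' Separable Gaussian smoothing of a matrix
#'
#' Small utility used by the phantom generator to turn white noise into a
#' smooth background texture. Replicate padding at the edges keeps the
#' kernel mass normalized everywhere.
#'
#' @param x Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; `sigma = 0` returns
#'   `x` unchanged.
#' @return Smoothed matrix of the same shape.
#' @keywords internal
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(half + 1):(half + length(v))])
  }
  x <- apply(x, 2, smooth1)
  t(apply(x, 1, smooth1))
}

# Discrete ellipse indicator over a 0-based pixel grid.
ellipse_mask <- function(height, width, center, axes) {
  r <- matrix(seq_len(height) - 1, height, width)
  c_ <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

#' Generate a mammogram-like phantom with an elliptical lesion
#'
#' A deliberately simple stand-in for a full-field digital mammogram: a
#' half-ellipse breast region anchored at the left image edge over a dark
#' background, textured with smoothed seeded noise, plus an additive bright
#' elliptical lesion. The returned mask marks exactly the lesion ellipse
#' pixels, independent of how conspicuous the lesion is (contrast 0 still
#' yields the full mask — ground truth does not depend on visibility).
#'
#' @param height,width Image size in pixels (default 128 x 128).
#' @param breast_axes Semi-axes (rows, cols) of the breast half-ellipse,
#'   centered on the left edge at mid-height.
#' @param blur Background texture smoothness: Gaussian blur radius in
#'   pixels applied to the noise field.
#' @param lesion_center Lesion center (row, col), 0-based pixels.
#' @param lesion_axes Lesion semi-axes (rows, cols) in pixels.
#' @param lesion_contrast Additive lesion brightness (unitless, >= 0).
#' @param noise_sd Standard deviation of the pre-blur background noise.
#' @param seed Integer seed; the phantom is a pure function of its
#'   parameters including the seed.
#' @return List with `image` (numeric matrix) and `mask` (logical matrix).
#' @export
make_phantom <- function(height = 128, width = 128,
                         breast_axes = c(0.45 * height, 0.85 * width),
                         blur = 3,
                         lesion_center = c(height / 2, width / 4),
                         lesion_axes = c(5, 3),
                         lesion_contrast = 0.4,
                         noise_sd = 0.15,
                         seed = 1) {
  if (lesion_contrast < 0) stop("lesion_contrast must be >= 0")
  breast <- ellipse_mask(height, width,
                         center = c((height - 1) / 2, 0), axes = breast_axes)
  mask <- ellipse_mask(height, width, lesion_center, lesion_axes)
  if (any(mask & !breast)) {
    stop("lesion ellipse extends outside the breast region")
  }
  set.seed(as.integer(seed))
  texture <- gauss_blur(matrix(stats::rnorm(height * width, sd = noise_sd),
                               height, width), blur)
  img <- matrix(0.02, height, width)
  img[breast] <- 0.35 + texture[breast]
  img <- img + lesion_contrast * mask
  list(image = img, mask = mask)
}

#' Generate a saliency field with tunable lesion localization
#'
#' Emulates the range of behaviors seen in saliency maps of detection
#' networks, from tightly lesion-focused to diffuse attention over a large
#' sub-region placed independently of the lesion:
#' `lambda * K_lesion + (1 - lambda) * K_diffuse + noise`, then per-image
#' min-max normalized. `K_lesion` is a Gaussian bump at the lesion centroid
#' (flat zero when the mask is empty, as for control images); `K_diffuse`
#' is a broad Gaussian bump at a seeded random location.
#'
#' @param mask Lesion mask matrix (may be empty / all `FALSE`).
#' @param lambda Localization in \[0, 1\]: 1 = concentrated on the lesion,
#'   0 = diffuse and independent of the lesion.
#' @param lesion_width Kernel width (pixels) of the lesion bump.
#' @param diffuse_width Kernel width (pixels) of the diffuse bump.
#' @param noise Amplitude of added white noise.
#' @param seed Integer seed.
#' @return Normalized saliency matrix (attributes as
#'   [normalize_saliency()]).
#' @export
make_saliency <- function(mask, lambda, lesion_width = 8,
                          diffuse_width = 32, noise = 0.05, seed = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  h <- nrow(mask); w <- ncol(mask)
  r <- matrix(seq_len(h) - 1, h, w)
  c_ <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  set.seed(as.integer(seed))
  if (sum(mask != 0) > 0) {
    idx <- which(mask != 0, arr.ind = TRUE) - 1
    ctr <- colMeans(idx)
    k_lesion <- exp(-((r - ctr[1])^2 + (c_ - ctr[2])^2) /
                      (2 * lesion_width^2))
  } else {
    k_lesion <- matrix(0, h, w)
  }
  d_ctr <- c(stats::runif(1, 0, h - 1), stats::runif(1, 0, w - 1))
  k_diffuse <- exp(-((r - d_ctr[1])^2 + (c_ - d_ctr[2])^2) /
                     (2 * diffuse_width^2))
  field <- lambda * k_lesion + (1 - lambda) * k_diffuse +
    noise * matrix(stats::rnorm(h * w), h, w)
  normalize_saliency(field)
}

#' Generate binormal detection scores with known true AUC
#'
#' Control scores are standard normal; case scores are `Normal(mu, 1)`.
#' The true AUC of this binormal model is `pnorm(mu / sqrt(2))` in closed
#' form, which makes the generator a known-truth input for AUC and
#' bootstrap-coverage checks.
#'
#' @param n_cases,n_controls Class sizes (>= 1).
#' @param mu Case mean shift in standard-deviation units.
#' @param seed Integer seed.
#' @return Data frame with `image_id`, `woman_id`, `label`, `score`.
#' @export
make_scores <- function(n_cases, n_controls, mu, seed = 1) {
  if (n_cases < 1 || n_controls < 1) stop("need at least one of each class")
  set.seed(as.integer(seed))
  data.frame(
    image_id = c(sprintf("case_%04d", seq_len(n_cases)),
                 sprintf("ctrl_%04d", seq_len(n_controls))),
    woman_id = c(sprintf("wcase_%04d", seq_len(n_cases)),
                 sprintf("wctrl_%04d", seq_len(n_controls))),
    label = factor(rep(c("case", "control"), c(n_cases, n_controls)),
                   levels = c("case", "control")),
    score = c(stats::rnorm(n_cases, mean = mu), stats::rnorm(n_controls)),
    stringsAsFactors = FALSE
  )
}

#' True AUC of the binormal score model
#'
#' @param mu Case mean shift in standard-deviation units.
#' @return `pnorm(mu / sqrt(2))`.
#' @export
binormal_auc <- function(mu) stats::pnorm(mu / sqrt(2))

#' Generate a synthetic screening cohort with guaranteed matchability
#'
#' Emulates a biennial screening program inviting women aged 50-69:
#' screening years 2015-2017, birth years constrained so ages fall in
#' 50-69, two mammographic systems (PH/GE) with configurable mix, and
#' cancer types for cases at typical screening-detection proportions.
#' For every case, at least one control candidate with the identical
#' (birth year, screening year, system) key is constructed, so a full
#' 1:1 matching always exists; the remaining candidates get random keys.
#'
#' @param n_cases Number of cases.
#' @param n_pool Number of control candidates (>= `n_cases`).
#' @param seed Integer seed.
#' @param screening_years Vector of possible screening years.
#' @param age_range Permissible age at screening (inclusive).
#' @param p_ge Proportion of images on the GE system (the rest PH).
#' @return Data frame of cohort records (see [read_cohort()] columns).
#' @export
make_cohort <- function(n_cases, n_pool, seed = 1,
                        screening_years = 2015:2017,
                        age_range = c(50, 69),
                        p_ge = 0.78) {
  if (n_pool < n_cases) {
    stop("n_pool must be >= n_cases to guarantee a full matching")
  }
  set.seed(as.integer(seed))
  draw_keys <- function(n) {
    sy <- sample(screening_years, n, replace = TRUE)
    age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
    data.frame(
      birth_year = sy - age,
      screening_year = sy,
      system = sample(c("GE", "PH"), n, replace = TRUE,
                      prob = c(p_ge, 1 - p_ge)),
      stringsAsFactors = FALSE
    )
  }
  case_keys <- draw_keys(n_cases)
  cases <- data.frame(
    woman_id = sprintf("wcase_%04d", seq_len(n_cases)),
    status = "case",
    case_keys,
    cancer_type = sample(c("DCIS", "ductal", "lobular", "other"),
                         n_cases, replace = TRUE,
                         prob = c(0.17, 0.64, 0.13, 0.06)),
    stringsAsFactors = FALSE
  )
  # one guaranteed key-sharing candidate per case, then random extras
  extra <- n_pool - n_cases
  pool_keys <- rbind(case_keys,
                     if (extra > 0) draw_keys(extra))
  pool <- data.frame(
    woman_id = sprintf("wctrl_%04d", seq_len(n_pool)),
    status = "control",
    pool_keys,
    cancer_type = "",
    stringsAsFactors = FALSE
  )
  rbind(cases, pool)
}

# Deterministic sub-seeds from one master seed, so a single seed
# reproduces the whole run. Kept below 2^31 - 1.
derive_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write a complete synthetic dataset directory
#'
#' Emits everything the pipeline consumes, laid out exactly as the CLI
#' expects: `masks/` (one PNG per lesion image), `saliency/<system>/` (one
#' PNG per lesion image), `scores/<system>.csv`, `cohort.csv`, and
#' `manifest.csv`. Each case woman contributes `views_per_woman` scored
#' images of which `lesion_views` (both views of the affected breast)
#' carry a lesion mask and saliency maps; control women contribute scored
#' images only. A fraction of lesion images can be left unsegmented
#' (`p_unsegmented`) to exercise the exclusion path, emulating lesions
#' conspicuous in only one view.
#'
#' @param dir Output directory (created if needed).
#' @param n_cases,n_controls Women per arm (defaults 191/191).
#' @param systems Named list: for each AI system, a list with `lambda`
#'   (saliency localization) and `mu` (binormal detection effect).
#' @param height,width Phantom size.
#' @param views_per_woman Scored images per woman (default 4: bilateral
#'   two-view).
#' @param lesion_views Lesion-bearing images per case (default 2).
#' @param p_unsegmented Fraction of lesion images without a mask.
#' @param seed Master seed; all stages sub-seed from it.
#' @return The dataset directory path, invisibly.
#' @export
make_dataset <- function(dir,
                         n_cases = 191, n_controls = 191,
                         systems = list(sysA = list(lambda = 1, mu = 1)),
                         height = 128, width = 128,
                         views_per_woman = 4, lesion_views = 2,
                         p_unsegmented = 0, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(dir, "scores"), showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4 + length(systems))

  cohort <- make_cohort(n_cases, n_controls, seed = seeds[1])
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)

  # image records: case women get lesion_views lesion images on the
  # affected breast plus plain images up to views_per_woman; controls get
  # plain images only
  records <- list()
  lesion_ids <- character(0)
  for (i in seq_len(n_cases)) {
    wid <- sprintf("wcase_%04d", i)
    side <- if (i %% 2 == 0) "left" else "right"
    for (v in seq_len(views_per_woman)) {
      view <- if (v %% 2 == 1) "CC" else "MLO"
      lat <- if (v <= 2) side else setdiff(c("left", "right"), side)
      iid <- sprintf("%s_img%d", wid, v)
      has_lesion <- as.integer(v <= lesion_views)
      if (has_lesion == 1) lesion_ids <- c(lesion_ids, iid)
      records[[length(records) + 1]] <- data.frame(
        image_id = iid, woman_id = wid, laterality = lat, view = view,
        height = height, width = width, has_lesion = has_lesion,
        mask = "", stringsAsFactors = FALSE
      )
    }
  }
  for (i in seq_len(n_controls)) {
    wid <- sprintf("wctrl_%04d", i)
    for (v in seq_len(views_per_woman)) {
      view <- if (v %% 2 == 1) "CC" else "MLO"
      lat <- if (v <= 2) "right" else "left"
      records[[length(records) + 1]] <- data.frame(
        image_id = sprintf("%s_img%d", wid, v), woman_id = wid,
        laterality = lat, view = view, height = height, width = width,
        has_lesion = 0L, mask = "", stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, records)

  # phantoms + masks for lesion images; a fraction stays unsegmented
  set.seed(seeds[2])
  phantom_seeds <- sample.int(.Machine$integer.max - 1L, length(lesion_ids))
  unseg <- stats::runif(length(lesion_ids)) < p_unsegmented
  masks <- list()
  for (j in seq_along(lesion_ids)) {
    ph_seed <- phantom_seeds[j]
    set.seed(ph_seed)
    center <- c(stats::runif(1, 0.3, 0.7) * height,
                stats::runif(1, 0.1, 0.4) * width)
    ph <- make_phantom(height = height, width = width,
                       lesion_center = center, seed = ph_seed)
    masks[[lesion_ids[j]]] <- ph$mask
    if (!unseg[j]) {
      mpath <- file.path("masks", paste0(lesion_ids[j], ".png"))
      write_mask(ph$mask, file.path(dir, mpath))
      manifest$mask[manifest$image_id == lesion_ids[j]] <- mpath
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)

  # per-system saliency maps and scores
  sysnames <- names(systems)
  for (s in seq_along(sysnames)) {
    sysname <- sysnames[s]
    pars <- systems[[sysname]]
    sdir <- file.path(dir, "saliency", sysname)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seeds[4 + s])
    sal_seeds <- sample.int(.Machine$integer.max - 1L, length(lesion_ids))
    for (j in seq_along(lesion_ids)) {
      sal <- make_saliency(masks[[lesion_ids[j]]], lambda = pars$lambda,
                           seed = sal_seeds[j])
      png::writePNG(sal, file.path(sdir, paste0(lesion_ids[j], ".png")))
    }
    score_seed <- sal_seeds[length(sal_seeds)] %% 1000003L + s
    sc <- make_scores(n_cases * views_per_woman,
                      n_controls * views_per_woman,
                      mu = pars$mu, seed = score_seed)
    # manifest rows are ordered case images first, then control images,
    # matching make_scores' label order
    sc$image_id <- manifest$image_id
    sc$woman_id <- manifest$woman_id
    utils::write.csv(sc, file.path(dir, "scores", paste0(sysname, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
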