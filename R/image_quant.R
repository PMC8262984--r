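# Congo red colony color segmentation (hue gate + k-means in HSB space)
# and crystal-violet pellicle intensity-profile quantification.  Images
# are in-memory H x W x 3 arrays with channel values in [0, 1]; I/O
# supports ASCII PPM (portable, text-only) always and PNG when the `png`
# package is available.

#' Read an RGB image (PPM, or PNG when available)
#'
#' @param path image path; `.ppm` is parsed natively (ASCII "P3"),
#'   `.png` requires the `png` package.
#' @return H x W x 3 numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") return(read_ppm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package; use ASCII PPM instead")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) stop("grayscale image: RGB required")
    return(img[, , 1:3, drop = FALSE])
  }
  stop("unsupported image format: ", ext)
}

#' Write an RGB image (PPM, or PNG when available)
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path output path (`.ppm` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") return(write_ppm(image, path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package; use ASCII PPM instead")
    }
    png::writePNG(image, path)
    return(invisible(path))
  }
  stop("unsupported image format: ", ext)
}

read_ppm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE,
                 comment.char = "#")
  if (tokens[1] != "P3") stop("only ASCII PPM (P3) is supported")
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxv <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)]) / maxv
  if (length(vals) != 3L * w * h) stop("truncated PPM ", path)
  # PPM is row-major, pixel-interleaved RGB
  arr <- array(NA_real_, dim = c(h, w, 3))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  for (ch in 1:3) arr[, , ch] <- matrix(m[, ch], nrow = h, byrow = TRUE)
  arr
}

write_ppm <- function(image, path, maxv = 255L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  q <- round(pmin(pmax(image, 0), 1) * maxv)
  m <- cbind(as.vector(t(q[, , 1])), as.vector(t(q[, , 2])),
             as.vector(t(q[, , 3])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxv)), con)
  writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

# HSB coordinates per pixel; hue on a 0-`hue_scale` wheel (default 255,
# the ImageJ byte convention), saturation/brightness in [0, 1]
image_hsb <- function(image, hue_scale = 255) {
  stopifnot(length(dim(image)) == 3L)
  if (dim(image)[3] < 3L) stop("grayscale image: RGB required")
  n <- dim(image)[1] * dim(image)[2]
  rgb <- rbind(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
               b = as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = hsv[1, ] * hue_scale, s = hsv[2, ], b = hsv[3, ], n = n)
}

#' Segment a Congo red colony image into red / brown / background
#'
#' Pixels are converted to HSB; those with hue inside
#' `[hue_low, hue_high]` (0-255 hue wheel by default) are red-eligible.
#' k-means (k = 3, fixed seed, multiple restarts) clusters pixels in HSB
#' space; the lowest-brightness centroid is the black background, and of
#' the remaining clusters the one dominated by hue-gated pixels is red.
#' Red pixels are the hue-gated members of the red cluster; everything
#' else non-background is brown.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param hue_low,hue_high red hue gate (default 1-14, ImageJ byte hue).
#' @param hue_scale hue wheel size (255 default; 360 supported).
#' @param seed k-means seed (default 0).
#' @param restarts k-means restarts (default 10).
#' @return list of class `"segmentation_result"`: red_pixels,
#'   brown_pixels, background_pixels, red_fraction
#'   (= red / (red + brown)).
#' @export
segment_congo_red <- function(image, hue_low = 1, hue_high = 14,
                              hue_scale = 255, seed = 0L, restarts = 10L) {
  px <- image_hsb(image, hue_scale)
  gated <- px$h >= hue_low & px$h <= hue_high
  feats <- cbind(h = px$h / hue_scale, s = px$s, b = px$b)
  distinct <- unique(feats)
  if (nrow(distinct) <= 3L) {
    # degenerate palette: assign clusters by exact color
    cl <- match(apply(feats, 1, paste, collapse = ","),
                apply(distinct, 1, paste, collapse = ","))
    centers <- distinct
  } else {
    km <- with_local_seed(seed, {
      ok <- NULL
      for (i in seq_len(restarts)) {
        res <- tryCatch(stats::kmeans(feats, centers = 3L, nstart = 5L,
                                      iter.max = 100L),
                        error = function(e) NULL)
        if (!is.null(res) && all(res$size > 0L)) { ok <- res; break }
      }
      ok
    })
    if (is.null(km)) stop("k-means failed after ", restarts, " restarts")
    cl <- km$cluster
    centers <- km$centers
  }
  bg_cluster <- which.min(centers[, "b"])
  non_bg <- setdiff(seq_len(nrow(centers)), bg_cluster)
  gated_share <- vapply(non_bg, function(k) {
    if (!any(cl == k)) return(0)
    mean(gated[cl == k])
  }, numeric(1))
  red_cluster <- if (length(non_bg)) non_bg[which.max(gated_share)]
    else integer(0)
  red <- length(red_cluster) && sum(cl == red_cluster & gated) > 0
  red_idx <- if (red) cl == red_cluster & gated else rep(FALSE, px$n)
  bg_idx <- cl == bg_cluster
  red_pixels <- sum(red_idx)
  background_pixels <- sum(bg_idx)
  brown_pixels <- px$n - red_pixels - background_pixels
  structure(list(red_pixels = red_pixels, brown_pixels = brown_pixels,
                 background_pixels = background_pixels,
                 red_fraction = if (red_pixels + brown_pixels > 0)
                   red_pixels / (red_pixels + brown_pixels) else NA_real_),
            class = "segmentation_result")
}

#' Normalize dye uptake to the wild type
#'
#' Fold dye binding = red fraction / mean wild-type red fraction.
#'
#' @param results list of [segment_congo_red()] results (or numeric red
#'   fractions).
#' @param wild_type_results same, for the wild-type strain.
#' @return numeric fold values.
#' @export
normalize_dye_uptake <- function(results, wild_type_results) {
  frac <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) r$red_fraction, numeric(1))
  }
  wt <- mean(frac(wild_type_results))
  if (!is.finite(wt) || wt == 0) {
    stop("wild-type mean red fraction is zero; fold undefined")
  }
  frac(results) / wt
}

#' Per-row intensity profile along a tube image
#'
#' Mean grayscale (luma: 0.299 R + 0.587 G + 0.114 B) per image row, top
#' row first (index 0).  With `invert = TRUE` the profile is
#' `1 - luma`, so higher values mean more crystal-violet stain.
#'
#' @param image H x W x 3 (or H x W) array in `[0, 1]`.
#' @param invert report stain-positive intensity (default FALSE).
#' @return numeric vector of length H (class `"intensity_profile"`,
#'   attribute `row_index` = 0-based indices).
#' @export
vertical_profile <- function(image, invert = FALSE) {
  if (length(image) == 0L) stop("empty image")
  gray <- if (length(dim(image)) == 3L) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else image
  if (is.null(dim(gray))) gray <- matrix(gray, ncol = 1)
  prof <- rowMeans(gray)
  if (invert) prof <- 1 - prof
  structure(prof, row_index = seq_along(prof) - 1L,
            class = "intensity_profile")
}

#' Integrate a pellicle band from an intensity profile
#'
#' Trapezoidal integral of the profile over a 0-based pixel-row range
#' (default rows 2000-2500, the band where the pellicle forms in the
#' reference tube geometry).  The range is clipped to the profile with a
#' warning when it extends beyond it.
#'
#' @param profile a [vertical_profile()] (or plain numeric vector; index
#'   0 = first element).
#' @param range_start,range_end 0-based row range, `start < end`.
#' @return numeric score.
#' @export
pellicle_score <- function(profile, range_start = 2000, range_end = 2500) {
  if (range_start >= range_end) stop("range_start must be < range_end")
  n <- length(profile)
  lo <- max(0, range_start); hi <- min(n - 1, range_end)
  if (lo != range_start || hi != range_end) {
    warning("integration range clipped to profile bounds [0, ", n - 1, "]")
  }
  if (hi <= lo) return(0)
  idx <- (lo:hi) + 1L
  p <- as.numeric(profile[idx])
  sum((p[-length(p)] + p[-1]) / 2)
}
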