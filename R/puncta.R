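# Synaptic puncta quantification from two-channel 8-bit images: rolling-ball
# background subtraction, fixed-range thresholding, connected-component
# particle analysis with size exclusion, overlap-defined synapses, and
# engulfment of presynaptic material inside microglial masks.

#' Construct a single-channel 8-bit image
#'
#' @param pixels integer matrix with values in 0..255 (rows = y, cols = x).
#' @param pixel_size_um microns per pixel.
#' @param channel_label one of `"pre"`, `"post"`, `"microglia"`.
#' @return a `channel_image` object.
#' @export
channel_image <- function(pixels, pixel_size_um,
                          channel_label = c("pre", "post", "microglia")) {
  channel_label <- match.arg(channel_label)
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_label = channel_label),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %dx%d px @ %g um/px [%s]\n", nrow(x$pixels),
              ncol(x$pixels), x$pixel_size_um, x$channel_label))
  invisible(x)
}

#' Inclusive intensity threshold range
#'
#' Published fixed ranges: Bassoon (pre) 15--255, Homer1 (post) 30--255.
#'
#' @param low,high inclusive 8-bit bounds, 0 <= low <= high <= 255.
#' @return a `threshold_spec`.
#' @export
threshold_spec <- function(low, high = 255) {
  if (low < 0 || high > 255 || low > high) {
    stop("threshold bounds must satisfy 0 <= low <= high <= 255")
  }
  structure(list(low = low, high = high), class = "threshold_spec")
}

mean3x3 <- function(m) {
  # 3x3 mean with replicated edges
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (di in 0:2) {
    for (dj in 0:2) {
      acc <- acc + p[di + seq_len(nr), dj + seq_len(nc)]
    }
  }
  acc / 9
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' spherical structuring element of the given pixel radius (the classical
#' rolling-ball estimate: the surface traced by a ball rolled under the
#' image), subtracts it from the original, and clips to [0, 255]. Following
#' the reference particle-analysis implementation, the background is
#' estimated on a 3x3-mean pre-smoothed copy by default; without smoothing,
#' the ball drops into noise minima and the background is biased low by a few
#' times the noise SD. The output is pixelwise less than or equal to the
#' input.
#'
#' @param img a [channel_image()].
#' @param radius_px ball radius in pixels (default 10).
#' @param presmooth estimate the background on a 3x3-mean smoothed copy
#'   (default `TRUE`).
#' @return a background-subtracted [channel_image()].
#' @export
subtract_background <- function(img, radius_px = 10, presmooth = TRUE) {
  stopifnot(inherits(img, "channel_image"), radius_px >= 1)
  m <- matrix(as.numeric(img$pixels), nrow(img$pixels))
  bg <- .cpp_rolling_ball_background(if (presmooth) mean3x3(m) else m,
                                     radius_px)
  bg <- pmax(bg, 0)
  out <- pmin(pmax(round(img$pixels - bg), 0), 255)
  channel_image(matrix(as.integer(out), nrow(out)), img$pixel_size_um,
                img$channel_label)
}

#' Threshold a channel into a binary mask
#'
#' @param img a [channel_image()].
#' @param spec a [threshold_spec()]; both bounds are inclusive.
#' @return logical matrix.
#' @export
threshold_channel <- function(img, spec) {
  stopifnot(inherits(img, "channel_image"), inherits(spec, "threshold_spec"))
  img$pixels >= spec$low & img$pixels <= spec$high
}

#' Particle analysis: size-filtered connected components
#'
#' Labels connected components (8-connectivity by default), computes their
#' areas as pixel count x pixel area, and retains components with
#' 0.05 um^2 < area < 1.2 um^2 (strict bounds; objects outside this window
#' are unlikely to be synaptic puncta). Components touching the image border
#' are retained and flagged.
#'
#' @param mask logical matrix from [threshold_channel()].
#' @param pixel_size_um microns per pixel.
#' @param min_area_um2,max_area_um2 exclusive size bounds.
#' @param connectivity 8 (default) or 4.
#' @param channel_label carried through to the result.
#' @return a `puncta_set`: list with `table` (data frame: `id`, `n_px`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`, `edge`), `labels` (integer
#'   matrix of all components), `keep_ids` (ids passing the size filter),
#'   `pixel_size_um`, `channel_label`.
#' @export
find_puncta <- function(mask, pixel_size_um, min_area_um2 = 0.05,
                        max_area_um2 = 1.2, connectivity = 8L,
                        channel_label = "pre") {
  stopifnot(is.logical(mask), is.matrix(mask), pixel_size_um > 0,
            connectivity %in% c(4L, 8L))
  labels <- .cpp_label_components(mask, as.integer(connectivity))
  nlab <- max(labels)
  px_area <- pixel_size_um^2
  if (nlab == 0L) {
    tab <- data.frame(id = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), edge = logical(0))
    return(structure(list(table = tab, labels = labels,
                          keep_ids = integer(0),
                          pixel_size_um = pixel_size_um,
                          channel_label = channel_label),
                     class = "puncta_set"))
  }
  npx <- tabulate(labels, nbins = nlab)
  idx <- which(labels > 0L)
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  lab_at <- labels[idx]
  # 0-based pixel-centre convention: pixel (i, j) sits at ((j-1)px, (i-1)px)
  cx <- tapply((cols - 1) * pixel_size_um, lab_at, mean)
  cy <- tapply((rows - 1) * pixel_size_um, lab_at, mean)
  edge <- tapply(rows == 1L | rows == nrow(labels) |
                   cols == 1L | cols == ncol(labels), lab_at, any)
  tab <- data.frame(id = seq_len(nlab), n_px = npx,
                    area_um2 = npx * px_area,
                    centroid_x_um = as.numeric(cx),
                    centroid_y_um = as.numeric(cy),
                    edge = as.logical(edge))
  # strict bounds with a relative epsilon so that e.g. 5 px x (0.1 um)^2
  # compares equal to 0.05 um^2 despite floating-point representation
  eps <- 1e-9
  keep <- tab$id[tab$area_um2 > min_area_um2 * (1 + eps) &
                   tab$area_um2 < max_area_um2 * (1 - eps)]
  tab <- tab[tab$id %in% keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, labels = labels, keep_ids = keep,
                 pixel_size_um = pixel_size_um,
                 channel_label = channel_label),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d retained puncta [%s] @ %g um/px\n",
              nrow(x$table), x$channel_label, x$pixel_size_um))
  invisible(x)
}

retained_mask <- function(ps) {
  matrix(ps$labels %in% ps$keep_ids, nrow(ps$labels))
}

#' Colocalise presynaptic and postsynaptic puncta into synapses
#'
#' A synapse is a retained presynaptic punctum whose pixel set intersects at
#' least one pixel of at least one retained postsynaptic punctum (a pre
#' punctum overlapping several post puncta counts once). Densities are
#' normalised by the imaged area; the colocalised area is reported both as
#' the total pre/post intersection and as the union of the puncta involved.
#'
#' @param pre,post `puncta_set`s from [find_puncta()] on images of identical
#'   geometry.
#' @param count one of `"pre_anchored"` (default: synapses = overlapping pre
#'   puncta) or `"pairs"` (count distinct overlapping pre/post pairs).
#' @return a `synapse_report`: list with counts (`n_pre`, `n_post`,
#'   `n_synapses`), densities per mm^2 and per 100 um^2 for each, area
#'   fractions (`area_fraction_pre`, `area_fraction_post`,
#'   `area_fraction_coloc` = intersection,
#'   `area_fraction_coloc_union`), `coloc_area_um2`,
#'   `coloc_union_area_um2`, `fov_area_um2`, and `synapse_pre_ids`.
#' @export
colocalize <- function(pre, post, count = c("pre_anchored", "pairs")) {
  count <- match.arg(count)
  stopifnot(inherits(pre, "puncta_set"), inherits(post, "puncta_set"))
  if (!identical(dim(pre$labels), dim(post$labels)) ||
      pre$pixel_size_um != post$pixel_size_um) {
    stop("pre and post images have different geometry")
  }
  px_area <- pre$pixel_size_um^2
  fov_area_um2 <- length(pre$labels) * px_area
  pre_keep <- retained_mask(pre)
  post_keep <- retained_mask(post)
  inter <- pre_keep & post_keep
  # per-pre-punctum overlap pixel counts
  ov <- table(factor(pre$labels[inter], levels = pre$keep_ids))
  synapse_pre_ids <- pre$keep_ids[as.integer(ov) > 0L]
  n_syn <- if (count == "pre_anchored") {
    length(synapse_pre_ids)
  } else {
    pairs <- unique(data.frame(a = pre$labels[inter], b = post$labels[inter]))
    nrow(pairs)
  }
  # union of the puncta participating in any overlap
  post_part <- unique(post$labels[inter])
  union_mask <- (matrix(pre$labels %in% synapse_pre_ids, nrow(pre$labels)) |
                   matrix(post$labels %in% post_part, nrow(post$labels)))
  n_pre <- nrow(pre$table); n_post <- nrow(post$table)
  dens <- function(n) c(per_mm2 = n / (fov_area_um2 * 1e-6),
                        per_100um2 = n / (fov_area_um2 / 100))
  structure(list(
    n_pre = n_pre, n_post = n_post, n_synapses = n_syn,
    density_pre = dens(n_pre), density_post = dens(n_post),
    density_synapses = dens(n_syn),
    area_fraction_pre = sum(pre_keep) / length(pre_keep),
    area_fraction_post = sum(post_keep) / length(post_keep),
    area_fraction_coloc = sum(inter) / length(inter),
    area_fraction_coloc_union = sum(union_mask) / length(union_mask),
    coloc_area_um2 = sum(inter) * px_area,
    coloc_union_area_um2 = sum(union_mask) * px_area,
    fov_area_um2 = fov_area_um2, synapse_pre_ids = synapse_pre_ids),
    class = "synapse_report")
}

#' @export
print.synapse_report <- function(x, ...) {
  cat(sprintf(paste0("<synapse_report> pre %d, post %d, synapses %d ",
                     "(%.1f/100 um^2)\n"),
              x$n_pre, x$n_post, x$n_synapses,
              x$density_synapses[["per_100um2"]]))
  invisible(x)
}

#' Presynaptic area engulfed inside microglial masks
#'
#' Total area of retained presynaptic puncta pixels falling inside each
#' labelled microglial cell mask.
#'
#' @param pre a `puncta_set` of the presynaptic channel.
#' @param microglia_mask integer matrix of cell labels (0 = background) or a
#'   logical mask (treated as one cell), same geometry as `pre`.
#' @param pixel_size_um microns per pixel.
#' @return data frame with `cell`, `engulfed_area_um2`.
#' @export
engulfment <- function(pre, microglia_mask, pixel_size_um = pre$pixel_size_um) {
  stopifnot(inherits(pre, "puncta_set"))
  if (is.logical(microglia_mask)) {
    microglia_mask <- matrix(as.integer(microglia_mask), nrow(microglia_mask))
  }
  if (!identical(dim(pre$labels), dim(microglia_mask))) {
    stop("mask geometry does not match the puncta image")
  }
  cells <- sort(unique(microglia_mask[microglia_mask > 0L]))
  if (!length(cells)) {
    warning("empty microglia mask; engulfed area is 0")
    return(data.frame(cell = integer(0), engulfed_area_um2 = numeric(0)))
  }
  pre_keep <- retained_mask(pre)
  counts <- tabulate(microglia_mask[pre_keep], nbins = max(cells))
  data.frame(cell = cells,
             engulfed_area_um2 = counts[cells] * pixel_size_um^2)
}

#' Fraction of the imaged area covered by a mask or retained puncta
#'
#' @param x a logical mask matrix or a `puncta_set` (retained puncta only).
#' @return fraction in [0, 1].
#' @export
area_fraction <- function(x) {
  if (inherits(x, "puncta_set")) x <- retained_mask(x)
  stopifnot(is.logical(x), is.matrix(x))
  sum(x) / length(x)
}

#' Run the full puncta pipeline on a two-channel field
#'
#' Background subtraction (10-px rolling ball), fixed-range thresholding
#' (15--255 pre, 30--255 post by default), particle analysis with size
#' exclusion, and colocalisation.
#'
#' @param pre_img,post_img [channel_image()]s of identical geometry.
#' @param pre_threshold,post_threshold [threshold_spec()]s.
#' @param rolling_ball_radius_px rolling-ball radius (pixels).
#' @param connectivity component connectivity (8 or 4).
#' @return list with `report` (a `synapse_report`), `pre`, `post`
#'   (`puncta_set`s).
#' @export
puncta_pipeline <- function(pre_img, post_img,
                            pre_threshold = threshold_spec(15, 255),
                            post_threshold = threshold_spec(30, 255),
                            rolling_ball_radius_px = 10,
                            connectivity = 8L) {
  pre_bs <- subtract_background(pre_img, rolling_ball_radius_px)
  post_bs <- subtract_background(post_img, rolling_ball_radius_px)
  pre <- find_puncta(threshold_channel(pre_bs, pre_threshold),
                     pre_img$pixel_size_um, connectivity = connectivity,
                     channel_label = "pre")
  post <- find_puncta(threshold_channel(post_bs, post_threshold),
                      post_img$pixel_size_um, connectivity = connectivity,
                      channel_label = "post")
  list(report = colocalize(pre, post), pre = pre, post = post)
}
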