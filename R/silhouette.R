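#' Load a statolith silhouette image as a binary mask
#'
#' Reads a silhouette image (black statolith on white background, or the
#' inverse), binarizes it, keeps the largest 8-connected foreground
#' component, fills interior holes, and attaches the physical scale from the
#' manifest row. This mirrors how published silhouettes are prepared by
#' hand: stray fragments (e.g. statocyst membrane remnants) are discarded,
#' and the statolith itself becomes a single solid region.
#'
#' @param meta One manifest row (a one-row `data.frame` or a named list)
#'   with at least `image_path` and `um_per_px`; see [read_manifest()].
#' @param threshold Binarization threshold as a fraction of full intensity
#'   range, in (0, 1). Inputs are assumed near-binary, so a fixed threshold
#'   (default 0.5) is used rather than an adaptive one.
#' @param polarity `"dark_foreground"` (default: black statolith on white)
#'   or `"light_foreground"`. With `dark_foreground` a pixel is foreground
#'   when its luminance is below `threshold`; with `light_foreground`, when
#'   it is above `1 - threshold`, so that inverting the image and flipping
#'   the polarity yields the identical mask.
#'
#' @return An object of class `"silhouette_mask"`: a list with `pixels`
#'   (logical matrix, rows = y increasing upward, cols = x), `um_per_px`,
#'   and `meta`. The foreground is a single filled component that does not
#'   touch the image border.
#' @export
load_silhouette <- function(meta, threshold = 0.5,
                            polarity = c("dark_foreground",
                                         "light_foreground")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop_parameter("threshold must be a single number in (0, 1)")
  }
  meta <- as.list(meta)
  if (is.null(meta$image_path) || !file.exists(meta$image_path)) {
    stop_format(sprintf("image not readable: '%s'", meta$image_path))
  }
  img <- EBImage::readImage(meta$image_path)
  lum <- image_luminance(img)
  fg <- if (polarity == "dark_foreground") lum < threshold else
    lum > 1 - threshold
  mask_from_foreground(fg, meta)
}

# EBImage stores data as [x, y(, channel)] with y running top-down;
# collapse RGB to Rec.709 luminance and return a [y-up, x] matrix in [0,1]
image_luminance <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) {
    nc <- dim(d)[3]
    d <- if (nc >= 3) {
      0.2126 * d[, , 1] + 0.7152 * d[, , 2] + 0.0722 * d[, , 3]
    } else {
      d[, , 1]
    }
  }
  m <- t(d)                  # -> [y top-down, x]
  m[rev(seq_len(nrow(m))), , drop = FALSE]   # -> [y up, x]
}

# build a validated silhouette_mask from a logical [y-up, x] foreground grid
mask_from_foreground <- function(fg, meta) {
  if (!any(fg)) {
    stop_degenerate("empty silhouette: no foreground pixel after thresholding")
  }
  comp <- largest_component8(fg)
  comp <- fill_holes(comp)
  if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)])) {
    stop_validation(
      "foreground touches the image border; the outline would be clipped")
  }
  structure(list(pixels = comp,
                 um_per_px = as.numeric(meta$um_per_px),
                 meta = meta),
            class = "silhouette_mask")
}

# largest 8-connected foreground component. EBImage::bwlabel is
# 4-connected, so labels that touch diagonally are merged by union-find.
largest_component8 <- function(fg) {
  ebi <- EBImage::Image(t(fg[rev(seq_len(nrow(fg))), , drop = FALSE]) * 1)
  lab <- EBImage::imageData(EBImage::bwlabel(ebi))
  lab <- t(lab)
  lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]  # back to [y-up, x]

  nlab <- max(lab)
  if (nlab > 1) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    unite <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour pairs (down-right and down-left in the grid)
    a <- lab[-nr, -nc]; b <- lab[-1, -1]
    idx <- which(a > 0 & b > 0 & a != b)
    for (k in idx) unite(a[k], b[k])
    a <- lab[-nr, -1]; b <- lab[-1, -nc]
    idx <- which(a > 0 & b > 0 & a != b)
    for (k in idx) unite(a[k], b[k])
    roots <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)   # ties break to the lowest label: deterministic
  lab == keep
}

# fill interior holes of a single-component mask
fill_holes <- function(fg) {
  ebi <- EBImage::Image(t(fg[rev(seq_len(nrow(fg))), , drop = FALSE]) * 1)
  filled <- EBImage::imageData(EBImage::fillHull(ebi)) > 0
  filled <- t(filled)
  filled[rev(seq_len(nrow(filled))), , drop = FALSE]
}

#' Write a silhouette mask back to a PNG image
#'
#' Renders the mask as a black-on-white 8-bit grayscale PNG, the same
#' convention expected by [load_silhouette()], so that a save/load
#' round-trip reproduces the mask exactly.
#'
#' @param mask A `"silhouette_mask"`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(mask, path) {
  stopifnot(inherits(mask, "silhouette_mask"))
  px <- mask$pixels
  img <- 1 - px[rev(seq_len(nrow(px))), , drop = FALSE] * 1  # y-up -> top-down
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("silhouette_mask: %d x %d px, %d foreground px, %.4g um/px\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels), x$um_per_px))
  invisible(x)
}
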