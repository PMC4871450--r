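#' Construct an outline object
#'
#' An outline is the universal currency between the image stage and the
#' Fourier stage: an ordered, implicitly closed sequence of (x, y) points in
#' micrometres, oriented counterclockwise (positive signed area).
#'
#' @param points Numeric matrix with two columns (x, y). Consecutive
#'   duplicate points are collapsed; clockwise point sequences are reversed.
#' @param meta Optional named list of sample metadata (specimen_id, species,
#'   family, face, ...).
#' @return Object of class `"outline"` with elements `points` and `meta`.
#' @export
new_outline <- function(points, meta = list()) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop_parameter("outline points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  # collapse consecutive duplicates (including a repeated closing point)
  n <- nrow(points)
  if (n > 1) {
    same <- c(FALSE, rowSums(abs(points[-1, , drop = FALSE] -
                                 points[-n, , drop = FALSE])) == 0)
    points <- points[!same, , drop = FALSE]
    n <- nrow(points)
    if (n > 1 && all(points[n, ] == points[1, ]))
      points <- points[-n, , drop = FALSE]
  }
  if (nrow(points) < 3) {
    stop_degenerate("outline needs at least 3 distinct points")
  }
  if (signed_area(points) < 0) {
    points <- points[nrow(points):1, , drop = FALSE]
  }
  colnames(points) <- c("x", "y")
  structure(list(points = points, meta = as.list(meta)), class = "outline")
}

# shoelace signed area; > 0 for counterclockwise order (y up)
signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

outline_perimeter <- function(outline) {
  p <- outline$points
  sum(sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2)))
}

#' Extract the closed boundary outline of a silhouette mask
#'
#' Traces the boundary pixels of the (single) foreground component with
#' Moore neighbour tracing on the 8-connected foreground, yielding the
#' outline as an ordered list of x;y pixel-centre coordinates, then scales
#' to micrometres. The trace is returned counterclockwise; the y axis
#' points up.
#'
#' @param mask A `"silhouette_mask"` from [load_silhouette()].
#' @return An `"outline"` in micrometres, carrying the mask's metadata.
#' @export
extract_outline <- function(mask) {
  stopifnot(inherits(mask, "silhouette_mask"))
  bd <- moore_trace(mask$pixels)
  if (nrow(bd) < 3) {
    stop_degenerate("foreground too small: fewer than 3 boundary points")
  }
  new_outline(bd * mask$um_per_px, meta = mask$meta)
}

# Moore neighbour boundary tracing with Jacob's stopping criterion on a
# logical [y-up, x] grid. Returns boundary pixel (x, y) indices in trace
# order; orientation is fixed by the caller via new_outline().
moore_trace <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  # start at the bottom-most, then left-most foreground pixel: its southern
  # neighbour is guaranteed background
  ys <- which(rowSums(fg) > 0)[1]
  xs <- which(fg[ys, ])[1]
  # neighbour offsets in clockwise order (y up), W first
  dx <- c(-1L, -1L, 0L, 1L, 1L,  1L,  0L, -1L)
  dy <- c( 0L,  1L, 1L, 1L, 0L, -1L, -1L, -1L)
  south <- 7L   # index of (0, -1)

  px <- integer(0); py <- integer(0)
  cx <- xs; cy <- ys
  back <- south              # direction from current pixel to its backtrack
  first_leave <- NA_integer_
  max_steps <- 4L * sum(fg) + 8L
  for (step in seq_len(max_steps)) {
    px <- c(px, cx); py <- c(py, cy)
    found <- FALSE
    d <- back
    for (k in seq_len(8L)) {
      d <- if (d == 8L) 1L else d + 1L
      nx <- cx + dx[d]; ny <- cy + dy[d]
      if (nx >= 1L && nx <= nc && ny >= 1L && ny <= nr && fg[ny, nx]) {
        found <- TRUE
        break
      }
    }
    if (!found) break                       # isolated pixel
    if (cx == xs && cy == ys) {
      if (is.na(first_leave)) first_leave <- d
      else if (d == first_leave) break      # re-entered start, same exit: done
    }
    # the next pixel's backtrack is the last background cell examined
    prevd <- if (d == 1L) 8L else d - 1L
    bx <- cx + dx[prevd]; by <- cy + dy[prevd]
    back <- dir_index(bx - (cx + dx[d]), by - (cy + dy[d]), dx, dy)
    cx <- cx + dx[d]; cy <- cy + dy[d]
  }
  # drop the duplicated start at the end of the trace, if present
  n <- length(px)
  if (n > 1 && px[n] == px[1] && py[n] == py[1]) {
    px <- px[-n]; py <- py[-n]
  }
  cbind(x = px, y = py)
}

dir_index <- function(ddx, ddy, dx, dy) {
  which(dx == ddx & dy == ddy)[1]
}

#' Smooth a closed outline by iterated local averaging
#'
#' Each iteration replaces every point by the cyclic weighted mean of
#' itself and its two neighbours with weights (1/4, 1/2, 1/4) — the
#' conventional outline-smoothing step used before elliptical Fourier
#' decomposition to suppress pixel-level jaggedness.
#'
#' @param outline An `"outline"`.
#' @param iterations Non-negative integer; 0 returns the outline unchanged.
#' @return Smoothed `"outline"` with the same number of points.
#' @export
smooth_outline <- function(outline, iterations) {
  stopifnot(inherits(outline, "outline"))
  if (length(iterations) != 1 || iterations < 0 || iterations %% 1 != 0) {
    stop_parameter("iterations must be a single non-negative integer")
  }
  p <- outline$points
  n <- nrow(p)
  prv <- c(n, seq_len(n - 1)); nxt <- c(2:n, 1)
  for (i in seq_len(iterations)) {
    p <- 0.25 * p[prv, , drop = FALSE] + 0.5 * p +
      0.25 * p[nxt, , drop = FALSE]
  }
  out <- outline
  out$points <- p
  out
}

#' Resample an outline to equally spaced points by arc length
#'
#' @param outline An `"outline"`.
#' @param n_points Integer >= 3; the first point of the input is retained
#'   as the first point of the output.
#' @return An `"outline"` with `n_points` points equally spaced along the
#'   closed polygon.
#' @export
resample_outline <- function(outline, n_points) {
  stopifnot(inherits(outline, "outline"))
  if (length(n_points) != 1 || n_points < 3 || n_points %% 1 != 0) {
    stop_parameter("n_points must be a single integer >= 3")
  }
  p <- outline$points
  n <- nrow(p)
  pc <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((pc[-1, , drop = FALSE] - pc[-(n + 1), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[n + 1]
  if (total <= 0) stop_degenerate("outline has zero perimeter")
  target <- (seq_len(n_points) - 1) * total / n_points
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (target - s[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  q <- pc[idx, , drop = FALSE] +
    frac * (pc[idx + 1, , drop = FALSE] - pc[idx, , drop = FALSE])
  out <- outline
  out$points <- q
  colnames(out$points) <- c("x", "y")
  out
}

#' Length, width and L:W ratio of an outline
#'
#' Length is the maximum Feret diameter (largest point-to-point distance);
#' width is the maximum extent measured perpendicular to the length axis.
#' Both definitions are invariant to rotation and translation, and their
#' ratio also to uniform scaling.
#'
#' @param outline An `"outline"`.
#' @return Object of class `"lw_record"`: list with `length_um`,
#'   `width_um`, `ratio` and the outline's `meta`.
#' @export
measure_length_width <- function(outline) {
  stopifnot(inherits(outline, "outline"))
  p <- outline$points
  h <- p[unique(chull(p)), , drop = FALSE]   # Feret extremes lie on the hull
  m <- nrow(h)
  if (m < 2) stop_degenerate("degenerate outline: all points coincide")
  ends <- feret_endpoints(h)
  len <- sqrt(sum((h[ends[2], ] - h[ends[1], ])^2))
  if (len <= 0) stop_degenerate("degenerate outline: zero length")
  u <- (h[ends[2], ] - h[ends[1], ]) / len
  v <- c(-u[2], u[1])
  proj <- p %*% v
  wid <- max(proj) - min(proj)
  if (wid <= len * 1e-12) {
    stop_degenerate("degenerate outline: zero width (collinear points)")
  }
  structure(list(length_um = len, width_um = wid, ratio = len / wid,
                 meta = outline$meta),
            class = "lw_record")
}

# index pair realising the maximum point-to-point distance on a convex
# hull: exhaustive for small hulls, rotating calipers (antipodal pairs)
# for large ones
feret_endpoints <- function(h) {
  m <- nrow(h)
  if (m <= 1500) {
    d2 <- as.matrix(stats::dist(h))^2
    best <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    return(c(best[1], best[2]))
  }
  # ensure counterclockwise vertex order for the calipers sweep
  if (signed_area(h) < 0) h_ord <- m:1 else h_ord <- 1:m
  hv <- h[h_ord, , drop = FALSE]
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  nxt <- function(i) if (i == m) 1L else i + 1L
  best <- c(1L, 2L); best_d2 <- 0
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    repeat {
      j2 <- nxt(j)
      if (abs(cross2(hv[i, ], hv[i2, ], hv[j2, ])) >
          abs(cross2(hv[i, ], hv[i2, ], hv[j, ]))) j <- j2 else break
    }
    for (cand in c(j, nxt(j))) {
      d2 <- sum((hv[i, ] - hv[cand, ])^2)
      if (d2 > best_d2) { best_d2 <- d2; best <- c(i, cand) }
      d2 <- sum((hv[i2, ] - hv[cand, ])^2)
      if (d2 > best_d2) { best_d2 <- d2; best <- c(i2, cand) }
    }
  }
  c(h_ord[best[1]], h_ord[best[2]])
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("outline: %d points, perimeter %.4g, area %.4g\n",
              nrow(x$points), outline_perimeter(x),
              abs(signed_area(x$points))))
  invisible(x)
}

#' @export
print.lw_record <- function(x, ...) {
  cat(sprintf("L:W record: length %.4g um, width %.4g um, ratio %.4g\n",
              x$length_um, x$width_um, x$ratio))
  invisible(x)
}

#' Tabulate L:W records for export
#'
#' @param records List of `"lw_record"` objects.
#' @return `data.frame` with columns `specimen_id, species, family, face,
#'   length_um, width_um, lw_ratio`.
#' @export
lw_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    m <- r$meta
    data.frame(specimen_id = m$specimen_id %||% NA_character_,
               species = m$species %||% NA_character_,
               family = m$family %||% NA_character_,
               face = m$face %||% NA_character_,
               length_um = r$length_um, width_um = r$width_um,
               lw_ratio = r$ratio, stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
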