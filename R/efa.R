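#' Elliptical Fourier decomposition of a closed outline
#'
#' Computes the elliptical Fourier coefficients of a closed polygonal
#' outline using the exact piecewise-linear (chain-sum) formulas: the
#' outline's x(t) and y(t), parameterised by arc length over one full
#' traversal, are each expanded in a Fourier series, giving four
#' coefficients (A_n, B_n, C_n, D_n) per harmonic. Each harmonic describes
#' an ellipse; their sum traces the outline. The formulas are exact for
#' polygons and independent of how densely the outline is sampled.
#'
#' @param outline An `"outline"`.
#' @param n_harmonics Number of harmonics H >= 1.
#' @return Object of class `"efa_coeffs"`: list with `harmonics` (H x 4
#'   matrix, columns A, B, C, D), `dc` (A0, C0 centroid terms),
#'   `normalized = FALSE`, and `meta`. Units are those of the outline
#'   (micrometres).
#' @export
efa_decompose <- function(outline, n_harmonics) {
  stopifnot(inherits(outline, "outline"))
  if (length(n_harmonics) != 1 || n_harmonics < 1 || n_harmonics %% 1 != 0) {
    stop_parameter("n_harmonics must be a single integer >= 1")
  }
  p <- outline$points
  n <- nrow(p)
  nxt <- c(2:n, 1)
  dxy <- p[nxt, , drop = FALSE] - p
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]; dt <- dt[keep]
  x <- p[keep, 1]; y <- p[keep, 2]
  total <- sum(dt)
  if (total <= 0) stop_degenerate("outline has zero perimeter")

  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  H <- as.integer(n_harmonics)
  w <- 2 * pi * seq_len(H) / total
  # phase matrices: segments x harmonics
  c1 <- cos(outer(t1, w)); c0 <- cos(outer(t0, w))
  s1 <- sin(outer(t1, w)); s0 <- sin(outer(t0, w))
  vx <- dxy[, 1] / dt; vy <- dxy[, 2] / dt
  fac <- total / (2 * pi^2 * seq_len(H)^2)
  A <- fac * colSums(vx * (c1 - c0))
  B <- fac * colSums(vx * (s1 - s0))
  C <- fac * colSums(vy * (c1 - c0))
  D <- fac * colSums(vy * (s1 - s0))
  # centroid (dc) terms: arc-length average of the piecewise-linear x, y
  xn <- x + dxy[, 1]; yn <- y + dxy[, 2]
  dc <- c(A0 = sum(dt * (x + xn) / 2) / total,
          C0 = sum(dt * (y + yn) / 2) / total)
  harm <- cbind(A = A, B = B, C = C, D = D)
  structure(list(harmonics = harm, dc = dc, normalized = FALSE,
                 meta = outline$meta),
            class = "efa_coeffs")
}

#' Normalise elliptical Fourier coefficients to the first harmonic
#'
#' Standard first-harmonic normalisation: the starting point of the trace
#' is rotated to the first-harmonic ellipse's major axis, the shape is
#' rotated so that this axis is horizontal, and all coefficients are scaled
#' by the semi-major axis length. The resulting Normalised Elliptical
#' Fourier (NEF) coefficients are invariant to size, rotation, and the
#' starting point of the outline trace; after normalisation A1 = 1 and
#' B1 = C1 = 0 are constants, while D1 carries the aspect of the first
#' ellipse. Reflection is deliberately not normalised away: mirror-image
#' shapes keep distinct coefficients.
#'
#' @param coeffs Raw `"efa_coeffs"` from [efa_decompose()].
#' @return Normalised `"efa_coeffs"` (`normalized = TRUE`, `dc = (0, 0)`).
#' @export
efa_normalize <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coeffs"))
  if (isTRUE(coeffs$normalized)) {
    stop_parameter("coefficients are already normalized")
  }
  h <- coeffs$harmonics
  H <- nrow(h)
  A1 <- h[1, 1]; B1 <- h[1, 2]; C1 <- h[1, 3]; D1 <- h[1, 4]
  theta <- 0.5 * atan2(2 * (A1 * B1 + C1 * D1),
                       A1^2 + C1^2 - B1^2 - D1^2)
  rot1 <- start_rotate(h, theta)
  # the formula can land on the minor axis; if so, advance a quarter period
  if (rot1[1, 1]^2 + rot1[1, 3]^2 < rot1[1, 2]^2 + rot1[1, 4]^2) {
    theta <- theta + pi / 2
    rot1 <- start_rotate(h, theta)
  }
  scale <- sqrt(rot1[1, 1]^2 + rot1[1, 3]^2)
  if (!is.finite(scale) || scale <= 0) {
    stop_degenerate("degenerate first-harmonic ellipse; cannot normalize")
  }
  psi <- atan2(rot1[1, 3], rot1[1, 1])
  out <- shape_rotate(rot1, psi) / scale
  # starting-point phase is defined modulo pi: theta and theta + pi give
  # normalisations differing by the sign of every even harmonic. Fix a
  # canonical representative so the result is start-point invariant.
  even <- seq_len(H) %% 2 == 0
  if (any(even)) {
    vals <- as.vector(t(out[even, , drop = FALSE]))
    tol <- 1e-8 * max(abs(out))
    lead <- vals[abs(vals) > tol]
    if (length(lead) && lead[1] < 0) out[even, ] <- -out[even, ]
  }
  out[1, ] <- c(1, 0, 0, out[1, 4])
  res <- coeffs
  res$harmonics <- out
  res$dc <- c(A0 = 0, C0 = 0)
  res$normalized <- TRUE
  res
}

# shift the starting point of the trace by phase theta (per-harmonic n*theta)
start_rotate <- function(h, theta) {
  H <- nrow(h)
  out <- h
  for (n in seq_len(H)) {
    a <- n * theta
    m <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    out[n, c(1, 2)] <- h[n, c(1, 2)] %*% m
    out[n, c(3, 4)] <- h[n, c(3, 4)] %*% m
  }
  out
}

# rotate the shape (x, y) plane by -psi
shape_rotate <- function(h, psi) {
  r <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)
  out <- h
  for (n in seq_len(nrow(h))) {
    m <- r %*% rbind(h[n, c(1, 2)], h[n, c(3, 4)])
    out[n, ] <- c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  }
  out
}

#' Harmonic power spectrum of elliptical Fourier coefficients
#'
#' Power of harmonic n is (A_n^2 + B_n^2 + C_n^2 + D_n^2) / 2; the
#' cumulative fraction measures how much of the outline's geometry the
#' first n harmonics capture, relative to all computed harmonics.
#'
#' @param coeffs An `"efa_coeffs"` (raw or normalised).
#' @return Object of class `"harmonic_power"`: list with `per_harmonic` and
#'   `cumulative_fraction`.
#' @export
harmonic_power <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coeffs"))
  pw <- rowSums(coeffs$harmonics^2) / 2
  structure(list(per_harmonic = pw,
                 cumulative_fraction = cumsum(pw) / sum(pw)),
            class = "harmonic_power")
}

#' Minimum number of harmonics to reach a harmonic-power threshold
#'
#' @param coeffs An `"efa_coeffs"`.
#' @param threshold Power fraction in (0, 1), e.g. 0.99.
#' @return Smallest n such that the first n harmonics carry at least
#'   `threshold` of the total power; if the threshold is not reached within
#'   the computed harmonics, returns H with a warning.
#' @export
min_harmonics_for_power <- function(coeffs, threshold) {
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    stop_parameter("threshold must be a single number in (0, 1)")
  }
  cf <- harmonic_power(coeffs)$cumulative_fraction
  n <- which(cf >= threshold)[1]
  if (is.na(n)) {
    warning("power threshold not reached within computed harmonics")
    n <- length(cf)
  }
  as.integer(n)
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Inverse Fourier synthesis: sums the first `n_harmonics` harmonic
#' ellipses at `n_points` equally spaced parameter values.
#'
#' @param coeffs An `"efa_coeffs"`.
#' @param n_harmonics Number of harmonics to use (<= H available).
#' @param n_points Number of points on the reconstructed outline.
#' @return An `"outline"` (dimensionless if the coefficients are
#'   normalised).
#' @export
efa_reconstruct <- function(coeffs, n_harmonics = nrow(coeffs$harmonics),
                            n_points = 256) {
  stopifnot(inherits(coeffs, "efa_coeffs"))
  H <- nrow(coeffs$harmonics)
  if (n_harmonics < 1 || n_harmonics > H) {
    stop_parameter(sprintf(
      "n_harmonics must be between 1 and %d (harmonics available)", H))
  }
  tt <- (seq_len(n_points) - 1) / n_points
  ang <- 2 * pi * outer(tt, seq_len(n_harmonics))
  cosM <- cos(ang); sinM <- sin(ang)
  hh <- coeffs$harmonics[seq_len(n_harmonics), , drop = FALSE]
  x <- coeffs$dc[1] + cosM %*% hh[, 1] + sinM %*% hh[, 2]
  y <- coeffs$dc[2] + cosM %*% hh[, 3] + sinM %*% hh[, 4]
  new_outline(cbind(x, y), meta = coeffs$meta)
}

#' Assemble the specimen-by-coefficient feature matrix
#'
#' Concatenates normalised coefficients for a chosen harmonic range
#' (default 2-20, i.e. 76 variables per face, the first harmonic being
#' constant by construction and therefore omitted) across one or more
#' statolith faces, in the fixed face order proximal, oral, lateral.
#'
#' @param samples List of normalised `"efa_coeffs"`, each with `meta`
#'   fields `specimen_id`, `face`, `species`, `family`.
#' @param face_set Character subset of `c("proximal", "oral", "lateral")`.
#' @param harmonic_range Length-2 integer vector, default `c(2, 20)`.
#' @return `data.frame` of class `"nef_features"`: columns `specimen_id`,
#'   `species`, `family`, then one column per coefficient named like
#'   `A2_prox`, ..., `D20_lat`; one row per specimen.
#' @export
build_feature_matrix <- function(samples, face_set = FACES,
                                 harmonic_range = c(2, 20)) {
  if (length(face_set) == 0) stop_parameter("face_set must not be empty")
  face_set <- FACES[FACES %in% face_set]
  if (length(face_set) == 0) {
    stop_parameter("face_set must be a subset of proximal, oral, lateral")
  }
  lo <- harmonic_range[1]; hi <- harmonic_range[2]
  if (lo < 1 || hi < lo) stop_parameter("invalid harmonic_range")
  for (s in samples) {
    if (!inherits(s, "efa_coeffs") || !isTRUE(s$normalized)) {
      stop_parameter("all samples must be normalized efa_coeffs")
    }
    if (nrow(s$harmonics) < hi) {
      stop_parameter(sprintf(
        "sample has %d harmonics; harmonic_range requires %d",
        nrow(s$harmonics), hi))
    }
  }
  key_face <- vapply(samples, function(s) s$meta$face %||% NA_character_, "")
  key_id <- vapply(samples, function(s) s$meta$specimen_id %||% NA_character_, "")
  ids <- unique(key_id)
  missing <- unlist(lapply(ids, function(id) {
    absent <- setdiff(face_set, key_face[key_id == id])
    if (length(absent)) paste0(id, " (", paste(absent, collapse = ","), ")")
    else character(0)
  }))
  if (length(missing)) {
    stop_validation(paste0("specimen(s) missing required face(s): ",
                           paste(missing, collapse = "; ")))
  }
  hseq <- lo:hi
  abbr <- c(proximal = "prox", oral = "oral", lateral = "lat")
  coef_names <- unlist(lapply(face_set, function(f)
    paste0(rep(c("A", "B", "C", "D"), times = length(hseq)),
           rep(hseq, each = 4), "_", abbr[[f]])))
  rows <- lapply(ids, function(id) {
    vals <- unlist(lapply(face_set, function(f) {
      s <- samples[[which(key_id == id & key_face == f)[1]]]
      as.vector(t(s$harmonics[hseq, , drop = FALSE]))
    }))
    s1 <- samples[[which(key_id == id)[1]]]
    cbind(data.frame(specimen_id = id,
                     species = s1$meta$species %||% NA_character_,
                     family = s1$meta$family %||% NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(t(setNames(vals, coef_names))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nef_features", "data.frame")
  out
}

# numeric coefficient columns of a feature matrix
feature_columns <- function(features) {
  setdiff(names(features), c("specimen_id", "species", "family"))
}

#' @export
print.efa_coeffs <- function(x, ...) {
  cat(sprintf("efa_coeffs: %d harmonics, %s\n", nrow(x$harmonics),
              if (isTRUE(x$normalized)) "normalized (NEF)" else "raw (um)"))
  invisible(x)
}
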