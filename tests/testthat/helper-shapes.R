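# deterministic shape constructors used across the suite ------------------

circle_outline <- function(r = 1, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  new_outline(cbind(r * cos(th), r * sin(th)))
}

ellipse_outline <- function(a = 2, b = 1, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  new_outline(cbind(a * cos(th), b * sin(th)))
}

square_outline <- function(side = 1, pts_per_edge = 32) {
  u <- seq(0, side, length.out = pts_per_edge + 1)[-(pts_per_edge + 1)]
  new_outline(rbind(cbind(u, 0), cbind(side, u),
                    cbind(side - u, side), cbind(0, side - u)))
}

# two fixed irregular closed curves with rich harmonic content
blob_outline <- function(variant = 1, n = 400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- if (variant == 1) {
    cbind(cos(th) * (1 + 0.25 * cos(3 * th + 1)),
          sin(th) * (1 - 0.2 * sin(2 * th)))
  } else {
    cbind(cos(th) + 0.3 * cos(2 * th),
          sin(th) + 0.2 * sin(3 * th) + 0.1 * cos(5 * th))
  }
  new_outline(p)
}

rotate_points <- function(p, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  p %*% R
}

# independent oracle: dense trapezoidal integration of the Fourier
# integrals of the polygon's x(t), y(t) under arc-length parameterization
efa_oracle <- function(outline, H, M = 2^17) {
  p <- outline$points
  n <- nrow(p)
  pc <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((pc[-1, , drop = FALSE] - pc[-(n + 1), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[n + 1]
  tg <- seq(0, total, length.out = M + 1)
  xg <- approx(s, pc[, 1], xout = tg)$y
  yg <- approx(s, pc[, 2], xout = tg)$y
  dt <- total / M
  trap <- function(f) (sum(f) - (f[1] + f[M + 1]) / 2) * dt
  harm <- matrix(0, H, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  for (k in seq_len(H)) {
    w <- 2 * pi * k / total
    harm[k, ] <- (2 / total) * c(trap(xg * cos(w * tg)), trap(xg * sin(w * tg)),
                                 trap(yg * cos(w * tg)), trap(yg * sin(w * tg)))
  }
  list(harmonics = harm, dc = c(trap(xg), trap(yg)) / total)
}

# image fixtures ----------------------------------------------------------

# black disc on white; returns path with the exact foreground pixel count
write_disc_png <- function(path, size = 100, r = 30, cx = (size + 1) / 2,
                           cy = (size + 1) / 2) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # [row, col] = [y, x]
  ys <- matrix(rep(seq_len(size), times = size), size)
  inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  png::writePNG(1 - inside * 1, path)
  structure(path, area = sum(inside))
}

disc_meta <- function(path, um_per_px = 1, face = "proximal",
                      specimen_id = "s1") {
  list(specimen_id = specimen_id, species = "sp", family = "fam",
       face = face, image_path = path, um_per_px = um_per_px)
}

# manifest fixtures -------------------------------------------------------

manifest_df <- function(specimens, faces = c("proximal", "oral", "lateral"),
                        species = "Chironex fleckeri",
                        family = "Chirodropidae") {
  do.call(rbind, lapply(seq_along(specimens), function(i)
    data.frame(specimen_id = specimens[i],
               species = rep(species, length.out = length(specimens))[i],
               family = rep(family, length.out = length(specimens))[i],
               face = faces, image_path = paste0(specimens[i], "_", faces, ".png"),
               um_per_px = 0.5, stringsAsFactors = FALSE)))
}

write_manifest <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# feature-level fixtures --------------------------------------------------

# construct a normalised efa_coeffs object directly (for statistics-level
# tests that do not need the image pipeline)
make_nef <- function(harm, specimen_id, face, species, family) {
  structure(list(harmonics = harm, dc = c(A0 = 0, C0 = 0), normalized = TRUE,
                 meta = list(specimen_id = specimen_id, face = face,
                             species = species, family = family)),
            class = "efa_coeffs")
}

# small multispecies NEF sample set: k species x n specimens x 3 faces,
# species differ by fixed offsets, specimens by Gaussian noise
synth_nef_samples <- function(k = 3, n = 8, sd_noise = 0.005,
                              sd_species = 0.015, seed = 11,
                              families = NULL) {
  set.seed(seed)
  faces <- c("proximal", "oral", "lateral")
  if (is.null(families)) families <- paste0("F", rep(1:ceiling(k / 2), each = 2))[1:k]
  species_base <- lapply(1:k, function(s) lapply(faces, function(f) {
    m <- matrix(0, 20, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
    m[1, ] <- c(1, 0, 0, 0.6)
    m[2:8, ] <- rnorm(7 * 4) * sd_species / (2:8)
    m
  }))
  samples <- list()
  for (s in 1:k) for (i in 1:n) for (fi in 1:3) {
    base <- species_base[[s]][[fi]]
    h <- base
    h[2:20, ] <- h[2:20, ] + rnorm(19 * 4, 0, sd_noise)
    samples[[length(samples) + 1]] <-
      make_nef(h, sprintf("sp%d_%02d", s, i), faces[fi],
               paste0("species", s), families[s])
  }
  samples
}

# memoized full-scale synthetic run shared by the heavier tests -----------

full_dataset_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "statomorph-full-run")
      ds <- generate_dataset(default_templates(), seed = 42, out_dir = dir)
      res <- run_pipeline(ds$manifest, pipeline_config())
      cache <<- list(ds = ds, res = res)
    }
    cache
  }
})
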