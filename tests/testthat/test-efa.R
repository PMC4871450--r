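test_that("a circle is its own first harmonic", {
  co <- efa_decompose(circle_outline(10, 360), 10)
  h <- co$harmonics
  expect_lt(abs(h[1, "A"] - 10), 0.01)
  expect_lt(abs(abs(h[1, "D"]) - 10), 0.01)
  expect_lt(abs(h[1, "B"]), 1e-6)
  expect_lt(abs(h[1, "C"]), 1e-6)
  pw <- harmonic_power(co)$per_harmonic
  expect_lt(sum(pw[-1]) / sum(pw), 1e-6)
  expect_lt(max(abs(co$dc)), 1e-10)      # centred circle: no offset terms
})

test_that("chain-sum coefficients match the dense integration oracle on varied shapes", {
  shapes <- list(circle_outline(1, 360), ellipse_outline(1.3, 1, 360),
                 square_outline(1, 33), blob_outline(1), blob_outline(2))
  for (o in shapes) {
    mine <- efa_decompose(o, 12)
    orc <- efa_oracle(o, 12)
    expect_lt(max(abs(mine$harmonics - orc$harmonics)), 1e-6)
    expect_lt(max(abs(mine$dc - orc$dc)), 1e-6)
  }
})

test_that("four-fold symmetry confines square power to harmonics 1, 3, 5, 7", {
  co <- efa_decompose(square_outline(1, 40), 8)
  pw <- harmonic_power(co)$per_harmonic
  frac <- pw / sum(pw)
  expect_lt(max(frac[c(2, 4, 6, 8)]), 1e-20)
  expect_true(all(frac[c(1, 3, 5, 7)] > 1e-4))
})

test_that("NEF coefficients are invariant to size, rotation and trace start", {
  o <- blob_outline(2)
  nef <- efa_normalize(efa_decompose(o, 20))
  expect_equal(unname(nef$harmonics[1, 1:3]), c(1, 0, 0))

  # uniform x3 scale: identical to near machine precision
  n3 <- efa_normalize(efa_decompose(new_outline(o$points * 3), 20))
  expect_lt(max(abs(n3$harmonics - nef$harmonics)), 1e-9)

  # the fixed 37-degree + 41-point-shift case
  q <- rotate_points(o$points, 37 * pi / 180)
  q <- q[c(42:nrow(q), 1:41), ]
  n2 <- efa_normalize(efa_decompose(new_outline(q), 20))
  expect_lt(max(abs(n2$harmonics - nef$harmonics)), 1e-6)

  # circle: normalised first harmonic is (1, 0, 0, +/-1)
  nc <- efa_normalize(efa_decompose(circle_outline(3, 360), 10))
  expect_equal(unname(nc$harmonics[1, 1:3]), c(1, 0, 0))
  expect_lt(abs(abs(nc$harmonics[1, 4]) - 1), 1e-4)
  expect_lt(max(abs(nc$harmonics[-1, ])), 1e-6)

  expect_error(efa_normalize(nef), class = "statomorph_parameter_error")
})

test_that("harmonic power is conserved, non-negative, and cumulative fraction monotone", {
  for (o in list(square_outline(), blob_outline(1))) {
    co <- efa_decompose(o, 20)
    hp <- harmonic_power(co)
    expect_true(all(hp$per_harmonic >= 0))
    expect_equal(sum(hp$per_harmonic) / 2,
                 sum(co$harmonics^2) / 4)   # conservation, both routes
    expect_true(all(diff(hp$cumulative_fraction) >= -1e-15))
    expect_equal(hp$cumulative_fraction[20], 1)
  }
})

test_that("minimum harmonic count reaches the power threshold consistently", {
  ell <- efa_decompose(ellipse_outline(2, 1, 720), 20)
  expect_equal(min_harmonics_for_power(ell, 0.99), 1L)

  # monotone in the threshold
  sq <- efa_decompose(square_outline(1, 40), 20)
  ns <- vapply(c(0.9, 0.99, 0.999, 0.9999), min_harmonics_for_power,
               integer(1), coeffs = sq)
  expect_true(all(diff(ns) >= 0))

  # same answer from the analytic polygon and from a rasterized square,
  # and from an independent reconstruction-residual scan (Parseval route)
  img <- matrix(1, 120, 120); img[31:90, 31:90] <- 0
  f <- tempfile(fileext = ".png"); png::writePNG(img, f)
  sq_px <- efa_decompose(extract_outline(load_silhouette(disc_meta(f))), 20)
  expect_equal(min_harmonics_for_power(sq_px, 0.99),
               min_harmonics_for_power(sq, 0.99))
  pw <- harmonic_power(sq)$per_harmonic
  resid <- rev(cumsum(rev(pw)))[-1] / sum(pw)    # tail power after n harmonics
  n_resid <- which(c(resid, 0) <= 0.01)[1]
  expect_equal(min_harmonics_for_power(sq, 0.99), n_resid)

  expect_error(min_harmonics_for_power(sq, 1.2),
               class = "statomorph_parameter_error")
})

test_that("reconstruction converges monotonically with harmonic count", {
  # circle from one harmonic
  co <- efa_decompose(circle_outline(1, 360), 5)
  rec <- efa_reconstruct(co, 1, 360)
  expect_lt(max(abs(sqrt(rowSums(rec$points^2)) - 1)), 1e-3)

  # parameter-aligned residual decreases in n for every tested shape
  for (o in list(blob_outline(1), square_outline(1, 40))) {
    co <- efa_decompose(o, 20)
    dense <- resample_outline(o, 1024)$points
    err <- vapply(1:20, function(n) {
      rec <- efa_reconstruct(co, n, 1024)$points
      sqrt(mean(rowSums((rec - dense)^2)))
    }, numeric(1))
    expect_true(all(diff(err) <= 1e-12))
    expect_lt(err[20], err[5])
  }

  expect_error(efa_reconstruct(co, 25), class = "statomorph_parameter_error")
})

test_that("feature matrices concatenate harmonics 2-20 per face in fixed order", {
  harm <- matrix(0.01, 20, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  harm[1, ] <- c(1, 0, 0, 0.6)
  samples <- list()
  for (id in c("x1", "x2")) for (f in c("proximal", "oral", "lateral")) {
    samples[[length(samples) + 1]] <- make_nef(harm, id, f, "spA", "famA")
  }
  fm3 <- build_feature_matrix(samples)
  expect_equal(ncol(fm3) - 3, 228)
  expect_equal(nrow(fm3), 2)
  expect_equal(names(fm3)[4], "A2_prox")
  expect_equal(names(fm3)[ncol(fm3)], "D20_lat")

  fm1 <- build_feature_matrix(samples, face_set = "proximal")
  expect_equal(ncol(fm1) - 3, 76)

  expect_error(build_feature_matrix(samples, face_set = character(0)),
               class = "statomorph_parameter_error")
  expect_error(build_feature_matrix(samples[-1]),   # x1 lost its proximal face
               class = "statomorph_validation_error")
})

test_that("NEF invariance holds across random similarity transforms", {
  set.seed(99)
  o <- blob_outline(1)
  ref <- efa_normalize(efa_decompose(o, 20))$harmonics
  for (i in 1:25) {
    ang <- runif(1, 0, 2 * pi)
    sc <- runif(1, 0.05, 20)
    shift <- sample(nrow(o$points) - 1, 1)
    q <- rotate_points(o$points, ang) * sc
    q <- q[c((shift + 1):nrow(q), 1:shift), ]
    got <- efa_normalize(efa_decompose(new_outline(q), 20))$harmonics
    expect_lt(max(abs(got - ref)), 1e-6)
  }
})
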