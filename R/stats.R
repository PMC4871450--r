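#' One-way ANOVA with Tukey-Kramer HSD post hoc comparisons
#'
#' Classical between/within variance decomposition across groups (species,
#' typically), followed by all pairwise mean comparisons using the
#' studentized-range (Tukey HSD) procedure with the Tukey-Kramer adjustment
#' for unequal group sizes.
#'
#' @param values Numeric response (e.g. L:W ratios).
#' @param groups Group labels, same length as `values`.
#' @return Object of class `"anova_result"`: `F`, `df1` (= k - 1), `df2`
#'   (= N - k), `p`, `group_means`, and a `tukey` data.frame with one row
#'   per unordered pair (`group_i`, `group_j`, `mean_diff`, `q_statistic`,
#'   `adjusted_p`).
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  N <- length(values)
  if (k < 2) stop_parameter("need at least 2 groups")
  if (N <= k) stop_parameter("need N > k observations")
  means <- tapply(values, g, mean)
  ns <- as.vector(table(g))

  if (stats::var(values) == 0) {
    # all observations identical: no variance to partition
    pairs <- utils::combn(levels(g), 2)
    tukey <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                        mean_diff = 0, q_statistic = 0, adjusted_p = 1,
                        stringsAsFactors = FALSE)
    return(structure(list(F = 0, df1 = k - 1L, df2 = N - k, p = 1,
                          group_means = means, tukey = tukey),
                     class = "anova_result"))
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  pairs <- utils::combn(levels(g), 2)
  ni <- ns[match(pairs[1, ], levels(g))]
  nj <- ns[match(pairs[2, ], levels(g))]
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
  q <- abs(diff) / se
  padj <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  tukey <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                      mean_diff = as.vector(diff), q_statistic = as.vector(q),
                      adjusted_p = as.vector(padj), stringsAsFactors = FALSE)
  structure(list(F = tab["g", "F value"], df1 = k - 1L, df2 = N - k,
                 p = tab["g", "Pr(>F)"], group_means = means, tukey = tukey),
            class = "anova_result")
}

#' Principal component selection by the Kaiser criterion
#'
#' Eigen-decomposes the correlation matrix of the feature columns and
#' retains components whose eigenvalue exceeds 1 — components carrying more
#' variance than any single standardised input variable.
#'
#' @param features Numeric matrix/data.frame (rows = specimens), or an
#'   `"nef_features"` data.frame whose identifier columns are ignored.
#' @param face Optional face label carried through for reporting.
#' @return Object of class `"pca_selection"`: `eigenvalues`,
#'   `retained_count`, `scores` (N x retained), `loadings`, `face`,
#'   `dropped_columns`.
#' @export
pca_select <- function(features, face = NULL) {
  X <- as_feature_matrix(features)
  if (nrow(X) <= 1) stop_statomorph("need more than one observation for PCA",
                                    "statomorph_insufficient_data_error")
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance column(s) before PCA",
                    length(dropped)))
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  retained <- sum(ev > 1)
  if (retained == 0) {
    warning("no eigenvalue exceeds 1; retaining the first component")
    retained <- 1L
  }
  structure(list(eigenvalues = ev, retained_count = as.integer(retained),
                 scores = pc$x[, seq_len(retained), drop = FALSE],
                 loadings = pc$rotation[, seq_len(retained), drop = FALSE],
                 center = pc$center, scale = pc$scale,
                 face = face, dropped_columns = dropped),
            class = "pca_selection")
}

as_feature_matrix <- function(features) {
  if (inherits(features, "nef_features")) {
    X <- as.matrix(features[feature_columns(features)])
    rownames(X) <- features$specimen_id
    X
  } else {
    as.matrix(features)
  }
}

#' Fit a canonical discriminant analysis model
#'
#' Canonical variates are the eigenvectors of the within-group
#' inverse-SSCP times between-group SSCP problem, scaled so the pooled
#' within-group covariance of the canonical scores is the identity. Group
#' separation is summarised by Wilks' lambda (the product of 1/(1 + l_i)
#' over the nonzero eigenvalues l_i) and tested with Rao's F
#' approximation: with t = sqrt((p^2 (k-1)^2 - 4) / (p^2 + (k-1)^2 - 5))
#' and w = N - 1 - (p + k)/2, the statistic
#' F = ((1 - L^(1/t)) / L^(1/t)) * df2 / df1 has df1 = p (k - 1) and
#' df2 = w t - p (k - 1)/2 + 1 degrees of freedom (reported floored to
#' integers).
#'
#' @param features Numeric matrix/data.frame of predictors, or an
#'   `"nef_features"` data.frame.
#' @param labels Group labels (length N).
#' @param priors `"equal"` (default) or `"proportional"` to group sizes.
#' @return Object of class `"cda_model"`; see Details for fields.
#' @export
cda_fit <- function(features, labels, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  X <- as_feature_matrix(features)
  g <- factor(labels)
  k <- nlevels(g)
  N <- nrow(X)
  p <- ncol(X)
  if (k < 2) stop_parameter("need at least 2 groups for CDA")
  if (N < k) stop_parameter("need at least one observation per group")
  if (length(labels) != N) stop_parameter("labels length must match rows")

  M <- rowsum(X, g) / as.vector(table(g))      # k x p group means
  grand <- colMeans(X)
  Xc <- X - M[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc)
  Mb <- sweep(M, 2, grand) * sqrt(as.vector(table(g)))
  B <- crossprod(Mb)

  U <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(U)) {
    warning("singular pooled within-group SSCP; applying ridge regularization")
    ridge <- 1e-8 * mean(diag(W))
    if (ridge <= 0) ridge <- 1e-8
    W <- W + diag(ridge, p)
    U <- chol(W)
  }
  Ui <- backsolve(U, diag(p))
  S <- crossprod(Ui, B %*% Ui)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  r <- min(p, k - 1)
  lambda <- pmax(eg$values[seq_len(r)], 0)
  A <- Ui %*% eg$vectors[, seq_len(r), drop = FALSE] * sqrt(max(N - k, 1))
  colnames(A) <- paste0("CV", seq_len(r))

  wilks <- prod(1 / (1 + lambda))
  ft <- rao_f(wilks, p, k, N)
  centroids <- sweep(M, 2, grand) %*% A
  rownames(centroids) <- levels(g)
  pri <- if (priors == "equal") rep(1 / k, k) else as.vector(table(g)) / N
  names(pri) <- levels(g)

  structure(list(group_labels = levels(g), priors = pri,
                 prior_mode = priors,
                 canonical_coefficients = A, grand_mean = grand,
                 group_centroids = centroids, eigenvalues = lambda,
                 wilks_lambda = wilks, rao_F = ft$F,
                 df1 = ft$df1, df2 = ft$df2, p_value = ft$p,
                 counts = as.vector(table(g)), N = N, p = p, k = k),
            class = "cda_model")
}

# Rao's F approximation for Wilks' lambda
rao_f <- function(wilks, p, k, N) {
  df1 <- p * (k - 1)
  denom <- p^2 + (k - 1)^2 - 5
  t <- if (denom > 0) sqrt((p^2 * (k - 1)^2 - 4) / denom) else 1
  w <- N - 1 - (p + k) / 2
  df2_raw <- w * t - df1 / 2 + 1
  lam <- max(wilks, .Machine$double.xmin)
  Fstat <- ((1 - lam^(1 / t)) / lam^(1 / t)) * df2_raw / df1
  df2 <- as.integer(floor(df2_raw))
  # the approximation runs out of error degrees of freedom when p
  # approaches N; the test statistic is then reported without a p-value
  pval <- if (df2 >= 1) stats::pf(Fstat, df1, df2, lower.tail = FALSE) else
    NA_real_
  list(F = Fstat, df1 = as.integer(df1), df2 = df2, p = pval)
}

#' Classify observations with a fitted CDA model
#'
#' Each observation is assigned to the group whose centroid is nearest in
#' canonical-variate space (squared Mahalanobis distance), offset by
#' -2 log(prior).
#'
#' @param model A `"cda_model"`.
#' @param features Feature rows matching the model's dimensionality.
#' @param labels Optional true labels; when given, a resubstitution-style
#'   confusion table is included.
#' @return List with `predicted` (factor) and, when `labels` is supplied,
#'   `confusion` (a `"confusion_table"`, mode `"resubstitution"`).
#' @export
cda_classify <- function(model, features, labels = NULL) {
  stopifnot(inherits(model, "cda_model"))
  X <- as_feature_matrix(features)
  if (ncol(X) != model$p) {
    stop_parameter(sprintf("feature dimension %d does not match model (%d)",
                           ncol(X), model$p))
  }
  sc <- sweep(X, 2, model$grand_mean) %*% model$canonical_coefficients
  cen <- model$group_centroids
  d2 <- outer(rowSums(sc^2), rowSums(cen^2), "+") - 2 * sc %*% t(cen)
  score <- sweep(d2, 2, 2 * log(model$priors))
  pred <- factor(model$group_labels[apply(score, 1, which.min)],
                 levels = model$group_labels)
  out <- list(predicted = pred)
  if (!is.null(labels)) {
    out$confusion <- confusion_table(labels, pred, model$group_labels,
                                     mode = "resubstitution")
  }
  out
}

#' Build a confusion table
#'
#' @param true True group labels.
#' @param predicted Predicted labels.
#' @param levels Group levels fixing row/column order.
#' @param mode `"resubstitution"` or `"jackknife"`.
#' @return Object of class `"confusion_table"`: `mode`, `counts` (k x k,
#'   true x predicted), `percent_correct_per_group`,
#'   `overall_percent_correct`.
#' @export
confusion_table <- function(true, predicted, levels = sort(unique(true)),
                            mode = c("resubstitution", "jackknife")) {
  mode <- match.arg(mode)
  tt <- factor(true, levels = levels)
  pp <- factor(predicted, levels = levels)
  counts <- table(true = tt, predicted = pp)
  n <- rowSums(counts)
  pct <- ifelse(n > 0, 100 * diag(counts) / n, NA_real_)
  structure(list(mode = mode, counts = unclass(counts),
                 percent_correct_per_group = pct,
                 overall_percent_correct = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_table")
}

#' Leave-one-out jackknifed classification
#'
#' Each observation in turn is held out, the CDA refitted on the remaining
#' N - 1 observations, and the held-out observation classified by the
#' refitted model — an honest estimate of classification success.
#'
#' @inheritParams cda_fit
#' @return A `"confusion_table"` with mode `"jackknife"` and attribute
#'   `n_refits` (= N).
#' @export
jackknife_classify <- function(features, labels,
                               priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  X <- as_feature_matrix(features)
  g <- factor(labels)
  N <- nrow(X)
  k <- nlevels(g)
  if (N < k + 2) stop_parameter("need N >= k + 2 for jackknifed classification")
  if (any(table(g) == 1)) {
    warning(paste("group(s) of size 1: their held-out observation can",
                  "never be classified correctly"))
  }
  pred <- character(N)
  refits <- 0L
  for (i in seq_len(N)) {
    m <- cda_fit(X[-i, , drop = FALSE], g[-i], priors = priors)
    refits <- refits + 1L
    pred[i] <- as.character(
      cda_classify(m, X[i, , drop = FALSE])$predicted)
  }
  ct <- confusion_table(g, factor(pred, levels = levels(g)),
                        levels = levels(g), mode = "jackknife")
  attr(ct, "n_refits") <- refits
  ct
}

#' CDA over a set of statolith faces with optional PCA reduction
#'
#' The composition used throughout the analysis: build the NEF feature
#' matrix for the requested faces, optionally reduce each face's 76
#' coefficients to its Kaiser-retained principal component scores, then
#' run species- or family-level CDA with resubstitution and jackknifed
#' confusion tables. The PCA reduction is computed once on the full data
#' set and held fixed during the jackknife.
#'
#' @param samples List of normalised `"efa_coeffs"` (all specimens, all
#'   faces), or a prebuilt `"nef_features"` data.frame.
#' @param face_set Faces to include.
#' @param level `"species"` or `"family"`.
#' @param use_pca_reduction Reduce each face by [pca_select()] first?
#' @param priors Passed to [cda_fit()].
#' @param harmonic_range Passed to [build_feature_matrix()].
#' @return List with `model`, `resubstitution`, `jackknife`, `pca`
#'   (per-face selections or NULL), and `features`.
#' @export
run_face_combination_cda <- function(samples, face_set = FACES,
                                     level = c("species", "family"),
                                     use_pca_reduction = TRUE,
                                     priors = c("equal", "proportional"),
                                     harmonic_range = c(2, 20)) {
  level <- match.arg(level)
  priors <- match.arg(priors)
  abbr <- c(proximal = "prox", oral = "oral", lateral = "lat")
  face_set <- FACES[FACES %in% face_set]
  if (inherits(samples, "nef_features")) {
    keep <- unlist(lapply(face_set, function(f)
      grep(paste0("_", abbr[[f]], "$"), names(samples), value = TRUE)))
    if (!length(keep)) stop_parameter("no columns for requested face_set")
    features <- samples[c(intersect(c("specimen_id", "species", "family"),
                                    names(samples)), keep)]
    class(features) <- c("nef_features", "data.frame")
  } else {
    features <- build_feature_matrix(samples, face_set = face_set,
                                     harmonic_range = harmonic_range)
  }
  labels <- features[[level]]

  pca <- NULL
  if (use_pca_reduction) {
    pca <- list()
    blocks <- list()
    for (f in face_set) {
      cols <- grep(paste0("_", abbr[[f]], "$"), names(features), value = TRUE)
      sel <- pca_select(features[cols], face = f)
      colnames(sel$scores) <- paste0(abbr[[f]], "_", colnames(sel$scores))
      pca[[f]] <- sel
      blocks[[f]] <- sel$scores
    }
    X <- do.call(cbind, blocks)
  } else {
    X <- as_feature_matrix(features)
  }
  model <- cda_fit(X, labels, priors = priors)
  resub <- cda_classify(model, X, labels = labels)$confusion
  jack <- jackknife_classify(X, labels, priors = priors)
  list(model = model, resubstitution = resub, jackknife = jack,
       pca = pca, features = features, level = level, face_set = face_set)
}

#' Per-species regression of mean shape on statolith size
#'
#' Ordinary least-squares regression of the specimen's mean NEF
#' coefficient (the arithmetic mean over all coefficients in its feature
#' vector) on statolith length, fitted separately for each species, to
#' test whether shape depends on size (allometry).
#'
#' @param mean_nef Per-specimen mean NEF coefficient.
#' @param length_um Per-specimen statolith length (micrometres).
#' @param species Per-specimen species labels.
#' @return `data.frame` of class `"allometry_result"`: one row per species
#'   with `n`, `slope`, `intercept`, `r_squared`, `p_value` (slope t-test).
#' @export
allometry_regression <- function(mean_nef, length_um, species) {
  sp <- factor(species)
  rows <- lapply(levels(sp), function(s) {
    sel <- sp == s
    n <- sum(sel)
    if (n < 3) {
      stop_parameter(sprintf("species '%s' has n = %d; need n >= 3", s, n))
    }
    if (stats::var(length_um[sel]) == 0) {
      stop_degenerate(sprintf(
        "species '%s' has constant length; slope undefined", s))
    }
    fit <- stats::lm(mean_nef[sel] ~ length_um[sel])
    sm <- summary(fit)
    data.frame(species = s, n = n,
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("allometry_result", "data.frame")
  out
}

#' @export
print.cda_model <- function(x, ...) {
  cat(sprintf("CDA: %d groups, %d predictors, N = %d\n", x$k, x$p, x$N))
  cat(sprintf("Wilks' lambda = %.4g, F(%d, %d) = %.4g, p = %.3g\n",
              x$wilks_lambda, x$df1, x$df2, x$rao_F, x$p_value))
  invisible(x)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("%s confusion table: overall %.1f%% correct\n",
              x$mode, x$overall_percent_correct))
  print(x$counts)
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}
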