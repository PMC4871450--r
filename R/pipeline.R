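#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with defaults matching the
#' standard statolith protocol: 20 harmonics with 300 outline-smoothing
#' iterations before decomposition, NEF features from harmonics 2-20
#' (76 variables per face), a 99% harmonic-power reporting threshold,
#' Kaiser (eigenvalue > 1) principal-component retention before CDA, equal
#' priors, and leave-one-out jackknifed cross-validation.
#'
#' @param n_harmonics Harmonics computed per outline.
#' @param smoothing_iterations Outline smoothing iterations before EFA
#'   (L:W is measured on the unsmoothed outline).
#' @param harmonic_range Harmonics entering the feature vector.
#' @param power_threshold Harmonic-power fraction reported per specimen.
#' @param face_set Faces analysed.
#' @param priors `"equal"` or `"proportional"`.
#' @param pca_reduction Reduce each face by Kaiser-retained PC scores?
#' @param threshold,polarity Binarization settings; see [load_silhouette()].
#' @param seed Optional integer recorded in the run log.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_harmonics = 20, smoothing_iterations = 300,
                            harmonic_range = c(2, 20),
                            power_threshold = 0.99,
                            face_set = c("proximal", "oral", "lateral"),
                            priors = c("equal", "proportional"),
                            pca_reduction = TRUE,
                            threshold = 0.5,
                            polarity = "dark_foreground",
                            seed = NULL) {
  priors <- match.arg(priors)
  if (harmonic_range[2] > n_harmonics) {
    stop_parameter("harmonic_range upper bound must be <= n_harmonics")
  }
  structure(list(n_harmonics = n_harmonics,
                 smoothing_iterations = smoothing_iterations,
                 harmonic_range = harmonic_range,
                 power_threshold = power_threshold,
                 face_set = face_set, priors = priors,
                 pca_reduction = pca_reduction,
                 threshold = threshold, polarity = polarity, seed = seed),
            class = "pipeline_config")
}

#' Run the full statolith analysis pipeline
#'
#' Images to classification tables in one call: silhouettes are loaded and
#' traced; length:width ratios are measured on the raw outlines and tested
#' per face by one-way ANOVA with Tukey HSD, then by CDA on the three L:W
#' variables; outlines are smoothed and decomposed into normalised
#' elliptical Fourier coefficients; per-face PCA reduction feeds species-
#' and family-level CDA with resubstitution and jackknifed confusion
#' tables; and per-species shape-on-size regressions test for allometry.
#'
#' @param manifest A manifest path or validated manifest data.frame.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every output table is
#'   written as CSV together with a log containing the configuration
#'   snapshot and an MD5 content hash per file. Reruns with identical
#'   inputs and configuration are bit-identical.
#' @return Object of class `"statolith_pipeline"`; see the elements
#'   `lw`, `lw_anova`, `lw_cda`, `features`, `pca`, `species_cda`,
#'   `family_cda`, `allometry`, `harmonic_summary`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  mf <- if (is.character(manifest)) read_manifest(manifest) else
    validate_manifest(as.data.frame(manifest))

  samples <- vector("list", nrow(mf))
  lw_records <- vector("list", nrow(mf))
  n99 <- integer(nrow(mf))
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    step <- sprintf("%s/%s", row$specimen_id, row$face)
    res <- tryCatch({
      mask <- load_silhouette(row, threshold = config$threshold,
                              polarity = config$polarity)
      outline <- extract_outline(mask)
      lw <- measure_length_width(outline)
      smoothed <- smooth_outline(outline, config$smoothing_iterations)
      nef <- efa_normalize(efa_decompose(smoothed, config$n_harmonics))
      list(lw = lw, nef = nef,
           n99 = min_harmonics_for_power(nef, config$power_threshold))
    }, statomorph_error = function(e) {
      stop_statomorph(sprintf("specimen %s: %s", step, conditionMessage(e)),
                      class(e)[1])
    })
    samples[[i]] <- res$nef
    lw_records[[i]] <- res$lw
    n99[i] <- res$n99
  }

  lw <- lw_table(lw_records)
  lw_anova <- lapply(setNames(config$face_set, config$face_set), function(f) {
    sel <- lw$face == f
    anova_oneway(lw$lw_ratio[sel], lw$species[sel])
  })

  # CDA on the L:W ratios of the analysed faces (one variable per face)
  lw_wide <- stats::reshape(
    lw[lw$face %in% config$face_set,
       c("specimen_id", "species", "family", "face", "lw_ratio")],
    idvar = c("specimen_id", "species", "family"),
    timevar = "face", direction = "wide")
  ratio_cols <- paste0("lw_ratio.", config$face_set)
  lw_X <- as.matrix(lw_wide[ratio_cols])
  lw_model <- cda_fit(lw_X, lw_wide$species, priors = config$priors)
  lw_cda <- list(model = lw_model,
                 resubstitution = cda_classify(lw_model, lw_X,
                                               labels = lw_wide$species)$confusion,
                 jackknife = jackknife_classify(lw_X, lw_wide$species,
                                                priors = config$priors))

  features <- build_feature_matrix(samples, face_set = config$face_set,
                                   harmonic_range = config$harmonic_range)
  species_cda <- run_face_combination_cda(
    features, face_set = config$face_set, level = "species",
    use_pca_reduction = config$pca_reduction, priors = config$priors)
  family_cda <- run_face_combination_cda(
    features, face_set = config$face_set, level = "family",
    use_pca_reduction = config$pca_reduction, priors = config$priors)

  # allometry: mean NEF per specimen vs statolith length (proximal-face
  # Feret length, the conventional "statolith length")
  mean_nef <- rowMeans(as_feature_matrix(features))
  len_face <- if ("proximal" %in% config$face_set) "proximal" else
    config$face_set[1]
  lenv <- lw$length_um[lw$face == len_face]
  names(lenv) <- lw$specimen_id[lw$face == len_face]
  allom <- allometry_regression(mean_nef, lenv[features$specimen_id],
                                features$species)

  harmonic_summary <- data.frame(specimen_id = mf$specimen_id,
                                 face = mf$face, species = mf$species,
                                 n99 = n99, stringsAsFactors = FALSE)

  out <- structure(list(manifest = mf, config = config, lw = lw,
                        lw_anova = lw_anova, lw_cda = lw_cda,
                        features = features,
                        pca = species_cda$pca,
                        species_cda = species_cda, family_cda = family_cda,
                        allometry = allom,
                        harmonic_summary = harmonic_summary),
                   class = "statolith_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    path
  }
  paths <- c(
    wr(results$lw, "lw_table.csv"),
    wr(results$features, "nef_features.csv"),
    wr(pca_report(results$pca), "pca_report.csv"),
    wr(confusion_csv(results$species_cda), "species_confusion.csv"),
    wr(confusion_csv(results$family_cda), "family_confusion.csv"),
    wr(results$allometry, "allometry.csv"),
    wr(results$harmonic_summary, "harmonic_power_n99.csv"),
    wr(scores_csv(results$species_cda), "species_canonical_scores.csv"))
  log <- c("statomorph pipeline run",
           paste0("config: ", deparse1(unclass(results$config))),
           paste0("n_specimens: ", length(unique(results$manifest$specimen_id))),
           paste0("file_md5: ", basename(paths), " ",
                  unname(tools::md5sum(paths))))
  writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  invisible(paths)
}

pca_report <- function(pca) {
  if (is.null(pca)) return(data.frame(face = character(0)))
  do.call(rbind, lapply(names(pca), function(f)
    data.frame(face = f,
               component = seq_along(pca[[f]]$eigenvalues),
               eigenvalue = pca[[f]]$eigenvalues,
               retained = seq_along(pca[[f]]$eigenvalues) <=
                 pca[[f]]$retained_count)))
}

confusion_csv <- function(cda) {
  ct <- cda$jackknife
  rs <- cda$resubstitution
  k <- nrow(ct$counts)
  n <- rowSums(ct$counts)
  pct <- 100 * sweep(ct$counts, 1, pmax(n, 1), "/")
  df <- data.frame(group = rownames(ct$counts), n = as.vector(n),
                   pct_correct_resub = as.vector(rs$percent_correct_per_group),
                   pct_correct_jackknife = as.vector(ct$percent_correct_per_group))
  cbind(df, as.data.frame.matrix(pct))
}

scores_csv <- function(cda) {
  m <- cda$model
  X <- if (!is.null(cda$pca)) {
    do.call(cbind, lapply(cda$pca, function(s) s$scores))
  } else {
    as_feature_matrix(cda$features)
  }
  sc <- sweep(X, 2, m$grand_mean) %*% m$canonical_coefficients
  data.frame(specimen_id = cda$features$specimen_id,
             label = cda$features[[cda$level]], sc, check.names = FALSE)
}

#' Human-readable classification report
#'
#' Formats the species- and family-level classification outcomes the way
#' they are conventionally tabulated: per group, sample size and percent
#' correctly classified under resubstitution, then the jackknifed row
#' percentages over predicted groups, rounded to whole numbers (raw CSVs
#' written by [run_pipeline()] keep full precision).
#'
#' @param results A `"statolith_pipeline"` object.
#' @return Object of class `"classification_report"`: list with `species`
#'   and `family` data.frames.
#' @export
report_tables <- function(results) {
  stopifnot(inherits(results, "statolith_pipeline"))
  fam_map <- species_family_map(results$manifest)
  sp_tab <- report_one(results$species_cda, fam_map)
  fam_tab <- report_one(results$family_cda, NULL)
  structure(list(species = sp_tab, family = fam_tab),
            class = "classification_report")
}

report_one <- function(cda, fam_map) {
  jk <- cda$jackknife
  rs <- cda$resubstitution
  groups <- rownames(jk$counts)
  n <- rowSums(jk$counts)
  pct <- round(100 * sweep(jk$counts, 1, pmax(n, 1), "/"))
  df <- data.frame(group = groups, n = as.vector(n),
                   pct_correct = round(as.vector(rs$percent_correct_per_group)),
                   stringsAsFactors = FALSE)
  if (!is.null(fam_map)) df <- cbind(family = unname(fam_map[groups]), df)
  cbind(df, as.data.frame.matrix(pct))
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Species-level classification (jackknifed row %):\n")
  print(x$species, row.names = FALSE)
  cat("\nFamily-level classification (jackknifed row %):\n")
  print(x$family, row.names = FALSE)
  invisible(x)
}

#' @export
print.statolith_pipeline <- function(x, ...) {
  cat(sprintf("statolith pipeline: %d specimens, faces: %s\n",
              length(unique(x$manifest$specimen_id)),
              paste(x$config$face_set, collapse = ", ")))
  cat(sprintf("species CDA: %.1f%% resubstitution, %.1f%% jackknifed\n",
              x$species_cda$resubstitution$overall_percent_correct,
              x$species_cda$jackknife$overall_percent_correct))
  cat(sprintf("family CDA:  %.1f%% resubstitution, %.1f%% jackknifed\n",
              x$family_cda$resubstitution$overall_percent_correct,
              x$family_cda$jackknife$overall_percent_correct))
  invisible(x)
}
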