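#' Read and validate a sample manifest
#'
#' The manifest is the bridge between images on disk and the analysis: one
#' row per photographed statolith face, carrying the specimen identity, its
#' species and family, which of the three faces the image shows, the image
#' path, and the physical scale of the image in micrometres per pixel.
#'
#' @param path Path to a UTF-8 CSV file with header
#'   `specimen_id,species,family,face,image_path,um_per_px`.
#'
#' @details Validation enforces the structural assumptions the rest of the
#' pipeline relies on: `face` must be one of `"proximal"`, `"oral"`,
#' `"lateral"`; `um_per_px` must be a positive number; the pair
#' `(specimen_id, face)` must be unique (one image per face per specimen);
#' and every species must map to exactly one family across the whole
#' manifest.
#'
#' @return A `data.frame` of class `"statolith_manifest"` with the six
#'   manifest columns, one row per (specimen, face) image.
#' @seealso [load_silhouette()]
#' @export
#' @examples
#' mf <- data.frame(
#'   specimen_id = "cf_01", species = "Chironex fleckeri",
#'   family = "Chirodropidae", face = c("proximal", "oral", "lateral"),
#'   image_path = c("p.png", "o.png", "l.png"), um_per_px = 0.75
#' )
#' path <- tempfile(fileext = ".csv")
#' write.csv(mf, path, row.names = FALSE)
#' read_manifest(path)
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("manifest file not found: '%s'", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("specimen_id", "species", "family", "face",
                "image_path", "um_per_px")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format(sprintf("manifest is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  df <- df[required]
  # image paths may be stored relative to the manifest itself (the layout
  # generate_dataset() writes); resolve them for the caller
  rel <- !grepl("^(/|~|[A-Za-z]:)", df$image_path)
  df$image_path[rel] <- file.path(dirname(path), df$image_path[rel])
  validate_manifest(df)
}

validate_manifest <- function(df) {
  bad_face <- setdiff(unique(df$face), FACES)
  if (length(bad_face)) {
    stop_validation(sprintf(
      "unknown face token(s): %s (expected %s)",
      paste(sQuote(bad_face), collapse = ", "),
      paste(FACES, collapse = ", ")))
  }
  if (!is.numeric(df$um_per_px) || anyNA(df$um_per_px) ||
      any(df$um_per_px <= 0)) {
    stop_validation("um_per_px must be a positive number for every row")
  }
  key <- paste(df$specimen_id, df$face, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop_validation(sprintf(
      "duplicate (specimen_id, face) pair(s): %s",
      paste(unique(paste0(dup$specimen_id, "/", dup$face)), collapse = ", ")))
  }
  fam_per_sp <- tapply(df$family, df$species, function(x) length(unique(x)))
  if (any(fam_per_sp > 1)) {
    stop_validation(sprintf(
      "species mapped to more than one family: %s",
      paste(names(fam_per_sp)[fam_per_sp > 1], collapse = ", ")))
  }
  class(df) <- c("statolith_manifest", "data.frame")
  df
}

#' Species-to-family lookup from a manifest
#'
#' @param manifest A validated manifest (see [read_manifest()]).
#' @return Named character vector mapping species to family.
#' @export
species_family_map <- function(manifest) {
  u <- unique(manifest[c("species", "family")])
  setNames(u$family, u$species)
}
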