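#' Rectangular assay arena configuration
#'
#' Describes the rectangular open-field tank in which a single fish is
#' assayed. Coordinates are arena-frame centimetres with the origin at the
#' bottom-left corner, x increasing to the right and y increasing upwards.
#' The default 45 x 28 cm footprint matches a standard single-fish assay
#' tank; water depth is informational only (tracking is 2-D).
#'
#' @param width_cm Arena width (x extent) in cm. Default 45.
#' @param height_cm Arena height (y extent) in cm. Default 28.
#' @param water_depth_cm Water depth in cm, informational. Default 12.5.
#' @return An object of class `arena_config`.
#' @examples
#' arena_config()
#' arena_config(width_cm = 60, height_cm = 30)
#' @export
arena_config <- function(width_cm = 45, height_cm = 28, water_depth_cm = 12.5) {
  stopifnot(is.numeric(width_cm), length(width_cm) == 1, width_cm > 0,
            is.numeric(height_cm), length(height_cm) == 1, height_cm > 0)
  structure(
    list(width_cm = as.numeric(width_cm),
         height_cm = as.numeric(height_cm),
         water_depth_cm = as.numeric(water_depth_cm),
         origin = "bottom-left"),
    class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %g x %g cm (origin bottom-left)\n",
              x$width_cm, x$height_cm))
  invisible(x)
}

# closed enums used across the package
.eye_morphs   <- c("eyeless", "micro_eyed", "normal_eyed")
.body_shapes  <- c("fusiform", "compressiform")
.assay_types  <- c(no_stimulation_10min = 600,
                   landmark_5min        = 300,
                   vibration_3min       = 180)
.clade_levels <- c("A", "B", "C", "D")

#' Per-individual metadata record
#'
#' Holds the morphological metadata needed to normalise trajectory metrics:
#' standard length (SL, snout to caudal peduncle) is the normalising unit
#' for all distance and speed indicators; eye morph and body shape are
#' closed categories.
#'
#' @param individual_id Unique individual label.
#' @param species Species label (used to join the phylogeny).
#' @param eye_morph One of `"eyeless"`, `"micro_eyed"`, `"normal_eyed"`.
#' @param standard_length_cm Standard length in cm, must be positive.
#' @param pectoral_fin_length_cm Optional pectoral fin length in cm.
#' @param body_shape One of `"fusiform"`, `"compressiform"`.
#' @param clade Optional clade label `"A"`..`"D"`.
#' @return An object of class `individual_record`.
#' @examples
#' individual_record("f1", "S_tianlinensis", "eyeless", 8.4)
#' @export
individual_record <- function(individual_id, species, eye_morph,
                              standard_length_cm,
                              pectoral_fin_length_cm = NA_real_,
                              body_shape = "compressiform",
                              clade = NA_character_) {
  eye_morph <- match.arg(eye_morph, .eye_morphs)
  body_shape <- match.arg(body_shape, .body_shapes)
  if (!is.na(clade)) clade <- match.arg(clade, .clade_levels)
  stopifnot(is.numeric(standard_length_cm), standard_length_cm > 0)
  structure(
    list(individual_id = as.character(individual_id),
         species = as.character(species),
         eye_morph = eye_morph,
         standard_length_cm = as.numeric(standard_length_cm),
         pectoral_fin_length_cm = as.numeric(pectoral_fin_length_cm),
         body_shape = body_shape,
         clade = clade),
    class = "individual_record")
}

#' Read an individual metadata table
#'
#' Reads a CSV/TSV with columns `individual_id, species, eye_morph,
#' standard_length_cm, pectoral_fin_length_cm, body_shape, clade` and
#' validates each row.
#'
#' @param path Path to the metadata file (comma- or tab-separated,
#'   sniffed from the header line).
#' @return A data.frame, one validated row per individual.
#' @export
read_metadata_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("individual_id", "species", "eye_morph", "standard_length_cm")
  missing <- setdiff(needed, names(md))
  if (length(missing))
    stop("metadata table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$individual_id))
    stop("duplicate individual_id in metadata table")
  if (!all(md$eye_morph %in% .eye_morphs))
    stop("unknown eye_morph values: ",
         paste(setdiff(unique(md$eye_morph), .eye_morphs), collapse = ", "))
  if (any(md$standard_length_cm <= 0))
    stop("standard_length_cm must be positive")
  if (is.null(md$pectoral_fin_length_cm)) md$pectoral_fin_length_cm <- NA_real_
  if (is.null(md$body_shape)) md$body_shape <- "compressiform"
  if (is.null(md$clade)) md$clade <- NA_character_
  md
}

#' Convert a metadata row to an individual_record
#' @param row One-row data.frame from [read_metadata_table()].
#' @return An `individual_record`.
#' @export
as_individual_record <- function(row) {
  individual_record(row$individual_id, row$species, row$eye_morph,
                    row$standard_length_cm,
                    pectoral_fin_length_cm = row$pectoral_fin_length_cm,
                    body_shape = row$body_shape,
                    clade = if (is.na(row$clade)) NA_character_ else row$clade)
}
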