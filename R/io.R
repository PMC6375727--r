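# File I/O for the standard interchange formats: TIFF images, ROI and
# landmark CSV, SWC trees, TSV tables, JSON ground-truth sidecars.

# Intensities are stored as 32-bit float TIFF scaled by 1/65535 (the tiff
# package stores [0,1]); round-trip error is < 2e-5 AU.
.tiff_scale <- 65535

#' Write an image to TIFF
#'
#' @param img an [image_field] (intensities must be <= 65535).
#' @param path output file.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "image_field"))
  if (max(img$pixels) > .tiff_scale) {
    stop("intensities exceed the storable range (65535 AU)")
  }
  tiff::writeTIFF(img$pixels / .tiff_scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read an image from TIFF
#'
#' @param path TIFF file.
#' @param channel channel label to attach.
#' @param pixel_size physical pixel size (um/px).
#' @return an [image_field].
#' @export
read_image_tiff <- function(path, channel = "fluorescence", pixel_size = 1) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  image_field(px * .tiff_scale, channel = channel, pixel_size = pixel_size)
}

#' Write/read an ROI polygon as CSV (one vertex per row: x, y)
#'
#' @param roi an [roi_polygon].
#' @param path CSV file.
#' @export
write_roi_csv <- function(roi, path) {
  utils::write.csv(data.frame(x = roi$x, y = roi$y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @param label label for the polygon read from `path`.
#' @export
read_roi_csv <- function(path, label = "roi") {
  if (!file.exists(path)) stop("no such ROI file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("ROI CSV must have columns x, y: ", path)
  }
  roi_polygon(df$x, df$y, label = label)
}

#' Write/read a landmark table as CSV (columns name, x, y)
#'
#' @param landmarks data.frame with columns `name, x, y`.
#' @param path CSV file.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop("no such landmarks file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("name", "x", "y") %in% names(df))) {
    stop("landmarks CSV must have columns name, x, y: ", path)
  }
  df
}

#' Write/read an arbor tree as SWC
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent.
#'
#' @param tree an [arbor_tree].
#' @param path SWC file.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "arbor_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(tree$nodes, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such SWC file: ", path)
  df <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      col.names = c("id", "type", "x", "y", "z",
                                    "radius", "parent")),
    error = function(e) stop("malformed SWC file ", path, ": ",
                             conditionMessage(e))
  )
  arbor_tree(df)
}

#' Write/read a pSILAC table as TSV
#'
#' @param table pSILAC data.frame.
#' @param path TSV file.
#' @export
write_psilac_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_psilac_tsv
#' @export
read_psilac_tsv <- function(path) {
  if (!file.exists(path)) stop("no such pSILAC table: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"protein_id" %in% names(df) || !length(rep_cols(df))) {
    stop("pSILAC TSV needs a protein_id column and rep* columns: ", path)
  }
  df
}

#' Write/read a ground-truth sidecar as JSON
#'
#' @param gt a [ground_truth].
#' @param path JSON file.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  if (!file.exists(path)) stop("no such ground-truth file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$kind, x$parameters, x$seed)
}

# Deterministic TSV writer used for stage outputs (fixed significant
# digits so reruns are byte-identical across platforms).
write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
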