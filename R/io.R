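## PNG and manifest I/O.

#' Read a PNG as a grayscale matrix in [0,1]
#'
#' Color images are converted by the Rec.601 luma weights.
#' @param path PNG file path.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] >= 3) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  x
}

#' Write a matrix in [0,1] as an 8-bit grayscale PNG
#' @param x numeric matrix; values clamped to `[0,1]`.
#' @param path output path.
#' @export
write_image_png <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Read and validate a dataset manifest CSV
#'
#' @param path manifest CSV with at least `image_path`, `mask_path`
#'   columns (plus `edge_path` for training and `size_class` for
#'   stratified evaluation).
#' @param require_edges check `edge_path` too.
#' @return the manifest data frame.
#' @export
read_manifest <- function(path, require_edges = FALSE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path")
  if (require_edges) need <- c(need, "edge_path")
  miss_col <- setdiff(need, names(man))
  if (length(miss_col) > 0) {
    stop("manifest is missing columns: ", paste(miss_col, collapse = ", "))
  }
  for (col in need) {
    missing_files <- man[[col]][!file.exists(man[[col]])]
    if (length(missing_files) > 0) {
      stop("manifest references missing files:\n  ",
           paste(utils::head(missing_files, 10), collapse = "\n  "))
    }
  }
  man
}
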