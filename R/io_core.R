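## Domain types and readers/writers for the standard artefacts:
## spot-position tables, count matrices, tile sets, feature embeddings,
## prediction tables, and RGB images.

#' Construct and validate a spot table
#'
#' A `spot_table` links spot barcodes to their array-grid coordinates and
#' full-resolution pixel centres. Pixel coordinates follow the image
#' convention: 0-based, `pixel_x` = column and `pixel_y` = row of the spot
#' centre in the full-resolution image.
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param array_row,array_col integer grid indices of each spot.
#' @param pixel_x,pixel_y non-negative integer pixel coordinates of the
#'   spot centre (x = column, y = row, 0-based).
#' @param in_tissue logical; whether the spot overlaps tissue. Defaults to
#'   all `TRUE`.
#' @param spot_diameter_um positive spot diameter in microns; 55 for
#'   10x Visium, 100 for the legacy array.
#' @return A `data.frame` of class `spot_table`, sorted by `spot_id`.
#' @export
spot_table <- function(spot_id, array_row, array_col, pixel_x, pixel_y,
                       in_tissue = TRUE, spot_diameter_um = 55) {
  df <- data.frame(
    spot_id = as.character(spot_id),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    pixel_x = as.integer(round(pixel_x)),
    pixel_y = as.integer(round(pixel_y)),
    in_tissue = rep_len(as.logical(in_tissue), length(spot_id)),
    spot_diameter_um = rep_len(as.numeric(spot_diameter_um), length(spot_id)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$spot_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  validate_spot_table(df)
}

validate_spot_table <- function(x) {
  if (anyDuplicated(x$spot_id))
    stop_spotnb(sprintf("duplicate spot_id: %s",
                        paste(unique(x$spot_id[duplicated(x$spot_id)]), collapse = ", ")),
                "spotnb_validation_error")
  if (any(x$pixel_x < 0) || any(x$pixel_y < 0))
    stop_spotnb("pixel coordinates must be non-negative", "spotnb_validation_error")
  if (any(!is.finite(x$spot_diameter_um)) || any(x$spot_diameter_um <= 0))
    stop_spotnb("spot_diameter_um must be positive", "spotnb_validation_error")
  key <- paste(x$array_row, x$array_col)
  if (anyDuplicated(key))
    stop_spotnb("duplicate (array_row, array_col) pairs", "spotnb_validation_error")
  x
}

#' Read a spot-position table
#'
#' Reads either a Space-Ranger style `tissue_positions` CSV (columns
#' barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres; with or without a header line) or a generic CSV with
#' columns `spot_id, array_row, array_col, pixel_x, pixel_y` and optional
#' `in_tissue`, `spot_diameter_um`. For the Space-Ranger dialect the last
#' two columns are the pixel row and column; they are mapped to
#' `pixel_y` and `pixel_x` respectively.
#'
#' @param path path to the CSV file.
#' @param dialect `"spaceranger"` or `"generic"`.
#' @param spot_diameter_um spot diameter used when the file carries none.
#' @return A validated [spot_table], sorted by `spot_id`.
#' @export
read_spot_table <- function(path, dialect = c("generic", "spaceranger"),
                            spot_diameter_um = 55) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_spotnb(sprintf("file not found: %s", path), "spotnb_format_error")
  if (dialect == "spaceranger") {
    first <- readLines(path, n = 1L)
    has_header <- grepl("barcode", first, ignore.case = TRUE)
    df <- data.table::fread(path, header = has_header, data.table = FALSE)
    if (ncol(df) < 6)
      stop_spotnb("spaceranger spot table needs 6 columns (barcode, in_tissue, array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres)",
                  "spotnb_format_error")
    spot_table(spot_id = df[[1]], in_tissue = as.logical(df[[2]]),
               array_row = df[[3]], array_col = df[[4]],
               pixel_y = df[[5]], pixel_x = df[[6]],
               spot_diameter_um = spot_diameter_um)
  } else {
    df <- data.table::fread(path, data.table = FALSE)
    required <- c("spot_id", "array_row", "array_col", "pixel_x", "pixel_y")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop_spotnb(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
                  "spotnb_format_error")
    if (!"in_tissue" %in% names(df)) {
      warning("no in_tissue column; assuming all spots are in tissue")
      df$in_tissue <- TRUE
    }
    if (!"spot_diameter_um" %in% names(df)) df$spot_diameter_um <- spot_diameter_um
    spot_table(df$spot_id, df$array_row, df$array_col, df$pixel_x, df$pixel_y,
               df$in_tissue, df$spot_diameter_um)
  }
}

#' Write a spot table to CSV
#' @param spots a [spot_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  data.table::fwrite(as.data.frame(spots), path)
  invisible(path)
}

#' Construct and validate an expression matrix
#'
#' Raw observed counts, spots in rows and genes in columns. Counts are
#' kept raw (no library-size normalisation): the NB head models the
#' observed RNA count directly.
#'
#' @param counts numeric matrix of non-negative integers with rownames =
#'   spot ids and colnames = gene names.
#' @return The matrix with class `expr_matrix`, rows sorted by spot id.
#' @export
expression_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_spotnb("counts must carry spot rownames and gene colnames",
                "spotnb_format_error")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop_spotnb("duplicate spot or gene labels", "spotnb_validation_error")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop_spotnb("counts must be finite non-negative integers",
                "spotnb_validation_error")
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  storage.mode(counts) <- "double"
  class(counts) <- c("expr_matrix", class(counts))
  counts
}

#' Read a gene-by-spot count matrix
#'
#' Accepts either a MatrixMarket triplet file plus plain-text gene and
#' barcode lists (genes in matrix rows, barcodes in columns, as written by
#' Space Ranger), or a dense CSV with spots in rows (first column
#' `spot_id`) and genes in columns. Both encodings of the same data yield
#' identical matrices.
#'
#' @param matrix_path MatrixMarket `.mtx` file (genes x spots).
#' @param genes_path,barcodes_path one-label-per-line text files.
#' @param csv_path dense CSV alternative; overrides the triplet arguments.
#' @return An [expression_matrix] (spots x genes, sorted by spot id).
#' @export
read_counts <- function(matrix_path = NULL, genes_path = NULL,
                        barcodes_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.table::fread(csv_path, data.table = FALSE)
    if (names(df)[1] != "spot_id")
      stop_spotnb("dense counts CSV must have first column spot_id",
                  "spotnb_format_error")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$spot_id)
    return(expression_matrix(m))
  }
  m <- as.matrix(Matrix::readMM(matrix_path))
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  ## Space Ranger features.tsv may carry id/name/type columns; keep field 1
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop_spotnb(sprintf("matrix is %d x %d but %d genes / %d barcodes listed",
                        nrow(m), ncol(m), length(genes), length(barcodes)),
                "spotnb_format_error")
  m <- t(m)
  dimnames(m) <- list(barcodes, genes)
  expression_matrix(m)
}

#' Write a count matrix as MatrixMarket triplets plus label lists
#' @param counts an [expression_matrix] (spots x genes).
#' @param dir output directory; writes `matrix.mtx`, `genes.txt`,
#'   `barcodes.txt` (genes in matrix rows, matching [read_counts]).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(unclass(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.txt"))
  writeLines(rownames(counts), file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' Write per-spot per-gene NB predictions to CSV
#'
#' Long-format CSV with columns `spot_id, gene, r, p, mean, std` (or just
#' `spot_id, gene, mean` when only means are available). Values round-trip
#' through [read_predictions] to better than 1e-9 relative error.
#'
#' @param pred an `nb_params` object (see [nb_head_apply]) or a data.frame
#'   with at least `spot_id`, `gene`, `mean`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  if (inherits(pred, "nb_params")) {
    mom <- nb_moments(pred)
    df <- data.frame(
      spot_id = rep(rownames(pred$r), times = ncol(pred$r)),
      gene = rep(colnames(pred$r), each = nrow(pred$r)),
      r = as.vector(pred$r), p = as.vector(pred$p),
      mean = as.vector(mom$mean), std = as.vector(mom$std),
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(pred)
    if (!all(c("spot_id", "gene", "mean") %in% names(df)))
      stop_spotnb("prediction table needs spot_id, gene, mean columns",
                  "spotnb_validation_error")
  }
  df <- df[order(df$spot_id, df$gene), , drop = FALSE]
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a prediction CSV written by [write_predictions]
#' @param path CSV path.
#' @return data.frame sorted by (spot_id, gene).
#' @export
read_predictions <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  df[order(df$spot_id, df$gene), , drop = FALSE]
}

#' Read precomputed per-spot feature embeddings
#'
#' CSV with a `spot_id` column followed by F numeric feature columns —
#' the import surface for externally computed embeddings (e.g. histology
#' foundation models).
#'
#' @param path CSV path.
#' @return spots x F numeric matrix (class `latent_features`, sorted by
#'   spot id) with attribute `extractor = "imported"`.
#' @export
read_embeddings <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (names(df)[1] != "spot_id")
    stop_spotnb("embeddings CSV must have first column spot_id",
                "spotnb_format_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$spot_id)
  latent_features(m, extractor = "imported")
}

#' Write feature embeddings to CSV
#' @param features spots x F matrix with spot-id rownames.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(features, path) {
  df <- data.frame(spot_id = rownames(features), unclass(features)[, , drop = FALSE],
                   stringsAsFactors = FALSE, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

latent_features <- function(m, extractor = "unknown") {
  if (any(!is.finite(m)))
    stop_spotnb("latent features must be finite", "spotnb_validation_error")
  m <- m[order(rownames(m)), , drop = FALSE]
  storage.mode(m) <- "double"
  attr(m, "extractor") <- extractor
  class(m) <- c("latent_features", class(m))
  m
}

#' Read an 8-bit RGB image (PNG or TIFF)
#' @param path image path; format chosen by extension.
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_spotnb(sprintf("unsupported image format: .%s", ext), "spotnb_format_error"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB image (PNG or TIFF)
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop_spotnb(sprintf("unsupported image format: .%s", ext), "spotnb_format_error"))
  invisible(path)
}

#' Validate that a directory holds a consistent slide dataset
#'
#' Checks that the spot table, count matrix and (optionally) image agree:
#' barcodes match, counts pass the integer/non-negative invariants, and
#' all in-tissue spot centres fall inside the image.
#'
#' @param dir directory with `positions.csv`, counts (either
#'   `counts.csv` or `matrix.mtx` + `genes.txt` + `barcodes.txt`), and
#'   optionally `image.png`/`image.tif`.
#' @return invisibly, a list with the loaded `spots`, `counts` and image
#'   dimensions; errors describe the first inconsistency found.
#' @export
validate_slide_dir <- function(dir) {
  pos <- file.path(dir, "positions.csv")
  if (!file.exists(pos))
    stop_spotnb("positions.csv not found", "spotnb_format_error")
  spots <- read_spot_table(pos, "generic")
  counts <- if (file.exists(file.path(dir, "counts.csv"))) {
    read_counts(csv_path = file.path(dir, "counts.csv"))
  } else {
    read_counts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.txt"),
                file.path(dir, "barcodes.txt"))
  }
  if (!setequal(rownames(counts), spots$spot_id))
    stop_spotnb("count-matrix barcodes do not match the spot table",
                "spotnb_alignment_error")
  img_path <- Filter(file.exists,
                     file.path(dir, c("image.png", "image.tif", "image.tiff")))
  dim_img <- NULL
  if (length(img_path)) {
    img <- read_image(img_path[[1]])
    dim_img <- dim(img)
    inside <- spots$pixel_x < dim(img)[2] & spots$pixel_y < dim(img)[1]
    if (any(!inside & spots$in_tissue))
      stop_spotnb("in-tissue spot centres fall outside the image",
                  "spotnb_validation_error")
  }
  invisible(list(spots = spots, counts = counts, image_dim = dim_img))
}
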