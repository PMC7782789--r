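# On-disk interchange formats: delimited text and MatrixMarket for matrices,
# multi-page TIFF (one page per z-slice) plus a plain-text spacing sidecar
# for volumes, and delimited text for labels / pairing / anchors. All
# indices in files are 0-based; file headers say so.

#' Write a cells-by-features matrix as TSV (and optionally MTX)
#'
#' @param X matrix.
#' @param path output `.tsv` path (a header row of feature names is
#'   written).
#' @param mtx also write a MatrixMarket sparse copy beside it.
#' @return invisibly, the path(s) written.
#' @export
write_matrix_tsv <- function(X, path, mtx = FALSE) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- path
  if (mtx) {
    mtx_path <- sub("\\.tsv$", ".mtx", path)
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), mtx_path)
    paths <- c(paths, mtx_path)
  }
  invisible(paths)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path `.tsv` path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write an integer vector (labels or pairing) as 0-based delimited text
#'
#' @param v integer vector (1-based in memory).
#' @param path output path.
#' @param what column name.
#' @return invisibly, the path.
#' @export
write_index_tsv <- function(v, path, what = "value") {
  df <- data.frame(x = as.integer(v) - 1L)
  names(df) <- paste0(what, "_0based")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 0-based index vector back to 1-based
#' @param path path written by [write_index_tsv()].
#' @return integer vector.
#' @export
read_index_tsv <- function(path) {
  as.integer(utils::read.table(path, header = TRUE, sep = "\t")[[1]]) + 1L
}

#' Write anchor pairs as 0-based delimited text
#' @param anchors 2-column matrix of row pairs (1-based in memory).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_anchors_tsv <- function(anchors, path) {
  df <- data.frame(i_0based = as.integer(anchors[, 1]) - 1L,
                   j_0based = as.integer(anchors[, 2]) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read anchors written by [write_anchors_tsv()]
#' @param path file path.
#' @return 2-column integer matrix (1-based).
#' @export
read_anchors_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cbind(i = as.integer(df[[1]]) + 1L, j = as.integer(df[[2]]) + 1L)
}

#' Write a volume (and its mask) as multi-page TIFF with a spacing sidecar
#'
#' One TIFF page per z-slice; intensities must lie in \[0, 1\]. The sidecar
#' `<stem>.spacing.txt` holds the voxel spacing in micrometres as
#' `x<TAB>y<TAB>z`.
#'
#' @param vol `list(volume, mask, spacing_um)` (see
#'   [generate_volume_modality()]).
#' @param stem output path without extension; writes `<stem>.tif`,
#'   `<stem>.mask.tif` and `<stem>.spacing.txt`.
#' @return invisibly, the paths written.
#' @export
write_volume_tiff <- function(vol, stem) {
  slices <- lapply(seq_len(dim(vol$volume)[3]), function(z) vol$volume[, , z])
  tiff::writeTIFF(slices, paste0(stem, ".tif"), bits.per.sample = 32L)
  mslices <- lapply(seq_len(dim(vol$mask)[3]),
                    function(z) matrix(as.numeric(vol$mask[, , z] != 0),
                                       nrow(vol$mask), ncol(vol$mask)))
  tiff::writeTIFF(mslices, paste0(stem, ".mask.tif"), bits.per.sample = 8L)
  writeLines(paste(vol$spacing_um, collapse = "\t"),
             paste0(stem, ".spacing.txt"))
  invisible(paste0(stem, c(".tif", ".mask.tif", ".spacing.txt")))
}

#' Read a volume written by [write_volume_tiff()]
#' @param stem path stem used at write time.
#' @return `list(volume, mask, spacing_um)`.
#' @export
read_volume_tiff <- function(stem) {
  slices <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
  vol <- simplify2array(slices)
  mslices <- tiff::readTIFF(paste0(stem, ".mask.tif"), all = TRUE)
  mask <- array(as.integer(simplify2array(mslices) > 0.5), dim(vol))
  spacing <- as.numeric(strsplit(readLines(paste0(stem, ".spacing.txt")),
                                 "\t")[[1]])
  list(volume = vol, mask = mask, spacing_um = spacing)
}

#' Write a coupled benchmark to a directory
#'
#' Vector modalities become `modality<i>.tsv` (+ `.mtx`); volume modalities
#' become a `modality<i>/` directory of per-nucleus TIFF stacks. Labels,
#' pairing and anchors are 0-based delimited text.
#'
#' @param bench a `coupled_benchmark`.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_along(bench$datasets)) {
    d <- bench$datasets[[m]]
    if (bench$specs[[m]]$kind == "vector") {
      write_matrix_tsv(d, file.path(dir, sprintf("modality%d.tsv", m)),
                       mtx = TRUE)
    } else {
      vdir <- file.path(dir, sprintf("modality%d", m))
      dir.create(vdir, showWarnings = FALSE)
      for (i in seq_along(d)) {
        write_volume_tiff(d[[i]], file.path(vdir, sprintf("nucleus%04d", i)))
      }
    }
    write_index_tsv(bench$labels[[m]],
                    file.path(dir, sprintf("labels%d.tsv", m)), "label")
  }
  write_index_tsv(bench$pairing, file.path(dir, "pairing.tsv"), "partner_row")
  write_anchors_tsv(bench$anchors, file.path(dir, "anchors.tsv"))
  invisible(dir)
}
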