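#' @useDynLib emg3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
#' @importFrom utils read.csv write.csv head tail
NULL

grid_to_list <- function(grid) {
  list(rows = grid$rows, cols = grid$cols,
       channel_map = grid$channel_map, layout_name = grid$layout_name)
}

grid_from_list <- function(x) {
  cm <- x$channel_map
  if (!is.null(cm)) cm <- matrix(as.integer(unlist(cm)), ncol = 2)
  electrode_grid(x$rows, x$cols, channel_map = cm,
                 layout_name = if (is.null(x$layout_name)) "grid" else x$layout_name)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(rec, path, extra = list()) {
  obj <- c(list(fs = rec$fs, grid = grid_to_list(rec$grid), meta = rec$meta), extra)
  jsonlite::write_json(obj, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# --- minimal NPY (version 1.0, '<f8') reader/writer; no R package on the
# system handles the format, so the few dozen lines live here -----------------

write_npy_matrix <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  shape <- sprintf("(%d, %d)", nrow(mat), ncol(mat))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  # C-order: rows vary slowest
  writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
}

read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'descr':\\s*'<f8'", header))
    stop("unsupported NPY dtype (only '<f8' handled): ", path)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([0-9]+),\\s*([0-9]+),?\\)", header))
  dims <- as.integer(strsplit(gsub("[()]", "", shp), ",")[[1]])
  vals <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  if (fortran) matrix(vals, dims[1], dims[2])
  else t(matrix(vals, dims[2], dims[1]))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, h5 = "h5", hdf5 = "h5", npy = "npy", csv = "csv",
         stop("cannot infer container format from extension: ", ext))
}

#' Save a recording to disk
#'
#' Writes an [recording()] to one of the supported containers. HDF5 (`"h5"`)
#' is the native format with datasets `signal`, `fs`, grid geometry and a JSON
#' metadata string; `"npy"` stores the signal matrix with a JSON sidecar;
#' `"csv"` is a decimal-text table (channels as rows) with a JSON sidecar.
#' HDF5 and NPY round-trip bit-identically; CSV is limited by decimal-text
#' precision (17 significant digits are written).
#'
#' @param rec An `emg_recording`.
#' @param path Destination file path.
#' @param format One of `"auto"` (from extension), `"h5"`, `"npy"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, format = "auto") {
  stopifnot(inherits(rec, "emg_recording"))
  if (format == "auto") format <- guess_format(path)
  if (format == "h5") {
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$signal, path, "signal")
    rhdf5::h5write(rec$fs, path, "fs")
    rhdf5::h5createGroup(path, "grid")
    rhdf5::h5write(rec$grid$rows, path, "grid/rows")
    rhdf5::h5write(rec$grid$cols, path, "grid/cols")
    rhdf5::h5write(rec$grid$channel_map, path, "grid/channel_map")
    rhdf5::h5write(rec$grid$layout_name, path, "grid/layout_name")
    rhdf5::h5write(as.character(jsonlite::toJSON(rec$meta, auto_unbox = TRUE, digits = NA)),
                   path, "meta_json")
    rhdf5::h5closeAll()
  } else if (format == "npy") {
    write_npy_matrix(rec$signal, path)
    write_sidecar(rec, path)
  } else if (format == "csv") {
    df <- as.data.frame(format(rec$signal, digits = 17, scientific = TRUE, trim = TRUE))
    names(df) <- paste0("f", seq_len(ncol(rec$signal)) - 1L)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    write_sidecar(rec, path, extra = list(orientation = "channels"))
  } else stop("unsupported format: ", format)
  invisible(path)
}

#' Load a recording from disk
#'
#' Reads a container written by [save_recording()] (or a foreign CSV with an
#' orientation flag) back into an `emg_recording`. Signal orientation is
#' normalized to channels x frames; a channel count inconsistent with the
#' declared grid is a descriptive error.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"h5"`, `"npy"`, `"csv"`.
#' @param grid Optional [electrode_grid()] overriding the stored geometry
#'   (required for foreign CSV files without a sidecar).
#' @param orientation For CSV only: `"channels"` if channels are rows (the
#'   default), `"frames"` if frames are rows (the matrix is transposed on
#'   load). Ignored when a sidecar declares the orientation.
#' @param fs Sampling rate in Hz for foreign CSV files without a sidecar.
#' @return An `emg_recording`.
#' @export
load_recording <- function(path, format = "auto", grid = NULL,
                           orientation = NULL, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "h5") {
    sig <- rhdf5::h5read(path, "signal")
    fs <- as.numeric(rhdf5::h5read(path, "fs"))
    g <- electrode_grid(as.integer(rhdf5::h5read(path, "grid/rows")),
                        as.integer(rhdf5::h5read(path, "grid/cols")),
                        channel_map = rhdf5::h5read(path, "grid/channel_map"),
                        layout_name = as.character(rhdf5::h5read(path, "grid/layout_name")))
    meta <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta_json")),
                               simplifyVector = TRUE)
    rhdf5::h5closeAll()
    if (!is.null(grid)) g <- grid
    return(recording(sig, fs, g, meta))
  }
  if (format == "npy") {
    sig <- read_npy_matrix(path)
    sc <- read_sidecar(path)
    g <- if (is.null(grid)) grid_from_list(sc$grid) else grid
    return(recording(sig, sc$fs, g, as.list(sc$meta)))
  }
  if (format == "csv") {
    sig <- as.matrix(read.csv(path, header = TRUE))
    storage.mode(sig) <- "double"
    dimnames(sig) <- NULL
    meta <- list()
    if (file.exists(sidecar_path(path))) {
      sc <- read_sidecar(path)
      if (is.null(fs)) fs <- sc$fs
      meta <- as.list(sc$meta)
      if (is.null(orientation)) orientation <- sc$orientation
      if (is.null(grid)) grid <- grid_from_list(sc$grid)
    }
    if (is.null(orientation)) orientation <- "channels"
    if (orientation == "frames") sig <- t(sig)
    if (is.null(grid)) stop("CSV loading requires a grid (argument or sidecar)")
    if (is.null(fs)) stop("CSV loading requires fs from a sidecar")
    return(recording(sig, fs, grid, meta))
  }
  stop("unsupported format: ", format)
}
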