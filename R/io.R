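# On-disk formats for hyperspectral cubes and label maps.
#
# ENVI: flat binary raster + text header (samples/lines/bands, data type,
# interleave, byte order). MAT: MATLAB level-5 containers, the form in which
# the Indian Pines / Salinas / Pavia University benchmarks circulate; the
# reader handles uncompressed and zlib-compressed numeric array elements
# (v7.3/HDF5 containers are not supported). Label maps also travel as plain
# CSV.

# ---- ENVI ------------------------------------------------------------------

.envi_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `3` = list(what = "integer", size = 4L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.envi_hdr_path <- function(path) {
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) return(path)
  cand <- paste0(path, ".hdr")
  if (file.exists(cand)) return(cand)
  cand2 <- sub("\\.[^.]*$", ".hdr", path)
  if (file.exists(cand2)) return(cand2)
  cand
}

.envi_data_path <- function(hdr) {
  base <- sub("\\.hdr$", "", hdr, ignore.case = TRUE)
  for (p in c(base, paste0(base, ".dat"), paste0(base, ".img")))
    if (file.exists(p) && !grepl("\\.hdr$", p, ignore.case = TRUE)) return(p)
  stop("no ENVI data file found next to header: ", hdr)
}

#' Read an ENVI raster
#'
#' @param path Path to the ENVI data file or its `.hdr` header.
#' @return A numeric array `lines x samples x bands`.
#' @export
read_envi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- .envi_hdr_path(path)
  if (!file.exists(hdr)) stop("ENVI header not found: ", hdr)
  data_path <- if (grepl("\\.hdr$", path, ignore.case = TRUE))
    .envi_data_path(path) else path
  lines <- readLines(hdr, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[tolower(m[2])]] <- trimws(m[3])
  }
  need <- function(k) {
    if (is.null(kv[[k]])) stop("ENVI header missing field: ", k)
    kv[[k]]
  }
  S <- as.integer(need("samples")); L <- as.integer(need("lines"))
  B <- as.integer(need("bands"))
  dt <- as.character(as.integer(need("data type")))
  il <- tolower(if (is.null(kv[["interleave"]])) "bsq" else kv[["interleave"]])
  off <- as.integer(if (is.null(kv[["header offset"]])) 0L else kv[["header offset"]])
  bo <- as.integer(if (is.null(kv[["byte order"]])) 0L else kv[["byte order"]])
  spec <- .envi_types[[dt]]
  if (is.null(spec)) stop("unsupported ENVI data type: ", dt)
  endian <- if (bo == 0L) "little" else "big"
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (off > 0L) readBin(con, "raw", off)
  v <- readBin(con, spec$what, n = S * L * B, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) != S * L * B)
    stop("ENVI data file shorter than header promises")
  v <- as.numeric(v)
  switch(il,
    bsq = aperm(array(v, c(S, L, B)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(S, B, L)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(B, S, L)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", il))
}

#' Write an ENVI raster
#'
#' Writes band-sequential (BSQ) double-precision data plus a text header.
#'
#' @param values Numeric array `lines x samples x bands` (a plain matrix is
#'   treated as a single band).
#' @param path Path for the data file; the header is written to `path` +
#'   `".hdr"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(values, path) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3)
  d <- dim(values)
  con <- file(path, "wb")
  writeBin(as.numeric(aperm(values, c(2L, 1L, 3L))), con, size = 8L,
           endian = "little")
  close(con)
  hdr <- c("ENVI",
           "description = {sgtn export}",
           paste("samples =", d[2L]),
           paste("lines =", d[1L]),
           paste("bands =", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0")
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# ---- MATLAB v5 -------------------------------------------------------------

.mi_types <- list(
  `1` = list(what = "integer", size = 1L, signed = TRUE),
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `3` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "integer", size = 2L, signed = FALSE),
  `5` = list(what = "integer", size = 4L, signed = TRUE),
  `6` = list(what = "numeric", size = 4L, signed = FALSE),  # uint32 via double
  `7` = list(what = "numeric", size = 4L, signed = TRUE),   # single
  `9` = list(what = "numeric", size = 8L, signed = TRUE)    # double
)

.mat_read_values <- function(raw, type, nbytes) {
  spec <- .mi_types[[as.character(type)]]
  if (is.null(spec)) stop("unsupported MAT data type: ", type)
  n <- nbytes %/% spec$size
  if (type == 6L) {
    # uint32: read as two uint16 words to avoid signed overflow
    lo <- readBin(raw, "integer", n = 2L * n, size = 2L, signed = FALSE,
                  endian = "little")
    idx <- seq(1L, 2L * n, by = 2L)
    return(lo[idx] + 65536 * lo[idx + 1L])
  }
  as.numeric(readBin(raw, spec$what, n = n, size = spec$size,
                     signed = spec$signed, endian = "little"))
}

# Parse one tagged data element starting at offset pos (1-based) of raw.
# Returns list(type, data_raw, next_pos).
.mat_element <- function(raw, pos) {
  tag <- readBin(raw[pos:(pos + 7L)], "integer", n = 2L, size = 4L,
                 endian = "little")
  type <- tag[1L]
  if (bitwAnd(type, -65536L) != 0L) {  # small element format
    nb <- bitwShiftR(bitwAnd(type, -65536L), 16L)
    type <- bitwAnd(type, 65535L)
    data <- raw[(pos + 4L):(pos + 4L + nb - 1L)]
    return(list(type = type, nbytes = nb, data = data, next_pos = pos + 8L))
  }
  nb <- tag[2L]
  data <- if (nb > 0L) raw[(pos + 8L):(pos + 8L + nb - 1L)] else raw(0)
  adv <- nb + (8L - nb %% 8L) %% 8L
  list(type = type, nbytes = nb, data = data, next_pos = pos + 8L + adv)
}

.mat_parse_matrix <- function(body) {
  pos <- 1L
  fl <- .mat_element(body, pos)                   # array flags (miUINT32 x2)
  cls <- as.integer(readBin(fl$data[1:4], "integer", size = 4L,
                            endian = "little")) %% 256L
  pos <- fl$next_pos
  dm <- .mat_element(body, pos)                   # dimensions
  dims <- readBin(dm$data, "integer", n = dm$nbytes %/% 4L, size = 4L,
                  endian = "little")
  pos <- dm$next_pos
  nm <- .mat_element(body, pos)                   # name
  name <- rawToChar(nm$data)
  pos <- nm$next_pos
  if (!(cls %in% 6:13)) return(list(name = name, value = NULL))
  pr <- .mat_element(body, pos)                   # real part
  vals <- .mat_read_values(pr$data, pr$type, pr$nbytes)
  if (length(vals) != prod(dims))
    stop("MAT array '", name, "': payload length does not match dimensions")
  value <- if (length(dims) > 1L) array(vals, dims) else vals
  list(name = name, value = value)
}

#' Read numeric arrays from a MATLAB v5 file
#'
#' Supports uncompressed and zlib-compressed numeric array elements (the
#' common benchmark containers). Complex, sparse, cell, struct, and v7.3/HDF5
#' files are not supported.
#'
#' @param path Path to the `.mat` file.
#' @return Named list of numeric arrays.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file: ", path)
  magic <- rawToChar(raw[1:4])
  if (identical(magic, "MATL") == FALSE)
    stop("not a MAT v5 file (missing MATLAB header): ", path)
  endmark <- rawToChar(raw[127:128])
  if (!identical(endmark, "IM"))
    stop("big-endian MAT files are not supported")
  out <- list()
  pos <- 129L
  n <- length(raw)
  while (pos + 7L <= n) {
    el <- .mat_element(raw, pos)
    body <- el$data
    type <- el$type
    if (type == 15L) {                            # miCOMPRESSED
      body <- memDecompress(body, type = "gzip")
      inner <- .mat_element(body, 1L)
      type <- inner$type
      body <- inner$data
      # compressed elements are not padded to the 8-byte boundary
      pos <- pos + 8L + el$nbytes
    } else {
      pos <- el$next_pos
    }
    if (type == 14L) {                            # miMATRIX
      res <- .mat_parse_matrix(body)
      if (!is.null(res$value)) out[[res$name]] <- res$value
    }
  }
  out
}

.mat_pad8 <- function(con, nb) {
  pad <- (8L - nb %% 8L) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
}

#' Write numeric arrays to an uncompressed MATLAB v5 file
#'
#' @param arrays Named list of numeric vectors/matrices/arrays.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(arrays, path) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  con <- file(path, "wb")
  on.exit(close(con))
  txt <- sprintf("MATLAB 5.0 MAT-file, created by sgtn on %s",
                 format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(txt)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                           # subsystem offset
  writeBin(as.integer(c(0L, 1L)), con, size = 1L)  # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    dims <- if (is.null(dim(a))) c(1L, length(a)) else dim(a)
    nd <- length(dims)
    name_raw <- charToRaw(nm)
    sz_flags <- 16L
    sz_dims <- 8L + 4L * nd; sz_dims <- sz_dims + (8L - sz_dims %% 8L) %% 8L
    sz_name <- 8L + length(name_raw)
    sz_name <- sz_name + (8L - sz_name %% 8L) %% 8L
    sz_data <- 8L + 8L * length(a)
    total <- sz_flags + sz_dims + sz_name + sz_data
    writeBin(c(14L, total), con, size = 4L, endian = "little")   # miMATRIX
    writeBin(c(6L, 8L), con, size = 4L, endian = "little")       # flags tag
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")       # mxDOUBLE
    writeBin(c(5L, 4L * nd), con, size = 4L, endian = "little")  # dims tag
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    .mat_pad8(con, 4L * nd)
    writeBin(c(1L, length(name_raw)), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    .mat_pad8(con, length(name_raw))
    writeBin(c(9L, 8L * length(a)), con, size = 4L, endian = "little")
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
  }
  invisible(path)
}

# ---- label maps as CSV -----------------------------------------------------

#' Write / read a label map as CSV
#'
#' Plain integer matrix, one image row per CSV row, no header.
#'
#' @param labels Integer matrix of class labels (0 = unlabeled).
#' @param path File path.
#' @return `write_labels_csv` returns `path` invisibly; `read_labels_csv`
#'   returns an integer matrix.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.table(labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "integer"))
}
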