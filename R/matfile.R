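# Minimal MATLAB level-5 MAT-file reader/writer.
#
# Covers exactly what probe-design (".SD") files need: double matrices,
# character arrays, cell arrays and (nested) structs, plus zlib-compressed
# elements.  Not a general MAT-file implementation.

MI_TYPES <- c(INT8 = 1, UINT8 = 2, INT16 = 3, UINT16 = 4, INT32 = 5,
              UINT32 = 6, SINGLE = 7, DOUBLE = 9, INT64 = 12, UINT64 = 13,
              MATRIX = 14, COMPRESSED = 15, UTF8 = 16)

mat5_read_numeric <- function(raw, type, n) {
  switch(as.character(type),
    "1" = readBin(raw, "integer", n, size = 1, signed = TRUE),
    "2" = as.integer(readBin(raw, "integer", n, size = 1, signed = FALSE)),
    "3" = readBin(raw, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "4" = readBin(raw, "integer", n, size = 2, signed = FALSE, endian = "little"),
    "5" = readBin(raw, "integer", n, size = 4, endian = "little"),
    "6" = readBin(raw, "integer", n, size = 4, endian = "little"),
    "7" = readBin(raw, "numeric", n, size = 4, endian = "little"),
    "9" = readBin(raw, "numeric", n, size = 8, endian = "little"),
    "16" = utf8ToInt(rawToChar(raw[seq_len(n)])),
    stop("unsupported MAT data type ", type))
}

# Parse the sequence of data elements contained in `raw`; returns list of
# list(type, data_raw).
mat5_elements <- function(raw) {
  out <- list()
  pos <- 1L
  n <- length(raw)
  while (pos + 7L <= n + 1L && pos <= n) {
    hdr <- raw[pos:(pos + 3L)]
    type32 <- readBin(hdr, "integer", 1, size = 4, endian = "little")
    small_size <- bitwAnd(bitwShiftR(type32, 16), 0xFFFF)
    if (small_size > 0) {  # small data element: 4-byte tag, 4-byte data
      type <- bitwAnd(type32, 0xFFFF)
      dat <- raw[(pos + 4L):(pos + 3L + small_size)]
      out[[length(out) + 1]] <- list(type = type, data = dat)
      pos <- pos + 8L
    } else {
      type <- type32
      size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4, endian = "little")
      dat <- if (size > 0) raw[(pos + 8L):(pos + 7L + size)] else raw(0)
      out[[length(out) + 1]] <- list(type = type, data = dat)
      pad <- (8L - size %% 8L) %% 8L
      pos <- pos + 8L + size + pad
    }
  }
  out
}

mat5_parse_matrix <- function(raw) {
  els <- mat5_elements(raw)
  flags <- readBin(els[[1]]$data, "integer", 2, size = 4, endian = "little")
  cls <- bitwAnd(flags[1], 0xFF)
  dims <- readBin(els[[2]]$data, "integer",
                  length(els[[2]]$data) %/% 4, size = 4, endian = "little")
  name <- rawToChar(els[[3]]$data[els[[3]]$data != as.raw(0)])
  value <- switch(as.character(cls),
    "1" = {  # cell array
      lapply(els[-(1:3)], function(e) mat5_parse_matrix(e$data)$value)
    },
    "2" = {  # struct
      flen <- readBin(els[[4]]$data, "integer", 1, size = 4, endian = "little")
      fn_raw <- els[[5]]$data
      nf <- length(fn_raw) %/% flen
      fnames <- vapply(seq_len(nf), function(i) {
        chunk <- fn_raw[((i - 1) * flen + 1):(i * flen)]
        rawToChar(chunk[chunk != as.raw(0)])
      }, character(1))
      vals <- lapply(els[-(1:5)], function(e) mat5_parse_matrix(e$data)$value)
      # one element per field per struct-array entry; SD files are 1x1
      setNames(vals[seq_len(nf)], fnames)
    },
    "4" = {  # char
      e <- els[[4]]
      n <- prod(dims)
      codes <- if (e$type == 16) utf8ToInt(rawToChar(e$data))
               else mat5_read_numeric(e$data, e$type, n)
      paste(intToUtf8(codes, multiple = TRUE), collapse = "")
    },
    {  # numeric
      e <- els[[4]]
      n <- prod(dims)
      v <- mat5_read_numeric(e$data, e$type, min(n, length(e$data)))
      v <- as.numeric(v)
      if (length(dims) == 2 && dims[2] > 1 && dims[1] > 1)
        matrix(v, dims[1], dims[2]) else v
    })
  list(name = name, value = value)
}

#' Read a (subset of a) MATLAB level-5 MAT file
#'
#' Supports double/char/cell/struct variables and zlib-compressed
#' elements; enough for AtlasViewer-style probe design files.
#'
#' @param path File path.
#' @return Named list of variables.
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT-file: too short")
  magic <- rawToChar(raw[1:4])
  if (!grepl("^MATL", magic)) stop("not a level-5 MAT-file")
  els <- mat5_elements(raw[-(1:128)])
  vars <- list()
  for (e in els) {
    if (e$type == MI_TYPES[["COMPRESSED"]]) {
      dat <- tryCatch(memDecompress(e$data, type = "gzip"),
                      error = function(err)
                        stop("cannot decompress MAT element: ", conditionMessage(err)))
      inner <- mat5_elements(dat)[[1]]
      if (inner$type != MI_TYPES[["MATRIX"]]) next
      pm <- mat5_parse_matrix(inner$data)
    } else if (e$type == MI_TYPES[["MATRIX"]]) {
      pm <- mat5_parse_matrix(e$data)
    } else next
    vars[[pm$name]] <- pm$value
  }
  vars
}

# -- writer ------------------------------------------------------------------

mat5_tag <- function(type, size) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(size), raw(), size = 4, endian = "little"))
}

mat5_pad <- function(bytes) {
  pad <- (8L - length(bytes) %% 8L) %% 8L
  c(bytes, rep(as.raw(0), pad))
}

mat5_element <- function(type, data_raw) {
  mat5_pad(c(mat5_tag(type, length(data_raw)), data_raw))
}

mat5_encode_matrix <- function(name, value) {
  if (is.list(value) && !is.null(names(value)) && length(names(value)) == length(value)) {
    cls <- 2L  # struct
  } else if (is.list(value)) {
    cls <- 1L  # cell
  } else if (is.character(value)) {
    cls <- 4L
  } else cls <- 6L
  dims <- if (cls == 6 && is.matrix(value)) dim(value)
          else if (cls == 4) c(1L, nchar(value))
          else if (cls == 6) c(length(value), if (length(value)) 1L else 0L)
          else if (cls == 2) c(1L, 1L)
          else c(1L, length(value))
  flags <- writeBin(c(as.integer(cls), 0L), raw(), size = 4, endian = "little")
  body <- c(mat5_element(6, flags),
            mat5_element(5, writeBin(as.integer(dims), raw(), size = 4, endian = "little")),
            mat5_element(1, charToRaw(name)))
  if (cls == 6) {
    body <- c(body, mat5_element(9, writeBin(as.numeric(value), raw(),
                                             size = 8, endian = "little")))
  } else if (cls == 4) {
    codes <- utf8ToInt(value)
    body <- c(body, mat5_element(4, writeBin(as.integer(codes), raw(),
                                             size = 2, endian = "little")))
  } else if (cls == 1) {
    for (v in value) body <- c(body, mat5_encode_matrix("", v))
  } else {
    fnames <- names(value)
    flen <- 32L
    body <- c(body,
              mat5_element(5, writeBin(flen, raw(), size = 4, endian = "little")),
              mat5_element(1, as.raw(unlist(lapply(fnames, function(f) {
                b <- charToRaw(f)
                c(as.integer(b), rep(0L, flen - length(b)))
              })))))
    for (v in value) body <- c(body, mat5_encode_matrix("", v))
  }
  mat5_element(14, body)
}

#' Write variables to a MATLAB level-5 MAT file (uncompressed)
#'
#' @param vars Named list: numeric vectors/matrices, strings, lists
#'   (cells) and named lists (structs).
#' @param path Output path.
#' @export
write_mat <- function(vars, path) {
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by capgen%s",
                           strrep(" ", 200)))[1:116]
  hdr <- c(hdr, rep(as.raw(0), 8))                          # subsys offset
  hdr <- c(hdr, writeBin(256L, raw(), size = 2, endian = "little")) # version
  hdr <- c(hdr, charToRaw("IM"))
  out <- hdr
  for (nm in names(vars)) out <- c(out, mat5_encode_matrix(nm, vars[[nm]]))
  writeBin(out, path)
  invisible(path)
}
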