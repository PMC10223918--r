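# Minimal MAT-file (level 5) reader/writer for numeric and character arrays.
# Covers the subset used for trial-tensor exchange: little-endian files,
# uncompressed data elements (zlib-compressed elements are inflated when the
# zlib header is present), real full arrays. Column-major layout matches R.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_NUMERIC_CLASSES <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)

pad8 <- function(n) (8L - n %% 8L) %% 8L

write_mat5 <- function(path, vars) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by rlscca on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)               # endian indicator
  for (nm in names(vars)) {
    writeBin(mat5_element(nm, vars[[nm]]), con)
  }
  invisible(path)
}

# serialize one miMATRIX element to raw
mat5_element <- function(name, x) {
  is_char <- is.character(x)
  if (is_char) {
    stopifnot(length(x) == 1L)
    codes <- utf8ToInt(x)
    dims <- c(1L, length(codes))
  } else {
    stopifnot(is.numeric(x))
    dims <- if (is.null(dim(x))) c(1L, length(x)) else dim(x)
  }
  sub <- c(
    mat5_sub(MI_UINT32, writeBin(c(if (is_char) MX_CHAR else MX_DOUBLE, 0L),
                                 raw(), size = 4L, endian = "little")),
    mat5_sub(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                                endian = "little")),
    mat5_sub(MI_INT8, charToRaw(name)),
    if (is_char) {
      mat5_sub(MI_UINT16, writeBin(as.integer(codes), raw(), size = 2L,
                                   endian = "little"))
    } else {
      mat5_sub(MI_DOUBLE, writeBin(as.double(x), raw(), size = 8L,
                                   endian = "little"))
    }
  )
  c(writeBin(c(MI_MATRIX, length(sub)), raw(), size = 4L, endian = "little"),
    sub)
}

mat5_sub <- function(type, payload) {
  n <- length(payload)
  c(writeBin(c(as.integer(type), n), raw(), size = 4L, endian = "little"),
    payload, raw(pad8(n)))
}

read_mat5 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 128L) {
    stop("not a MAT-5 file: header truncated (", basename(path), ")",
         call. = FALSE)
  }
  endian <- rawToChar(raw_all[127:128])
  if (endian != "IM") {
    stop("unsupported MAT-5 byte order indicator '", endian,
         "' (only little-endian files are supported)", call. = FALSE)
  }
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw_all)) {
    el <- mat5_read_element(raw_all, pos)
    pos <- el$next_pos
    body <- el$data
    type <- el$type
    if (type == MI_COMPRESSED) {
      # compressed elements are not 8-byte padded on disk (scipy, MATLAB)
      pos <- pos - pad8(length(body))
      body <- tryCatch(
        memDecompress(body, type = "gzip"),
        error = function(e) stop(
          "compressed MAT-5 element could not be inflated; ",
          "re-save the file without compression", call. = FALSE))
      inner <- mat5_read_element(body, 1L)
      type <- inner$type
      body <- inner$data
    }
    if (type != MI_MATRIX) next
    v <- mat5_parse_matrix(body)
    if (!is.null(v)) out[[v$name]] <- v$value
  }
  out
}

# read one tagged data element starting at pos; handles the small-element form
mat5_read_element <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 3L)], "integer", n = 1L, size = 4L,
                 endian = "little")
  small_size <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small_size != 0L) {
    type <- bitwAnd(tag, 0xFFFFL)
    data <- buf[(pos + 4L):(pos + 3L + small_size)]
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", n = 1L, size = 4L,
                    endian = "little")
    data <- if (size > 0L) buf[(pos + 8L):(pos + 7L + size)] else raw()
    list(type = tag, data = data, next_pos = pos + 8L + size + pad8(size))
  }
}

mat5_parse_matrix <- function(body) {
  flags <- mat5_read_element(body, 1L)
  class_id <- as.integer(flags$data[1L])
  dims_el <- mat5_read_element(body, flags$next_pos)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) %/% 4L,
                  size = 4L, endian = "little")
  name_el <- mat5_read_element(body, dims_el$next_pos)
  name <- rawToChar(name_el$data)
  data_el <- mat5_read_element(body, name_el$next_pos)
  if (class_id == MX_CHAR) {
    codes <- mat5_decode_numeric(data_el)
    return(list(name = name, value = intToUtf8(as.integer(codes))))
  }
  if (!class_id %in% MX_NUMERIC_CLASSES) return(NULL)
  vals <- mat5_decode_numeric(data_el)
  if (length(vals) != prod(dims)) {
    stop(sprintf("MAT-5 variable '%s': %d values for dims [%s]", name,
                 length(vals), paste(dims, collapse = ", ")), call. = FALSE)
  }
  dim(vals) <- dims
  list(name = name, value = vals)
}

mat5_decode_numeric <- function(el) {
  d <- el$data
  switch(as.character(el$type),
    "1" = as.double(readBin(d, "integer", n = length(d), size = 1L,
                            signed = TRUE)),
    "2" = as.double(readBin(d, "integer", n = length(d), size = 1L,
                            signed = FALSE)),
    "3" = as.double(readBin(d, "integer", n = length(d) %/% 2L, size = 2L,
                            signed = TRUE, endian = "little")),
    "4" = as.double(readBin(d, "integer", n = length(d) %/% 2L, size = 2L,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(d, "integer", n = length(d) %/% 4L, size = 4L,
                            endian = "little")),
    "6" = {
      v <- readBin(d, "integer", n = length(d) %/% 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    "7" = readBin(d, "double", n = length(d) %/% 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(d, "double", n = length(d) %/% 8L, size = 8L,
                  endian = "little"),
    stop("unsupported MAT-5 storage type ", el$type, call. = FALSE)
  )
}
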