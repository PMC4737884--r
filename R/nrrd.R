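# Minimal NRRD volume I/O (detached headers are not supported; encodings:
# ascii and raw little-endian). Covers what the pipeline writes: 3D integer
# label atlases and float density/q maps with spacing metadata in um.

#' Write a 3D array as an NRRD volume
#'
#' @param x 3D numeric or integer array.
#' @param path output file.
#' @param spacing micrometres per voxel, scalar or length 3.
#' @param encoding `"ascii"` (default; text, portable) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing = c(1, 1, 1), encoding = "ascii") {
  stopifnot(length(dim(x)) == 3, encoding %in% c("ascii", "raw"))
  spacing <- rep_len(as.numeric(spacing), 3)
  type <- if (is.integer(x)) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste("type:", type),
           "dimension: 3",
           paste("sizes:", paste(dim(x), collapse = " ")),
           paste("spacings:", paste(format(spacing, scientific = FALSE),
                                    collapse = " ")),
           "space units: \"um\" \"um\" \"um\"",
           paste("encoding:", encoding),
           if (encoding == "raw") "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(x), digits = 17, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  } else {
    writeBin(as.vector(x), con, size = if (type == "int32") 4L else 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read an NRRD volume written by [write_nrrd()]
#'
#' @param path NRRD file with attached header, ascii or raw-little-endian
#'   encoding.
#' @return list: `data` (array), `spacing` (numeric), `type` (character).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else rep(1, length(sizes))
  int_types <- c("int", "int32", "signed int", "int32_t", "uchar", "short")
  if (enc %in% c("ascii", "txt", "text")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    is_int <- type %in% int_types
    sz <- switch(type, uchar = 1L, short = 2L, int = 4L, int32 = 4L,
                 `int32_t` = 4L, float = 4L, double = 8L,
                 stop("unsupported raw type: ", type))
    vals <- readBin(con, what = if (is_int) integer() else double(),
                    n = n, size = sz,
                    endian = if (identical(fields$endian, "big")) "big" else "little")
  } else stop("unsupported encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  if (type %in% int_types) vals <- as.integer(round(vals))
  list(data = array(vals, dim = sizes), spacing = spacing, type = type)
}
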