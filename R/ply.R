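# PLY reader/writer. Supports the two dialects common among scanning and
# reconstruction tools: "format ascii 1.0" and "format binary_little_endian
# 1.0". Vertices need float/double x,y,z; optional uchar red,green,blue is
# mapped to colors in [0,1]. Faces and other elements are ignored on read.

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw_block, offset, size, type, n, stride) {
  # Extract one interleaved property column out of a raw vertex block.
  idx <- outer(seq_len(size) + offset, (seq_len(n) - 1L) * stride, `+`)
  bytes <- raw_block[as.vector(idx)]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double"
          else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  readBin(bytes, what = what, n = n, size = size, signed = if (size < 4) signed else TRUE,
          endian = "little")
}

#' Read a point cloud from a PLY file
#'
#' @param path path to an ASCII or binary-little-endian PLY file containing a
#'   vertex element with float (or double) `x`, `y`, `z` properties and,
#'   optionally, uchar `red`, `green`, `blue`.
#' @return a [point_cloud()]; colors are populated iff the file declares
#'   red/green/blue.
#' @seealso [write_ply()]
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("malformed PLY header: first line must be 'ply', got '", magic, "'")
  format <- NULL
  elements <- list()   # list of list(name, count, props = data.frame(name,type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header: end of file before 'end_header'")
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      if (length(tok) < 2L) stop("malformed PLY header line: '", line, "'")
      format <- tok[2]
      if (format == "binary_big_endian")
        stop("binary_big_endian PLY is not supported; re-export as ascii or binary_little_endian")
      if (!format %in% c("ascii", "binary_little_endian"))
        stop("malformed PLY header line: '", line, "'")
    } else if (tok[1] == "element") {
      if (length(tok) != 3L || is.na(suppressWarnings(as.integer(tok[3]))))
        stop("malformed PLY header line: '", line, "'")
      cur <- length(elements) + 1L
      elements[[cur]] <- list(name = tok[2], count = as.integer(tok[3]),
                              props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before any element: '", line, "'")
      if (tok[2] == "list") {
        if (length(tok) != 5L) stop("malformed PLY header line: '", line, "'")
        elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <-
          list(name = tok[5], type = "list", count_type = tok[3], item_type = tok[4])
      } else {
        if (length(tok) != 3L || !tok[2] %in% names(.ply_type_size))
          stop("malformed PLY header line: '", line, "'")
        elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <-
          list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop("malformed PLY header line: '", line, "'")
    }
  }
  if (is.null(format)) stop("malformed PLY header: missing 'format' line")
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))
  if (length(vi) != 1L) stop("PLY schema error: file must declare exactly one 'vertex' element")
  vertex <- elements[[vi]]
  pnames <- vapply(vertex$props, `[[`, character(1), "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("PLY schema error: vertex element lacks x/y/z properties")
  has_rgb <- all(c("red", "green", "blue") %in% pnames)
  n <- vertex$count

  if (format == "ascii") {
    rows <- readLines(con)
    rows <- rows[nzchar(trimws(rows))]
    # vertex rows of the first element follow immediately; elements are in order
    skip <- 0L
    if (vi > 1L) skip <- sum(vapply(elements[seq_len(vi - 1L)], `[[`, integer(1), "count"))
    if (length(rows) < skip + n) stop("malformed PLY: fewer data rows than declared vertices")
    vrows <- rows[seq_len(n) + skip]
    if (any(vapply(vertex$props, function(p) p$type == "list", logical(1))))
      stop("PLY schema error: list property inside vertex element is not supported")
    vals <- utils::read.table(text = vrows, col.names = pnames,
                              colClasses = "numeric")
    pts <- as.matrix(vals[, c("x", "y", "z"), drop = FALSE])
    cols <- if (has_rgb) as.matrix(vals[, c("red", "green", "blue")]) / 255 else NULL
  } else {
    if (vi != 1L) stop("binary PLY with a non-leading vertex element is not supported")
    types <- vapply(vertex$props, `[[`, character(1), "type")
    if (any(types == "list"))
      stop("PLY schema error: list property inside vertex element is not supported")
    sizes <- .ply_type_size[types]
    stride <- sum(sizes)
    offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
    raw_block <- readBin(con, "raw", n = as.numeric(stride) * n)
    if (length(raw_block) < stride * n) stop("malformed PLY: truncated binary vertex data")
    get <- function(name) {
      j <- match(name, pnames)
      .ply_read_scalar(raw_block, offsets[j], sizes[j], types[j], n, stride)
    }
    if (n == 0L) {
      pts <- matrix(numeric(0), ncol = 3)
      cols <- if (has_rgb) matrix(numeric(0), ncol = 3) else NULL
    } else {
      pts <- cbind(get("x"), get("y"), get("z"))
      cols <- if (has_rgb) cbind(get("red"), get("green"), get("blue")) / 255 else NULL
    }
  }
  point_cloud(pts, colors = cols)
}

#' Write a point cloud to a PLY file
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly. Coordinates are stored as float32 and colors,
#'   when present, as uchar 0-255.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  stopifnot(is_point_cloud(cloud))
  n <- n_points(cloud)
  has_rgb <- !is.null(cloud$colors)
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment written by cowmorph",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_rgb) c("property uchar red", "property uchar green", "property uchar blue"),
    "end_header")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0L) return(invisible(path))
  rgb255 <- if (has_rgb) round(cloud$colors * 255) else NULL
  if (binary) {
    xyz <- t(cloud$points)
    if (has_rgb) {
      # interleave: 12 bytes float xyz + 3 bytes rgb per vertex
      fbytes <- writeBin(as.vector(xyz), raw(), size = 4, endian = "little")
      fmat <- matrix(fbytes, nrow = 12)
      cmat <- matrix(as.raw(t(rgb255)), nrow = 3)
      writeBin(as.vector(rbind(fmat, cmat)), con)
    } else {
      writeBin(as.vector(xyz), con, size = 4, endian = "little")
    }
  } else {
    coord <- formatC(cloud$points, format = "g", digits = 9)
    rows <- paste(coord[, 1], coord[, 2], coord[, 3])
    if (has_rgb)
      rows <- paste(rows, rgb255[, 1], rgb255[, 2], rgb255[, 3])
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
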