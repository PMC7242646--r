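#' Colored 3D point cloud of a single plant
#'
#' Container for the raw 3D representation of one potted plant as produced by
#' multi-view structure-from-motion reconstruction: an N x 3 matrix of XYZ
#' coordinates (arbitrary length units; millimetres by convention throughout
#' this package) together with an N x 3 matrix of 8-bit RGB colors.
#'
#' @param positions Numeric matrix (or data frame) with N rows and 3 columns
#'   of finite XYZ coordinates.
#' @param colors Integer matrix with N rows and 3 columns (r, g, b), each
#'   value in \code{[0, 255]}.
#' @return An object of class \code{colored_point_cloud}: a list with
#'   elements \code{positions} (double matrix) and \code{colors}
#'   (integer matrix).
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3),
#'                   matrix(120L, 10, 3))
#' pc
#' @export
point_cloud <- function(positions, colors) {
  positions <- as.matrix(positions)
  colors <- as.matrix(colors)
  if (length(positions) == 0L) positions <- matrix(numeric(0), 0L, 3L)
  if (length(colors) == 0L) colors <- matrix(integer(0), 0L, 3L)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop_field("positions", "must have 3 columns")
  if (ncol(colors) != 3L) stop_field("colors", "must have 3 columns")
  if (nrow(positions) != nrow(colors))
    stop_field("colors", "must have one row per point")
  if (nrow(positions) > 0L && !all(is.finite(positions)))
    stop_field("positions", "must be finite")
  if (nrow(colors) > 0L) {
    if (anyNA(colors) || any(colors < 0) || any(colors > 255))
      stop_field("colors", "values must lie in [0, 255]")
    if (any(colors != round(colors)))
      stop_field("colors", "values must be integers")
  }
  storage.mode(colors) <- "integer"
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  structure(list(positions = positions, colors = colors),
            class = "colored_point_cloud")
}

#' Number of points in a cloud
#' @param cloud A \code{colored_point_cloud}.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$positions)

#' @export
print.colored_point_cloud <- function(x, ...) {
  cat(sprintf("Colored point cloud: %d points\n", n_points(x)))
  if (n_points(x) > 0L) {
    r <- apply(x$positions, 2L, range)
    cat(sprintf("  extent  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f]\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' Subset a point cloud by point index
#' @param cloud A \code{colored_point_cloud}.
#' @param idx Integer or logical index vector.
#' @return A new \code{colored_point_cloud} with the selected points, in the
#'   order given by \code{idx}.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$positions[idx, , drop = FALSE],
              cloud$colors[idx, , drop = FALSE])
}

#' Read a colored point cloud from disk
#'
#' Supports PLY (ASCII and binary little-endian, with \code{x/y/z} float or
#' double properties and \code{red/green/blue} uchar properties) and
#' whitespace-delimited XYZRGB text (six columns: x y z r g b).
#'
#' @param path Path to the file.
#' @param format \code{"ply"} or \code{"xyzrgb"}; default guesses from the
#'   file extension.
#' @return A \code{colored_point_cloud}.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyzrgb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, ply = read_ply(path), xyzrgb = read_xyzrgb(path))
}

#' Write a colored point cloud to disk
#'
#' @param cloud A \code{colored_point_cloud}.
#' @param path Output path.
#' @param format \code{"ply"} or \code{"xyzrgb"}.
#' @param binary For PLY: write \code{binary_little_endian} instead of ASCII.
#' @param digits Decimal digits for ASCII coordinate output.
#' @return \code{path}, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("ply", "xyzrgb"),
                        binary = FALSE, digits = 6L) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "colored_point_cloud"))
  if (format == "ply") write_ply(cloud, path, binary = binary, digits = digits)
  else write_xyzrgb(cloud, path, digits = digits)
  invisible(path)
}

read_xyzrgb <- function(path) {
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("malformed XYZRGB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dat) == 0L) return(point_cloud(matrix(0, 0, 3), matrix(0L, 0, 3)))
  if (ncol(dat) != 6L)
    stop("XYZRGB file must have 6 columns (x y z r g b), got ",
         ncol(dat), call. = FALSE)
  point_cloud(as.matrix(dat[, 1:3]), as.matrix(dat[, 4:6]))
}

write_xyzrgb <- function(cloud, path, digits = 6L) {
  df <- data.frame(round(cloud$positions, digits), cloud$colors)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

# -- PLY ---------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply"))
    stop("malformed PLY '", path, "': missing 'ply' magic line", call. = FALSE)
  fmt <- NULL; n_vertex <- NULL
  props <- character(); types <- character()
  in_vertex <- FALSE
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(ln) == 0L)
      stop("malformed PLY '", path, "': header ends before end_header (line ",
           lineno, ")", call. = FALSE)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format: ", fmt, call. = FALSE)
    } else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
      else if (as.integer(tok[3]) > 0L)
        stop("unsupported PLY element with data: ", tok[2], call. = FALSE)
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list")
        stop("unsupported list property in vertex element", call. = FALSE)
      types <- c(types, tok[2]); props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(n_vertex))
    stop("malformed PLY '", path, "': no vertex element", call. = FALSE)
  need_xyz <- c("x", "y", "z")
  need_rgb <- c("red", "green", "blue")
  if (!all(need_xyz %in% props))
    stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
  if (!all(need_rgb %in% props))
    stop("colors required: PLY vertex element lacks red/green/blue properties",
         call. = FALSE)
  if (n_vertex == 0L)
    return(point_cloud(matrix(0, 0, 3), matrix(0L, 0, 3)))

  if (fmt == "ascii") {
    dat <- tryCatch(
      utils::read.table(path, skip = lineno, nrows = n_vertex,
                        header = FALSE),
      error = function(e) stop("malformed PLY '", path, "' vertex data: ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(dat) < n_vertex)
      stop("PLY '", path, "' declares ", n_vertex, " vertices but has ",
           nrow(dat), call. = FALSE)
    vals <- as.matrix(dat)
  } else {
    sizes <- ply_type_size[types]
    if (anyNA(sizes)) stop("unknown PLY property type", call. = FALSE)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * n_vertex)
    if (length(raw) < rec * n_vertex)
      stop("PLY '", path, "': truncated binary vertex data", call. = FALSE)
    raw <- matrix(raw, nrow = rec)
    vals <- matrix(0, n_vertex, length(props))
    off <- 0L
    for (j in seq_along(props)) {
      bytes <- raw[(off + 1L):(off + sizes[j]), , drop = FALSE]
      ty <- types[j]
      vals[, j] <- if (ty %in% c("float", "float32"))
        readBin(as.vector(bytes), "double", n = n_vertex, size = 4L,
                endian = "little")
      else if (ty %in% c("double", "float64"))
        readBin(as.vector(bytes), "double", n = n_vertex, size = 8L,
                endian = "little")
      else if (ty %in% c("uchar", "uint8", "char", "int8"))
        as.integer(as.vector(bytes[1L, , drop = TRUE]))
      else
        readBin(as.vector(bytes), "integer", n = n_vertex, size = sizes[j],
                endian = "little")
      off <- off + sizes[j]
    }
  }
  colnames(vals) <- props
  point_cloud(vals[, need_xyz, drop = FALSE], vals[, need_rgb, drop = FALSE])
}

write_ply <- function(cloud, path, binary = FALSE, digits = 6L) {
  n <- n_points(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  if (!binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0L) {
      df <- data.frame(round(cloud$positions, digits), cloud$colors)
      utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0L) {
      xyz <- cloud$positions
      rgb <- cloud$colors
      for (i in seq_len(n)) {
        writeBin(as.double(xyz[i, ]), con, size = 4L, endian = "little")
        writeBin(as.raw(rgb[i, ]), con)
      }
    }
  }
  invisible(path)
}
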