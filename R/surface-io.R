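#' Read an anatomical surface from an STL or PLY file
#'
#' Auto-detects the format from the file extension and, for `.stl`, from the
#' content (binary vs ASCII). Coordinates are taken to be millimetres, the CT
#' convention: neither STL nor PLY carries units. Duplicate vertices are
#' merged when faces are present, so an STL triangle soup yields a proper
#' indexed mesh.
#'
#' @param path path to an `.stl` or `.ply` file.
#' @param label surface label, `"wall"` or `"calcification"`.
#' @param patient_id subject identifier; defaults to the file name stem.
#' @return a [surface].
#' @export
read_surface <- function(path, label = c("wall", "calcification"),
                         patient_id = NULL) {
  label <- match.arg(label)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("format error: empty file: ", path, call. = FALSE)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  geo <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("format error: unsupported extension '", ext, "' for ", path, call. = FALSE)
  )
  if (nrow(geo$points) == 0L)
    stop("empty geometry in ", path, call. = FALSE)
  if (!is.null(geo$faces)) {
    m <- merge_vertices(geo$points, geo$faces)
    geo <- m
  }
  surface(geo$points, geo$faces, patient_id = patient_id, label = label,
          source_path = normalizePath(path))
}

#' Write a surface to an STL or PLY file
#'
#' Format is chosen by extension: `.stl` (binary unless `ascii = TRUE`) or
#' `.ply` (always ASCII). Faceless point clouds can only be written to PLY;
#' STL is a triangle format.
#'
#' @param x a [surface].
#' @param path output path ending in `.stl` or `.ply`.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path, ascii = FALSE) {
  stopifnot(inherits(x, "surface"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    if (is.null(x$faces))
      stop("STL requires faces; write faceless clouds to PLY", call. = FALSE)
    if (ascii) write_stl_ascii(x$points, x$faces, path)
    else write_stl_binary(x$points, x$faces, path)
  } else if (ext == "ply") {
    write_ply_ascii(x$points, x$faces, path)
  } else {
    stop("unsupported extension '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

## ---- STL ----------------------------------------------------------------

is_binary_stl <- function(path) {
  # An ASCII STL starts with "solid", but some binary exporters do too, so
  # cross-check the declared triangle count against the file size.
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) return(TRUE)
  !identical(tolower(rawToChar(head[1:5])), "solid")
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0)
    stop("format error: corrupt binary STL header in ", path, call. = FALSE)
  rec <- readBin(con, "raw", n = 50 * ntri)
  if (length(rec) != 50 * ntri)
    stop("format error: truncated binary STL: ", path, call. = FALSE)
  rec <- matrix(rec, nrow = 50)
  # each 50-byte record: normal (12) + 3 vertices (36) + attribute (2)
  vbytes <- rec[13:48, , drop = FALSE]
  vals <- readBin(as.vector(vbytes), "double", n = 9 * ntri, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  list(points = pts, faces = faces)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("format error: not a valid ASCII STL: ", path, call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(is.na(nums)))
    stop("format error: non-numeric vertex in ASCII STL: ", path, call. = FALSE)
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  list(points = nums, faces = faces)
}

write_stl_binary <- function(points, faces, path) {
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "binary STL written by vcohort"))[1:80]
  writeBin(hdr, con)
  ntri <- nrow(faces)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  attrib <- as.raw(c(0, 0))
  for (i in seq_len(ntri)) {
    v <- points[faces[i, ], , drop = FALSE]
    n <- tri_normal(v)
    writeBin(as.numeric(c(n, t(v))), con, size = 4, endian = "little")
    writeBin(attrib, con)
  }
  invisible(path)
}

write_stl_ascii <- function(points, faces, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid vcohort", con)
  for (i in seq_len(nrow(faces))) {
    v <- points[faces[i, ], , drop = FALSE]
    n <- tri_normal(v)
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid vcohort", con)
  invisible(path)
}

tri_normal <- function(v) {
  n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
  len <- sqrt(sum(n^2))
  if (len < .Machine$double.eps) c(0, 0, 0) else n / len
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  # header is always ASCII lines
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L)
      stop("format error: PLY header never ends: ", path, call. = FALSE)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500)
      stop("format error: oversized PLY header: ", path, call. = FALSE)
  }
  if (!identical(trimws(header[1]), "ply"))
    stop("format error: missing 'ply' magic: ", path, call. = FALSE)
  fmt <- grep("^format ", header, value = TRUE)[1]
  nvert <- as.integer(sub("^element vertex\\s+", "",
                          grep("^element vertex ", header, value = TRUE)[1]))
  fline <- grep("^element face ", header, value = TRUE)
  nface <- if (length(fline)) as.integer(sub("^element face\\s+", "", fline[1])) else 0L
  if (is.na(nvert))
    stop("format error: PLY without vertex element: ", path, call. = FALSE)
  # vertex property names, in order
  elems <- sub("^element\\s+(\\w+).*", "\\1", grep("^element ", header, value = TRUE))
  prop_lines <- grep("^property ", header)
  elem_lines <- grep("^element ", header)
  vert_elem_line <- elem_lines[elems == "vertex"][1]
  next_elem <- elem_lines[elem_lines > vert_elem_line]
  vert_props <- prop_lines[prop_lines > vert_elem_line &
                             (if (length(next_elem)) prop_lines < next_elem[1] else TRUE)]
  pnames <- vapply(strsplit(header[vert_props], "\\s+"), function(f) f[3], "")
  ptypes <- vapply(strsplit(header[vert_props], "\\s+"), function(f) f[2], "")
  xyz <- match(c("x", "y", "z"), pnames)
  if (any(is.na(xyz)))
    stop("format error: PLY vertex element lacks x/y/z: ", path, call. = FALSE)

  if (grepl("ascii", fmt)) {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vl <- strsplit(trimws(body[seq_len(nvert)]), "\\s+")
    pts <- t(vapply(vl, function(f) as.numeric(f[xyz]), numeric(3)))
    faces <- NULL
    if (nface > 0L) {
      fl <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
      faces <- do.call(rbind, lapply(fl, function(f) {
        k <- as.integer(f[1]); idx <- as.integer(f[1 + seq_len(k)])
        if (k == 3L) matrix(idx + 1L, 1) else
          cbind(idx[1] + 1L, idx[seq_len(k - 2) + 1] + 1L, idx[seq_len(k - 2) + 2] + 1L)
      }))
    }
    list(points = pts, faces = faces)
  } else if (grepl("binary_little_endian", fmt)) {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
               ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
               int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
               double = 8L, float64 = 8L)
    psz <- sizes[ptypes]
    if (any(is.na(psz)))
      stop("format error: unsupported PLY property type in ", path, call. = FALSE)
    pts <- matrix(NA_real_, nvert, 3)
    off <- cumsum(c(0, psz))[xyz]
    rowbytes <- sum(psz)
    raw <- readBin(con, "raw", n = rowbytes * nvert)
    for (j in 1:3) {
      typ <- ptypes[xyz[j]]
      sz <- sizes[typ]
      idx <- as.vector(outer(seq_len(sz), (seq_len(nvert) - 1) * rowbytes + off[j], "+"))
      pts[, j] <- readBin(raw[idx], "double", n = nvert, size = sz, endian = "little")
    }
    # faces in binary PLY are rarely needed here; read triangles if present
    faces <- NULL
    if (nface > 0L) {
      faces <- matrix(NA_integer_, nface, 3)
      for (i in seq_len(nface)) {
        k <- readBin(con, "integer", 1, size = 1, signed = FALSE)
        idx <- readBin(con, "integer", k, size = 4, endian = "little")
        if (k != 3L) stop("format error: non-triangular binary PLY face", call. = FALSE)
        faces[i, ] <- idx + 1L
      }
    }
    list(points = pts, faces = faces)
  } else {
    stop("format error: unsupported PLY format line: ", fmt, call. = FALSE)
  }
}

write_ply_ascii <- function(points, faces, path) {
  con <- file(path, "w"); on.exit(close(con))
  nf <- if (is.null(faces)) 0L else nrow(faces)
  writeLines(c("ply", "format ascii 1.0",
               "comment written by vcohort",
               sprintf("element vertex %d", nrow(points)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", points[, 1], points[, 2], points[, 3]), con)
  if (nf > 0L)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}
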