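#' Load a segmented surface mesh
#'
#' Reads a bone or tumor surface mesh from STL (binary or ASCII) or PLY
#' (ASCII or binary little-endian), merges duplicate vertices, drops
#' degenerate faces, orients faces outward, and enforces watertightness.
#' Coordinates are taken to be millimeters in the scanner/base frame shared
#' by the bone and tumor segmentations.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @param label `"bone"` or `"tumor"`.
#' @return A [surface_mesh()].
#' @export
load_mesh <- function(path, label = c("bone", "tumor")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unknown mesh format '.", ext, "' (expected .stl or .ply)")
  )
  surface_mesh(raw$vertices, raw$faces, label = label)
}

#' Write a surface mesh
#'
#' Writes STL (binary by default, or ASCII) or ASCII PLY, chosen from the
#' file extension.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @param ascii write the ASCII variant of the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
    ply = write_ply_ascii(mesh, path),
    stop("unknown mesh format '.", ext, "'")
  )
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary iff the triangle count matches the file size exactly
  !is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  body <- readBin(con, "raw", 50 * ntri)
  keep <- rep(c(rep(TRUE, 48), FALSE, FALSE), ntri)
  vals <- readBin(body[keep], "numeric", n = 12 * ntri, size = 4,
                  endian = "little")
  rec <- matrix(vals, ncol = 12, byrow = TRUE)   # normal, v1, v2, v3
  verts <- rbind(rec[, 4:6], rec[, 7:9], rec[, 10:12])
  ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  list(vertices = verts[ord, , drop = FALSE],
       faces = matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(tok) as.numeric(tok[2:4]))
  verts <- do.call(rbind, nums)
  list(vertices = verts,
       faces = matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE))
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  v <- mesh$vertices
  n <- face_normals(mesh)
  block <- cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  f <- mesh$faces
  v <- mesh$vertices
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  n <- rowwise_cross(v[f[, 2], , drop = FALSE] - a,
                     v[f[, 3], , drop = FALSE] - a)
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

# ---- PLY ----------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  size <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "numeric", 1, size = size, endian = "little")
  } else {
    readBin(con, "integer", 1, size = size, endian = "little",
            signed = !(size < 4 && grepl("^u", type)))
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("malformed PLY: no end_header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1]] <-
        if (tok[2] == "list") {
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
        } else {
          list(name = tok[3], list = FALSE, type = tok[2])
        }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("PLY without vertex/face elements is not supported")
  }
  if (fmt == "ascii") {
    read_ply_ascii_body(con, elements)
  } else if (fmt == "binary_little_endian") {
    read_ply_binary_body(con, elements)
  } else {
    stop("unsupported PLY format: ", fmt)
  }
}

read_ply_ascii_body <- function(con, elements) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  nv <- elements$vertex$count
  nf <- elements$face$count
  vprops <- vapply(elements$vertex$props, `[[`, "", "name")
  vtab <- do.call(rbind, lapply(strsplit(trimws(lines[seq_len(nv)]), "\\s+"),
                                as.numeric))
  xyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z")
  flines <- strsplit(trimws(lines[nv + seq_len(nf)]), "\\s+")
  faces <- lapply(flines, function(tok) {
    n <- as.integer(tok[1])
    as.integer(tok[1 + seq_len(n)]) + 1L
  })
  list(vertices = vtab[, xyz, drop = FALSE],
       faces = triangulate_fans(faces))
}

read_ply_binary_body <- function(con, elements) {
  ve <- elements$vertex
  vprops <- vapply(ve$props, `[[`, "", "name")
  vtypes <- vapply(ve$props, `[[`, "", "type")
  if (any(vapply(ve$props, `[[`, TRUE, "list"))) {
    stop("list properties on PLY vertices are not supported")
  }
  sizes <- ply_type_size[vtypes]
  stride <- sum(sizes)
  body <- readBin(con, "raw", ve$count * stride)
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  vtab <- matrix(0, ve$count, length(vprops))
  base <- rep(seq(0L, by = stride, length.out = ve$count), each = 1L)
  for (j in seq_along(vprops)) {
    sel <- as.vector(outer(seq_len(sizes[j]), base + offs[j], `+`))
    vtab[, j] <- if (vtypes[j] %in% c("float", "float32", "double", "float64")) {
      readBin(body[sel], "numeric", ve$count, size = sizes[j], endian = "little")
    } else {
      readBin(body[sel], "integer", ve$count, size = sizes[j], endian = "little")
    }
  }
  xyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z")
  fe <- elements$face
  lp <- fe$props[[1]]
  if (!lp$list) stop("PLY face element must be a list property")
  faces <- vector("list", fe$count)
  for (i in seq_len(fe$count)) {
    n <- ply_read_scalar(con, lp$count_type)
    idx <- readBin(con, "integer", n, size = ply_type_size[[lp$type]],
                   endian = "little")
    faces[[i]] <- idx + 1L
  }
  list(vertices = vtab[, xyz, drop = FALSE],
       faces = triangulate_fans(faces))
}

# fan-triangulate polygonal faces (convex polygons assumed)
triangulate_fans <- function(faces) {
  tri <- lapply(faces, function(ix) {
    if (length(ix) < 3) return(NULL)
    cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])
  })
  do.call(rbind, tri)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
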