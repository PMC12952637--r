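#' Construct a seafloor mesh
#'
#' A `seafloor_mesh` is a triangulated surface in a metric frame: x and y are
#' horizontal metres, z is elevation in metres (negative below the sea-surface
#' datum, so depth = -z). Faces are optional; a point cloud is a mesh with
#' zero faces.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in metres.
#' @param faces integer matrix (m x 3) of 1-based vertex indices, or `NULL`.
#' @return An object of class `seafloor_mesh`: a list with elements
#'   `vertices` (double matrix) and `faces` (integer matrix, possibly 0-row).
#' @examples
#' m <- seafloor_mesh(rbind(c(0, 0, -5), c(1, 0, -5), c(0, 1, -5)),
#'                    rbind(c(1, 2, 3)))
#' m
#' @export
seafloor_mesh <- function(vertices, faces = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stop("vertices must have three columns (x, y, z)")
  storage.mode(vertices) <- "double"
  if (nrow(vertices) == 0L) stop("mesh has zero vertices")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), nrow = 0L, ncol = 3L)
  } else {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L) stop("faces must be triangles (three indices per row)")
    storage.mode(faces) <- "integer"
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face references an invalid vertex index")
    }
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "seafloor_mesh")
}

#' @export
print.seafloor_mesh <- function(x, ...) {
  cat(sprintf("seafloor_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("  x: [%.3f, %.3f] m  y: [%.3f, %.3f] m  z: [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  g <- attr(x, "georeference")
  if (!is.null(g)) {
    cat(sprintf("  georeferenced: scale %.6g, depth RMSE %.3g m\n",
                g$scale, g$depth_rmse))
  }
  invisible(x)
}

.mesh_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(tolower(format), c("ply", "obj")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj")) ext else
    stop("cannot infer mesh format from extension '", ext, "'; pass format=")
}

#' Read a triangulated mesh from PLY or OBJ
#'
#' PLY is supported in ascii and binary-little-endian flavours; OBJ reading is
#' limited to `v`/`f` records (materials, normals and texture coordinates are
#' ignored). Vertex order is preserved from the file.
#'
#' @param path path to the mesh file.
#' @param format `"ply"` or `"obj"`; inferred from the extension by default.
#' @return A [seafloor_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- .mesh_format(path, format)
  if (format == "ply") .read_ply(path) else .read_obj(path)
}

#' Write a mesh to PLY or OBJ
#'
#' Ascii PLY/OBJ store coordinates as full-precision doubles;
#' binary-little-endian PLY stores them as float32 (the conventional PLY
#' vertex type), so one binary round trip quantises to float32 and is exact
#' thereafter.
#'
#' @param mesh a [seafloor_mesh()].
#' @param path output path.
#' @param format `"ply"` or `"obj"`; inferred from the extension by default.
#' @param binary write binary-little-endian PLY instead of ascii (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  format <- .mesh_format(path, format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (format == "ply") .write_ply(mesh, path, binary) else .write_obj(mesh, path)
  invisible(path)
}

.ply_types <- list(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.ply_read_prop <- function(raw_block, n, stride, offset, type) {
  size <- .ply_types[[type]]
  byte_mat <- matrix(raw_block, nrow = stride)
  bytes <- byte_mat[offset + seq_len(size), , drop = FALSE]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  # uint32 read as signed int32; vertex counts never approach 2^31 here
  if (type %in% c("uint", "uint32")) signed <- TRUE
  readBin(as.vector(bytes), what = what, n = n, size = size,
          signed = if (size < 4L) signed else TRUE, endian = "little")
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("malformed PLY: missing 'ply' magic")
  fmt <- NULL
  elements <- list()  # list of list(name, count, props = data.frame(name,type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY: header not terminated")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY: property before element")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("malformed PLY: unrecognised header line '", line, "'")
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt %||% "<missing>")
  }
  ve <- elements[["vertex"]]
  if (is.null(ve)) stop("malformed PLY: no vertex element")
  if (ve$count == 0L) stop("mesh has zero vertices")
  pnames <- vapply(ve$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames)) stop("malformed PLY: vertex lacks x/y/z")
  if (any(vapply(ve$props, function(p) !is.null(p$list_count_type), TRUE))) {
    stop("unsupported PLY: list property in vertex element")
  }
  fe <- elements[["face"]]
  nface <- if (is.null(fe)) 0L else fe$count

  if (fmt == "ascii") {
    vals <- scan(con, what = double(), n = ve$count * length(pnames), quiet = TRUE)
    if (length(vals) < ve$count * length(pnames)) stop("malformed PLY: truncated vertex data")
    vm <- matrix(vals, ncol = length(pnames), byrow = TRUE)
    V <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    F <- NULL
    if (nface > 0L) {
      lines <- readLines(con)
      lines <- lines[nzchar(trimws(lines))][seq_len(nface)]
      if (anyNA(lines)) stop("malformed PLY: truncated face data")
      F <- t(vapply(strsplit(trimws(lines), "\\s+"), function(tk) {
        cnt <- as.integer(tk[1])
        if (cnt != 3L) stop("unsupported PLY: non-triangular face")
        as.integer(tk[2:4])
      }, integer(3)))
    }
  } else {
    sizes <- vapply(ve$props, function(p) .ply_types[[p$type]], 0L)
    stride <- sum(sizes)
    raw_block <- readBin(con, "raw", n = ve$count * stride)
    if (length(raw_block) < ve$count * stride) stop("malformed PLY: truncated vertex data")
    offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
    V <- sapply(c("x", "y", "z"), function(nm) {
      i <- match(nm, pnames)
      .ply_read_prop(raw_block, ve$count, stride, offsets[i], ve$props[[i]]$type)
    })
    V <- matrix(V, ncol = 3L)
    F <- NULL
    if (nface > 0L) {
      raw_faces <- readBin(con, "raw", n = nface * 13L + 64L)
      # fast path: all faces are triangles with uchar count + 3 x int32
      if (length(raw_faces) >= nface * 13L &&
          all(raw_faces[seq(1L, by = 13L, length.out = nface)] == as.raw(3L))) {
        bm <- matrix(raw_faces[seq_len(nface * 13L)], nrow = 13L)
        F <- sapply(1:3, function(k) {
          readBin(as.vector(bm[(2L + (k - 1L) * 4L):(1L + k * 4L), , drop = FALSE]),
                  "integer", n = nface, size = 4L, endian = "little")
        })
        F <- matrix(F, ncol = 3L)
      } else {
        stop("unsupported PLY: non-triangular or non-standard binary face records")
      }
    }
  }
  if (!is.null(F)) F <- F + 1L  # PLY is 0-based
  seafloor_mesh(V, F)
}

.write_ply <- function(mesh, path, binary) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c("ply", "format binary_little_endian 1.0",
                sprintf("element vertex %d", n),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", m),
                "property list uchar int vertex_indices", "end_header")
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    if (m > 0L) {
      f0 <- t(mesh$faces) - 1L
      for (j in seq_len(m)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[, j]), con, size = 4L, endian = "little")
      }
    }
  } else {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", n),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", m),
                "property list uchar int vertex_indices", "end_header")
    vlines <- sprintf("%.17g %.17g %.17g",
                      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
    flines <- if (m > 0L) {
      sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
              mesh$faces[, 3] - 1L)
    } else character(0)
    writeLines(c(header, vlines, flines), path)
  }
  invisible(path)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("mesh has zero vertices")
  V <- t(vapply(strsplit(vlines, "\\s+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(v)) stop("malformed OBJ vertex line")
    v
  }, double(3)))
  F <- NULL
  if (length(flines) > 0L) {
    F <- t(vapply(strsplit(flines, "\\s+"), function(tk) {
      if (length(tk) != 4L) stop("unsupported OBJ: non-triangular face")
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tk[2:4])))
      if (anyNA(idx)) stop("malformed OBJ face line")
      idx
    }, integer(3)))
  }
  seafloor_mesh(V, F)
}

.write_obj <- function(mesh, path) {
  vlines <- sprintf("v %.17g %.17g %.17g",
                    mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  flines <- if (nrow(mesh$faces) > 0L) {
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  } else character(0)
  writeLines(c(vlines, flines), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
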