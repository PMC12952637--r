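#' Indicator configuration
#'
#' Parameters of the two geomorphic indicators. `rh_radius` is the 3D
#' neighbourhood radius for relative height (m); `sc_window` is the side of
#' the box-counting window centred on the target vertex (m); `sc_cell` is the
#' box-counting cell side (m). The window must split into an integer number
#' of cells per axis (default 3.0 / 0.5 = 6, i.e. 216 cells in 3D).
#'
#' @param rh_radius neighbourhood radius in metres (default 1.5).
#' @param sc_window box-counting window side in metres (default 3.0).
#' @param sc_cell box-counting cell side in metres (default 0.5).
#' @return list of class `indicator_config`.
#' @export
indicator_config <- function(rh_radius = 1.5, sc_window = 3.0, sc_cell = 0.5) {
  stopifnot(rh_radius > 0, sc_window > 0, sc_cell > 0)
  m <- sc_window / sc_cell
  if (abs(m - round(m)) > 1e-9 || round(m) < 1) {
    stop("sc_window must be a positive integer multiple of sc_cell")
  }
  structure(list(rh_radius = rh_radius, sc_window = sc_window,
                 sc_cell = sc_cell, cells_per_axis = as.integer(round(m))),
            class = "indicator_config")
}

.check_vertex <- function(mesh, vertex) {
  if (!is.numeric(vertex) || length(vertex) != 1L || is.na(vertex) ||
      vertex < 1 || vertex > nrow(mesh$vertices) || vertex != round(vertex)) {
    stop("invalid vertex index: ", vertex)
  }
  as.integer(vertex)
}

#' Relative height of a vertex
#'
#' Height of the vertex above the deepest vertex within a fixed-radius 3D
#' Euclidean neighbourhood (the vertex itself included, so the result is
#' always >= 0 and equals 0 when the vertex is co-deepest).
#'
#' @param mesh a [seafloor_mesh()].
#' @param vertex vertex index (1-based). May be a vector.
#' @param config an [indicator_config()].
#' @return numeric vector of relative heights in metres.
#' @export
relative_height <- function(mesh, vertex, config = indicator_config()) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  V <- mesh$vertices
  r <- config$rh_radius
  vapply(vertex, function(i) {
    i <- .check_vertex(mesh, i)
    p <- V[i, ]
    box <- abs(V[, 1] - p[1]) <= r & abs(V[, 2] - p[2]) <= r &
      abs(V[, 3] - p[3]) <= r
    W <- V[box, , drop = FALSE]
    d2 <- (W[, 1] - p[1])^2 + (W[, 2] - p[2])^2 + (W[, 3] - p[3])^2
    p[3] - min(W[d2 <= r^2, 3])
  }, numeric(1))
}

#' Box-counting occupancy fraction of a point set
#'
#' The primitive behind surface complexity: an axis-aligned square (2D) or
#' cube (3D) of side `window` centred on `center` is split into
#' `(window/cell)^d` half-open cells `[a, a + cell)` anchored at the window's
#' minimum corner, and the fraction of cells containing at least one point is
#' returned. Points on the window's upper boundary are excluded by the
#' half-open convention.
#'
#' @param points numeric matrix with 2 or 3 columns.
#' @param center numeric vector matching `ncol(points)`.
#' @param window window side in metres.
#' @param cell cell side in metres.
#' @return fraction of occupied cells in `(0, 1]` (0 if no point is inside).
#' @export
box_count_fraction <- function(points, center, window = 3.0, cell = 0.5) {
  points <- as.matrix(points)
  d <- ncol(points)
  stopifnot(d %in% c(2L, 3L), length(center) == d)
  m <- window / cell
  if (abs(m - round(m)) > 1e-9) stop("window must be an integer multiple of cell")
  m <- as.integer(round(m))
  lo <- center - window / 2
  # half-open cells [lo + g*cell, lo + (g+1)*cell): findInterval against the
  # explicit cell edges keeps boundary points consistent with that definition
  idx <- matrix(0L, nrow(points), d)
  inside <- rep(TRUE, nrow(points))
  for (k in seq_len(d)) {
    edges <- lo[k] + (0:m) * cell
    f <- findInterval(points[, k], edges)
    inside <- inside & f >= 1L & f <= m
    idx[, k] <- f - 1L
  }
  idx <- idx[inside, , drop = FALSE]
  if (nrow(idx) == 0L) return(0)
  lin <- idx[, 1]
  for (k in seq_len(d)[-1]) lin <- lin * m + idx[, k]
  length(unique(lin)) / m^d
}

#' Surface complexity of a vertex
#'
#' Box-counting occupancy of mesh vertices in a cube (default 3.0 m side,
#' 0.5 m cells, 216 cells) centred on the target vertex. The target's own
#' cell is always occupied, so valid values lie in `[1/216, 1]` with the
#' defaults. `dims = 2` reproduces the two-dimensional variant of the
#' procedure (6 x 6 = 36 cells over the horizontal window).
#'
#' @param mesh a [seafloor_mesh()].
#' @param vertex vertex index (1-based). May be a vector.
#' @param config an [indicator_config()].
#' @param dims 3 (default) for the cubic window, 2 for the planar variant
#'   (x/z in the schematic; here x/y of the projected vertices).
#' @return numeric vector of occupancy fractions.
#' @export
surface_complexity <- function(mesh, vertex, config = indicator_config(),
                               dims = 3L) {
  stopifnot(inherits(mesh, "seafloor_mesh"), dims %in% c(2L, 3L))
  V <- mesh$vertices
  vapply(vertex, function(i) {
    i <- .check_vertex(mesh, i)
    if (dims == 3L) {
      box_count_fraction(V, V[i, ], config$sc_window, config$sc_cell)
    } else {
      box_count_fraction(V[, 1:2, drop = FALSE], V[i, 1:2],
                         config$sc_window, config$sc_cell)
    }
  }, numeric(1))
}

# Point-in-convex-polygon via half-plane tests; poly rows are ordered hull
# vertices. Boundary points (within tol) count as inside.
.in_convex_poly <- function(pts, poly, tol) {
  n <- nrow(poly)
  nx <- poly[c(2:n, 1), 1] - poly[, 1]
  ny <- poly[c(2:n, 1), 2] - poly[, 2]
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    cr <- nx[i] * (pts[, 2] - poly[i, 2]) - ny[i] * (pts[, 1] - poly[i, 1])
    inside <- inside & (sgn * cr >= -tol)
  }
  inside
}

#' Edge-exclusion mask
#'
#' Indicator values are meaningless near the rim of the mapped area, where
#' the analysis window extends past the surveyed surface. A vertex is valid
#' iff its full horizontal box-counting window (side `sc_window`) lies inside
#' the mesh's horizontal footprint, taken as the 2D convex hull of the
#' projected vertices; since that window contains the 1.5 m relative-height
#' disc, one test covers both indicators.
#'
#' @param mesh a [seafloor_mesh()].
#' @param config an [indicator_config()].
#' @return logical vector, one entry per vertex (`TRUE` = valid).
#' @export
edge_mask <- function(mesh, config = indicator_config()) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  xy <- mesh$vertices[, 1:2, drop = FALSE]
  n <- nrow(xy)
  hull <- grDevices::chull(xy)
  if (length(hull) < 3L) return(rep(FALSE, n))
  poly <- xy[hull, , drop = FALSE]
  area2 <- abs(sum(poly[, 1] * poly[c(2:nrow(poly), 1), 2] -
                     poly[c(2:nrow(poly), 1), 1] * poly[, 2]))
  if (area2 < 1e-12) return(rep(FALSE, n))
  tol <- 1e-9 * max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  half <- config$sc_window / 2
  valid <- rep(TRUE, n)
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    corners <- cbind(xy[, 1] + sx * half, xy[, 2] + sy * half)
    valid <- valid & .in_convex_poly(corners, poly, tol)
  }
  valid
}

#' Boulder annotations
#'
#' One row per installed boulder: identifier, horizontal centre, footprint
#' radius and the substrate it sits on (`"sand"` or `"cobble"`).
#'
#' @param boulder_id character ids.
#' @param x_m,y_m horizontal centre coordinates (m).
#' @param radius_m footprint radius (m, > 0).
#' @param bottom_type `"sand"` or `"cobble"`.
#' @return data.frame of class `boulder_annotations`.
#' @export
boulder_annotations <- function(boulder_id, x_m, y_m, radius_m, bottom_type) {
  bottom_type <- tolower(as.character(bottom_type))
  bad <- setdiff(unique(bottom_type), c("sand", "cobble"))
  if (length(bad)) stop("unknown bottom type: ", paste(bad, collapse = ", "))
  radius_m <- as.numeric(radius_m)
  if (any(!is.finite(radius_m) | radius_m <= 0)) stop("footprint radius must be > 0")
  df <- data.frame(boulder_id = as.character(boulder_id),
                   x_m = as.numeric(x_m), y_m = as.numeric(y_m),
                   radius_m = radius_m,
                   bottom_type = factor(bottom_type, c("sand", "cobble")),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$boulder_id)) stop("duplicate boulder ids")
  class(df) <- c("boulder_annotations", "data.frame")
  df
}

#' Read / write boulder annotation CSV
#'
#' Columns: `boulder_id`, `x_m`, `y_m`, `radius_m`, `bottom_type`.
#' @param path CSV path.
#' @return [boulder_annotations()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("boulder_id", "x_m", "y_m", "radius_m", "bottom_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV missing columns: ", paste(miss, collapse = ", "))
  boulder_annotations(df$boulder_id, df$x_m, df$y_m, df$radius_m, df$bottom_type)
}

#' @rdname read_annotations
#' @param annotations a [boulder_annotations()] table.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

#' Summit vertex of a boulder
#'
#' The highest-elevation vertex whose horizontal distance to the boulder
#' centre is at most the footprint radius; ties are broken by the lowest
#' vertex index.
#'
#' @param mesh a [seafloor_mesh()].
#' @param boulder one-row [boulder_annotations()] (or a list with `x_m`,
#'   `y_m`, `radius_m`).
#' @return vertex index, or an error if the footprint contains no vertex.
#' @export
summit_vertex <- function(mesh, boulder) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  V <- mesh$vertices
  d2 <- (V[, 1] - boulder$x_m)^2 + (V[, 2] - boulder$y_m)^2
  cand <- which(d2 <= boulder$radius_m^2)
  if (length(cand) == 0L) {
    stop("empty footprint: no vertex within radius of boulder ",
         boulder$boulder_id %||% "<unnamed>")
  }
  cand[which.max(V[cand, 3])]
}

#' Per-boulder geomorphic indicators
#'
#' For each annotated boulder: locate the summit vertex, apply the edge mask
#' there, and (when valid) evaluate relative height and surface complexity at
#' the summit. Every input boulder yields exactly one output row; boulders
#' whose footprint contains no mesh vertex, or whose summit fails edge
#' exclusion, are flagged `valid = FALSE` with `NA` indicators (with a
#' warning for empty footprints).
#'
#' @param mesh a [seafloor_mesh()].
#' @param boulders a [boulder_annotations()] table.
#' @param config an [indicator_config()].
#' @return data.frame: `boulder_id`, `bottom_type`, `summit_vertex`,
#'   `relative_height_m`, `surface_complexity`, `valid`.
#' @export
boulder_indicators <- function(mesh, boulders, config = indicator_config()) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  mask <- edge_mask(mesh, config)
  n <- nrow(boulders)
  out <- data.frame(boulder_id = boulders$boulder_id,
                    bottom_type = boulders$bottom_type,
                    summit_vertex = NA_integer_,
                    relative_height_m = NA_real_,
                    surface_complexity = NA_real_,
                    valid = FALSE, stringsAsFactors = FALSE)
  empties <- character(0)
  for (i in seq_len(n)) {
    b <- boulders[i, ]
    sv <- tryCatch(summit_vertex(mesh, b), error = function(e) NA_integer_)
    if (is.na(sv)) {
      empties <- c(empties, b$boulder_id)
      next
    }
    out$summit_vertex[i] <- sv
    if (mask[sv]) {
      out$valid[i] <- TRUE
      out$relative_height_m[i] <- relative_height(mesh, sv, config)
      out$surface_complexity[i] <- surface_complexity(mesh, sv, config)
    }
  }
  if (length(empties)) {
    warning("no mesh vertex inside footprint of boulder(s): ",
            paste(empties, collapse = ", "), "; rows flagged invalid")
  }
  out
}

#' Write per-boulder indicators to CSV
#' @param indicators output of [boulder_indicators()].
#' @param path CSV path.
#' @export
write_indicators <- function(indicators, path) {
  utils::write.csv(indicators[, c("boulder_id", "relative_height_m",
                                  "surface_complexity", "valid")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-boulder indicators from CSV
#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  if (!file.exists(path)) stop("indicator file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("boulder_id", "relative_height_m", "surface_complexity", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("indicator CSV missing columns: ", paste(miss, collapse = ", "))
  df$boulder_id <- as.character(df$boulder_id)
  df$valid <- as.logical(df$valid)
  df
}
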