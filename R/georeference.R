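#' Reference points for georeferencing
#'
#' Reference points tie the local photogrammetric model frame to real-world
#' scale and depth: each carries its position in (pre-adjustment) model
#' coordinates and its surveyed depth below the sea-surface datum.
#'
#' @param name character vector of point labels.
#' @param x,y,z numeric model-frame coordinates.
#' @param depth_m known depths in metres (> 0).
#' @return data.frame of class `reference_points`.
#' @export
reference_points <- function(name, x, y, z, depth_m) {
  df <- data.frame(name = as.character(name), x = as.numeric(x),
                   y = as.numeric(y), z = as.numeric(z),
                   depth_m = as.numeric(depth_m), stringsAsFactors = FALSE)
  if (nrow(df) < 3L) stop("at least 3 reference points are required")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z", "depth_m")])))) {
    stop("non-finite reference point values")
  }
  if (any(df$depth_m <= 0)) stop("known depths must be positive")
  class(df) <- c("reference_points", "data.frame")
  df
}

#' Read a georeferencing configuration
#'
#' The configuration is YAML with a `reference_points` list (keys `name`,
#' `x`, `y`, `z`, `depth_m`) and a `distance` block (`ref_a`, `ref_b`,
#' `meters`) giving one known inter-point distance that fixes the scale.
#'
#' @param path path to the YAML file.
#' @return list with elements `refs` ([reference_points()]) and
#'   `known_distance` (list with `ref_a`, `ref_b`, `meters`, or `NULL`).
#' @export
read_georef_config <- function(path) {
  if (!file.exists(path)) stop("georeferencing config not found: ", path)
  # keep "y"/"n" as literal strings: the coordinate key "y" must not become TRUE
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x))
  rp <- cfg$reference_points
  if (is.null(rp)) stop("config lacks 'reference_points'")
  refs <- reference_points(
    name = vapply(rp, function(p) as.character(p$name), ""),
    x = vapply(rp, function(p) as.numeric(p$x), 0),
    y = vapply(rp, function(p) as.numeric(p$y), 0),
    z = vapply(rp, function(p) as.numeric(p$z), 0),
    depth_m = vapply(rp, function(p) as.numeric(p$depth_m), 0))
  kd <- NULL
  if (!is.null(cfg$distance)) {
    kd <- list(ref_a = as.character(cfg$distance$ref_a),
               ref_b = as.character(cfg$distance$ref_b),
               meters = as.numeric(cfg$distance$meters))
  }
  list(refs = refs, known_distance = kd)
}

# Minimal rotation taking unit vector n to +e_z (Rodrigues).
.rotation_to_vertical <- function(n) {
  k <- c(n[2], -n[1], 0)  # n x e_z
  s <- sqrt(sum(k^2))
  cth <- n[3]
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # model is upside down relative to depths: rotate pi about x
    return(diag(c(1, -1, -1)))
  }
  k <- k / s
  th <- atan2(s, cth)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Georeference a mesh against depth reference points
#'
#' Fits a 7-parameter similarity transform (uniform scale, rotation,
#' translation) that (a) makes the distance between the named reference pair
#' equal the known distance, and (b) maps each reference point's elevation to
#' minus its known depth, exactly for three references and in least squares
#' for more. Depth references cannot constrain rotation about the vertical
#' axis or horizontal translation, so the transform uses the minimal rotation
#' taking the recovered up-direction to +z and leaves the horizontal origin
#' untouched; the mesh is therefore correct in scale, tilt and depth, and its
#' horizontal frame stays as close to the model frame as possible.
#'
#' @param mesh a [seafloor_mesh()] in model units.
#' @param refs a [reference_points()] table (>= 3 points, not collinear).
#' @param known_distance list with `ref_a`, `ref_b` (names in `refs`) and
#'   `meters`; required, because depth constraints alone cannot fix scale.
#' @return The transformed [seafloor_mesh()], with attribute `"georeference"`
#'   holding `scale`, `rotation`, `translation`, per-reference
#'   `depth_residuals` (m) and their RMS `depth_rmse`.
#' @export
georeference <- function(mesh, refs, known_distance) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  if (!inherits(refs, "reference_points")) {
    refs <- reference_points(refs$name, refs$x, refs$y, refs$z, refs$depth_m)
  }
  if (missing(known_distance) || is.null(known_distance)) {
    stop("known_distance is required: depth references alone cannot fix scale")
  }
  ia <- match(known_distance$ref_a, refs$name)
  ib <- match(known_distance$ref_b, refs$name)
  if (is.na(ia) || is.na(ib)) stop("known_distance names a reference not in refs")
  P <- as.matrix(refs[, c("x", "y", "z")])
  d <- refs$depth_m
  model_dist <- sqrt(sum((P[ia, ] - P[ib, ])^2))
  if (!is.finite(known_distance$meters) || known_distance$meters <= 0) {
    stop("known distance must be a positive number of meters")
  }
  if (model_dist <= 0) stop("non-positive scale: reference pair coincides in model space")
  s <- known_distance$meters / model_dist

  Q <- s * P
  Qc <- sweep(Q, 2L, colMeans(Q))
  sv <- svd(Qc)
  if (sv$d[1] <= 0 || sv$d[2] < 1e-9 * sv$d[1]) {
    stop("reference points are collinear: orientation is underdetermined")
  }
  target <- -(d - mean(d))
  if (sv$d[3] > 1e-7 * sv$d[1]) {
    # references span 3D: plain least squares for the up-direction
    a <- sv$v %*% (diag(1 / sv$d) %*% (t(sv$u) %*% target))
    a <- as.vector(a)
    n <- a / sqrt(sum(a^2))
  } else {
    # coplanar references: solve in the plane, close with the unit constraint
    a_par <- sv$v[, 1:2] %*% (diag(1 / sv$d[1:2]) %*% (t(sv$u[, 1:2]) %*% target))
    a_par <- as.vector(a_par)
    rem <- 1 - sum(a_par^2)
    if (rem < -1e-6) {
      stop("reference depths are incompatible with the supplied scale")
    }
    nu <- sv$v[, 3]
    sgn <- if (nu[3] >= 0) 1 else -1  # keep the model's own up as up
    a <- a_par + sgn * sqrt(max(rem, 0)) * nu
    n <- a / sqrt(sum(a^2))
  }
  cst <- mean(-d) - sum(n * colMeans(Q))
  resid <- as.vector(Q %*% n) + cst + d

  R <- .rotation_to_vertical(n)
  tr <- c(0, 0, cst)
  V <- t(R %*% (s * t(mesh$vertices))) + rep(tr, each = nrow(mesh$vertices))
  out <- seafloor_mesh(V, mesh$faces)
  attr(out, "georeference") <- list(
    scale = s, rotation = R, translation = tr,
    depth_residuals = stats::setNames(resid, refs$name),
    depth_rmse = sqrt(mean(resid^2)))
  out
}

#' Summarise a mesh
#'
#' Reports the horizontal area (sum of horizontally projected triangle areas;
#' for a non-overhanging surface this equals the footprint area), the mean
#' vertex resolution (mean 3D nearest-neighbour distance between vertices)
#' and the vertex count.
#'
#' @param mesh a [seafloor_mesh()] with at least 2 vertices.
#' @return list of class `mesh_summary` with `horizontal_area` (m^2, `NA`
#'   for a faceless point cloud), `mean_vertex_resolution` (m) and
#'   `vertex_count`.
#' @export
mesh_summary <- function(mesh) {
  stopifnot(inherits(mesh, "seafloor_mesh"))
  V <- mesh$vertices
  if (nrow(V) < 2L) stop("mesh summary needs at least 2 vertices")
  if (max(apply(V, 2L, function(c) diff(range(c)))) == 0) {
    stop("degenerate mesh: all vertices coincide")
  }
  area <- NA_real_
  if (nrow(mesh$faces) > 0L) {
    a <- V[mesh$faces[, 1], 1:2, drop = FALSE]
    b <- V[mesh$faces[, 2], 1:2, drop = FALSE]
    cc <- V[mesh$faces[, 3], 1:2, drop = FALSE]
    cross <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
      (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
    area <- sum(abs(cross)) / 2
  } else {
    warning("point cloud without faces: horizontal_area is NA")
  }
  res <- mean(.nearest_neighbor_dist(V))
  structure(list(horizontal_area = area, mean_vertex_resolution = res,
                 vertex_count = nrow(V)), class = "mesh_summary")
}

#' @export
print.mesh_summary <- function(x, ...) {
  cat(sprintf("mesh summary: %d vertices\n", x$vertex_count))
  cat(sprintf("  horizontal area: %s m^2\n",
              if (is.na(x$horizontal_area)) "NA" else format(x$horizontal_area)))
  cat(sprintf("  mean vertex resolution: %.4g m (%.1f cm)\n",
              x$mean_vertex_resolution, 100 * x$mean_vertex_resolution))
  invisible(x)
}

# Per-vertex distance to the nearest other vertex. Exact chunked scan for
# small point sets; 2D cell buckets (with per-point exact fallback) above.
.nearest_neighbor_dist <- function(V, exact_limit = 6000L) {
  n <- nrow(V)
  if (n <= exact_limit) return(.nn_exact(V))
  span_x <- diff(range(V[, 1])); span_y <- diff(range(V[, 2]))
  h <- max(sqrt(max(span_x, 1e-9) * max(span_y, 1e-9) / n) * 2, 1e-9)
  cx <- floor((V[, 1] - min(V[, 1])) / h)
  cy <- floor((V[, 2] - min(V[, 2])) / h)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  out <- rep(NA_real_, n)
  for (k in names(buckets)) {
    idx <- buckets[[k]]
    c0 <- c(cx[idx[1]], cy[idx[1]])
    cand <- idx
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      kk <- paste(c0[1] + dx, c0[2] + dy)
      if (exists(kk, envir = lookup, inherits = FALSE)) {
        cand <- c(cand, get(kk, envir = lookup))
      }
    }
    if (length(cand) < 2L) next  # fallback below
    D2 <- .cross_dist2(V[idx, , drop = FALSE], V[cand, , drop = FALSE])
    self <- match(idx, cand)
    D2[cbind(seq_along(idx), self)] <- Inf
    dmin <- sqrt(apply(D2, 1L, min))
    # the neighbour-bucket search is only guaranteed within one cell ring
    ok <- dmin <= h
    out[idx[ok]] <- dmin[ok]
  }
  todo <- which(is.na(out))
  for (i in todo) {
    d2 <- colSums((t(V) - V[i, ])^2)
    d2[i] <- Inf
    out[i] <- sqrt(min(d2))
  }
  out
}

.nn_exact <- function(V, chunk = 512L) {
  n <- nrow(V)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    D2 <- .cross_dist2(V[idx, , drop = FALSE], V)
    D2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(D2, 1L, min))
  }
  out
}

.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}
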