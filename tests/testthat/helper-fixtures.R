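# Programmatic fixtures shared across test files.

tetrahedron_ply <- function(path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property double x", "property double y", "property double z",
    "element face 4",
    "property list uchar int vertex_indices", "end_header",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), path)
  path
}

# regular grid mesh with a caller-supplied elevation function
grid_mesh <- function(L, W, spacing, zfun = function(x, y) -6) {
  X <- seq(0, L, by = spacing)
  Y <- seq(0, W, by = spacing)
  nx <- length(X); ny <- length(Y)
  V <- cbind(rep(X, times = ny), rep(Y, each = nx), 0)
  V[, 3] <- zfun(V[, 1], V[, 2])
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  seafloor_mesh(V, F)
}

# iid-noise rough terrain on a grid (point positions deterministic in seed)
rough_terrain <- function(n_side = 32, spacing = 0.3, z_sd = 0.3, seed = 1) {
  set.seed(seed)
  grid_mesh((n_side - 1) * spacing, (n_side - 1) * spacing, spacing,
            zfun = function(x, y) -6 + rnorm(length(x), sd = z_sd))
}

merge_indicators <- function(presence, indicators) {
  i <- match(presence$boulder_id, indicators$boulder_id)
  presence$relative_height <- indicators$relative_height_m[i]
  presence$surface_complexity <- indicators$surface_complexity[i]
  presence$valid <- indicators$valid[i]
  presence
}
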