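test_that("relative height is zero on a flat plane and the cap height at an apex", {
  fp <- make_fixture("flat_plane")
  inner <- which(fp$mesh$vertices[, 1] > 2 & fp$mesh$vertices[, 1] < 10 &
                   fp$mesh$vertices[, 2] > 2 & fp$mesh$vertices[, 2] < 10)
  expect_true(all(relative_height(fp$mesh, inner[c(1, 17, 53)]) == 0))

  sb <- make_fixture("single_boulder")
  apex <- nrow(sb$mesh$vertices)  # exact apex vertex appended last
  expect_equal(relative_height(sb$mesh, apex), 0.5)
})

test_that("both indicators match exhaustive recomputation on a rough terrain", {
  m <- rough_terrain(n_side = 32, spacing = 0.3, z_sd = 0.3, seed = 41)
  n <- nrow(m$vertices)
  expect_lte(n, 2000L)
  rh <- relative_height(m, seq_len(n))
  rh_oracle <- vapply(seq_len(n), function(i)
    oracle_relative_height(m$vertices, i), numeric(1))
  expect_identical(rh, rh_oracle)
  expect_true(all(rh >= 0))

  set.seed(42)
  probe <- sample(n, 40L)
  sc <- surface_complexity(m, probe)
  sc_oracle <- vapply(probe, function(i)
    oracle_surface_complexity(m$vertices, i), numeric(1))
  expect_identical(sc, sc_oracle)
  expect_true(all(sc >= 1 / 216 & sc <= 1))
})

test_that("surface complexity handles isolated and plane-covered windows", {
  iso <- seafloor_mesh(cbind(c(0, 10, 20, 30), 0, -6))
  expect_equal(surface_complexity(iso, 1), 1 / 216)

  fp <- make_fixture("flat_plane")  # 0.5 m sampling through the target
  centre <- which(fp$mesh$vertices[, 1] == 6 & fp$mesh$vertices[, 2] == 6)
  expect_equal(surface_complexity(fp$mesh, centre), 36 / 216)
})

test_that("the planar box-counting mode reproduces the 9-of-36 worked case", {
  # nine points in nine distinct cells of the 6x6 grid over a 3 m window
  cells <- cbind(c(3, 3, 2, 4, 1, 5, 0, 2, 4), c(3, 2, 3, 4, 1, 5, 0, 5, 1))
  pts <- -1.5 + (cells + 0.5) * 0.5
  expect_equal(box_count_fraction(pts, c(0, 0), 3, 0.5), 0.25)
  m <- seafloor_mesh(cbind(pts, -6))
  expect_equal(surface_complexity(m, 1, dims = 2), 0.25)
})

test_that("box counting is monotone under vertex insertion and vertical-shift invariant", {
  set.seed(43)
  for (rep in 1:10) {
    V <- cbind(runif(60, -2, 2), runif(60, -2, 2), runif(60, -2, 2))
    m <- seafloor_mesh(V)
    sc0 <- surface_complexity(m, 1)
    extra <- rep(V[1, ], each = 20) + matrix(runif(60, -1.4, 1.4), 20, 3)
    m2 <- seafloor_mesh(rbind(V, extra))
    sc1 <- surface_complexity(m2, 1)
    expect_gte(sc1, sc0)
    shift <- runif(1, -5, 5)
    m3 <- seafloor_mesh(V + rep(c(0, 0, shift), each = 60))
    expect_equal(surface_complexity(m3, 1), sc0)
    expect_equal(relative_height(m3, 1), relative_height(m, 1))
  }
})

test_that("edge exclusion keeps interior vertices and drops the rim", {
  fp <- make_fixture("flat_plane")  # 12 x 12 m footprint
  mask <- edge_mask(fp$mesh)
  V <- fp$mesh$vertices
  centroid <- which(V[, 1] == 6 & V[, 2] == 6)
  corner <- which(V[, 1] == 0 & V[, 2] == 0)
  expect_true(mask[centroid])
  expect_false(mask[corner])
})

test_that("edge mask agrees with a ray-casting oracle away from the boundary", {
  rv <- make_fixture("ridge_valley")
  mask <- edge_mask(rv$mesh)
  V <- rv$mesh$vertices
  xy <- V[, 1:2]
  hull <- grDevices::chull(xy)
  poly <- xy[hull, , drop = FALSE]
  set.seed(44)
  probe <- sample(nrow(V), 300L)
  for (i in probe) {
    corners <- cbind(xy[i, 1] + c(-1.5, -1.5, 1.5, 1.5),
                     xy[i, 2] + c(-1.5, 1.5, -1.5, 1.5))
    near_edge <- any(apply(corners, 1, dist_to_poly_edges, poly = poly) < 1e-6)
    if (near_edge) next  # ray casting is ambiguous exactly on the boundary
    oracle <- all(apply(corners, 1, oracle_point_in_poly, poly = poly))
    expect_identical(mask[i], oracle)
  }
})

test_that("summit selection picks the highest footprint vertex, lowest index on ties", {
  sb <- make_fixture("single_boulder")
  apex <- nrow(sb$mesh$vertices)
  expect_equal(summit_vertex(sb$mesh, sb$annotations[1, ]), apex)

  tie <- seafloor_mesh(rbind(c(0, 0, -6), c(0.2, 0, -5), c(-0.2, 0, -5),
                             c(0, 0.3, -5.8)))
  b <- list(boulder_id = "T", x_m = 0, y_m = 0, radius_m = 1)
  expect_equal(summit_vertex(tie, b), 2L)

  m <- rough_terrain(n_side = 20, spacing = 0.3, seed = 45)
  b2 <- list(boulder_id = "R", x_m = 2.5, y_m = 2.5, radius_m = 1.0)
  V <- m$vertices
  inside <- which((V[, 1] - 2.5)^2 + (V[, 2] - 2.5)^2 <= 1)
  expect_equal(summit_vertex(m, b2), inside[which.max(V[inside, 3])])

  expect_error(summit_vertex(m, list(boulder_id = "X", x_m = 100, y_m = 100,
                                     radius_m = 0.5)), "empty footprint")
})

test_that("per-boulder indicator rows match independent recomputation", {
  fx <- make_fixture("tiny_scene")
  ind <- boulder_indicators(fx$mesh, fx$annotations)
  expect_equal(nrow(ind), nrow(fx$annotations))  # no silent drops
  mask <- edge_mask(fx$mesh)
  for (i in seq_len(nrow(ind))) {
    sv <- summit_vertex(fx$mesh, fx$annotations[i, ])
    expect_equal(ind$summit_vertex[i], sv)
    expect_equal(ind$valid[i], mask[sv])
    if (mask[sv]) {
      expect_equal(ind$relative_height_m[i], relative_height(fx$mesh, sv))
      expect_equal(ind$surface_complexity[i], surface_complexity(fx$mesh, sv))
    } else {
      expect_true(is.na(ind$relative_height_m[i]))
    }
  }
})

test_that("boulders outside the mesh footprint are flagged, not dropped", {
  sb <- make_fixture("single_boulder")
  ann <- boulder_annotations(c("B0001", "B9999"), c(5, 50), c(5, 50),
                             c(0.5, 0.5), c("sand", "sand"))
  expect_warning(ind <- boulder_indicators(sb$mesh, ann), "B9999")
  expect_equal(nrow(ind), 2L)
  expect_true(ind$valid[1])
  expect_equal(ind$relative_height_m[1], 0.5)
  expect_false(ind$valid[2])
  expect_true(is.na(ind$summit_vertex[2]))
})

test_that("indicator configuration validates its geometry", {
  expect_error(indicator_config(sc_window = 3, sc_cell = 0.7), "multiple")
  expect_error(indicator_config(rh_radius = -1), "rh_radius")
  cfg <- indicator_config()
  expect_equal(cfg$cells_per_axis, 6L)
  m <- rough_terrain(n_side = 5, seed = 46)
  expect_error(relative_height(m, 0), "invalid vertex")
  expect_error(surface_complexity(m, 999), "invalid vertex")
})
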