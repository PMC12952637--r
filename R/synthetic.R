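#' Synthetic terrain configuration
#'
#' Describes the simulated survey scene: a sloping sandy seafloor crossed by
#' cobble ridges, seeded with ~1 m artificial boulders, mimicking an 80 x 20 m
#' man-made boulder reef at 4.5-9.2 m depth. Defaults follow the surveyed
#' site where its geometry is reported (extent, depth range, boulder
#' diameter, 0.08 m vertex spacing); ridge and noise geometry are free
#' parameters of the simulator.
#'
#' @param extent `(length_m, width_m)`; depth increases across the width.
#' @param depth_range `(shallow_m, deep_m)` depths below datum, deep > shallow.
#' @param ridge_count number of cobble ridges crossing the slope.
#' @param ridge_height ridge crest height (m).
#' @param ridge_sigma Gaussian half-width of a ridge (m).
#' @param cobble_size `(min_m, max_m)` cobble diameters scattered on ridges.
#' @param cobbles_per_ridge count of cobble bumps per ridge.
#' @param boulder_diameter artificial boulder diameter (m).
#' @param n_boulders number of artificial boulders to place.
#' @param pile_fraction share of boulders placed in stacked clusters of 2-4.
#' @param mesh_spacing grid spacing of the generated mesh (m).
#' @param noise_sd standard deviation of the smooth terrain noise (m).
#' @param seed integer seed; every derived random stage is deterministic in it.
#' @return list of class `terrain_config`.
#' @export
terrain_config <- function(extent = c(80, 20), depth_range = c(4.5, 9.2),
                           ridge_count = 5, ridge_height = 0.4,
                           ridge_sigma = 2.0, cobble_size = c(0.2, 0.5),
                           cobbles_per_ridge = 60, boulder_diameter = 1.0,
                           n_boulders = 0, pile_fraction = 0.3,
                           mesh_spacing = 0.08, noise_sd = 0.1, seed = 1L) {
  stopifnot(length(extent) == 2L, all(extent > 0),
            length(depth_range) == 2L, depth_range[2] > depth_range[1],
            mesh_spacing > 0, pile_fraction >= 0, pile_fraction <= 1,
            boulder_diameter > 0, n_boulders >= 0, ridge_count >= 0)
  structure(list(extent = as.numeric(extent),
                 depth_range = as.numeric(depth_range),
                 ridge_count = as.integer(ridge_count),
                 ridge_height = ridge_height, ridge_sigma = ridge_sigma,
                 cobble_size = as.numeric(cobble_size),
                 cobbles_per_ridge = as.integer(cobbles_per_ridge),
                 boulder_diameter = boulder_diameter,
                 n_boulders = as.integer(n_boulders),
                 pile_fraction = pile_fraction,
                 mesh_spacing = mesh_spacing, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "terrain_config")
}

.set_seed <- function(seed) {
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

# Spherical cap of base radius a and height h set down on heightfield Z
# (nx x ny), grid coordinates X / Y, centred at (cx, cy). The cap's base sits
# at the terrain level under its centre; overlapping caps combine by max, so
# a pile reads as one stacked mound.
.add_cap <- function(Z, X, Y, cx, cy, a, h) {
  Rs <- (a^2 + h^2) / (2 * h)
  ix <- which(abs(X - cx) <= a)
  iy <- which(abs(Y - cy) <= a)
  if (!length(ix) || !length(iy)) return(Z)
  z0 <- Z[which.min(abs(X - cx)), which.min(abs(Y - cy))]
  r2 <- outer((X[ix] - cx)^2, (Y[iy] - cy)^2, "+")
  dz <- sqrt(pmax(Rs^2 - r2, 0)) - (Rs - h)
  keep <- r2 <= a^2 & dz > 0
  Z[ix, iy][keep] <- pmax(Z[ix, iy][keep], z0 + dz[keep])
  Z
}

#' Generate a synthetic boulder-reef terrain
#'
#' Builds a heightfield mesh: a planar cross-slope from the shallow to the
#' deep edge plus smooth low-frequency noise; Gaussian-profile cobble ridges
#' crossing the slope, roughened with scattered cobble-sized bumps; and
#' artificial boulders as spherical caps (height = radius), isolated or in
#' stacked piles of 2-4 overlapping caps with a raised centre. Each boulder
#' is annotated with its centre, footprint radius, and a bottom type set by
#' whether its base sits on a ridge (`cobble`) or off-ridge (`sand`).
#' Deterministic given `config$seed`.
#'
#' @param config a [terrain_config()].
#' @return list with `mesh` ([seafloor_mesh()]), `annotations`
#'   ([boulder_annotations()], zero rows when `n_boulders = 0`), and
#'   `declared_vertex_count`.
#' @export
generate_terrain <- function(config = terrain_config()) {
  stopifnot(inherits(config, "terrain_config"))
  L <- config$extent[1]; W <- config$extent[2]
  sp <- config$mesh_spacing
  X <- seq(0, L, by = sp)
  Y <- seq(0, W, by = sp)
  nx <- length(X); ny <- length(Y)

  shallow <- config$depth_range[1]; deep <- config$depth_range[2]
  Z <- matrix(rep(-(shallow + (deep - shallow) * Y / W), each = nx), nx, ny)

  if (config$noise_sd > 0) {
    .set_seed(.stage_seed(config$seed, 1))
    K <- 8L
    amp <- config$noise_sd * sqrt(2 / K)
    for (k in seq_len(K)) {
      wl <- stats::runif(1, 5, 20)
      th <- stats::runif(1, 0, 2 * pi)
      ph <- stats::runif(1, 0, 2 * pi)
      fx <- cos(th) / wl; fy <- sin(th) / wl
      Z <- Z + amp * cos(2 * pi * (outer(X * fx, Y * fy, "+")) + ph)
    }
  }

  ridge_x <- numeric(0)
  if (config$ridge_count > 0) {
    .set_seed(.stage_seed(config$seed, 2))
    slots <- L * (seq_len(config$ridge_count) - 0.5) / config$ridge_count
    ridge_x <- slots + stats::runif(config$ridge_count, -0.05 * L, 0.05 * L)
    for (rx in ridge_x) {
      prof <- config$ridge_height * exp(-(X - rx)^2 / (2 * config$ridge_sigma^2))
      Z <- Z + matrix(rep(prof, ny), nx, ny)
      for (j in seq_len(config$cobbles_per_ridge)) {
        ccx <- stats::rnorm(1, rx, config$ridge_sigma)
        ccy <- stats::runif(1, 0, W)
        ca <- stats::runif(1, config$cobble_size[1], config$cobble_size[2]) / 2
        Z <- .add_cap(Z, X, Y, ccx, ccy, ca, ca)
      }
    }
  }
  on_ridge <- function(x) {
    length(ridge_x) > 0 && any(abs(x - ridge_x) <= 2 * config$ridge_sigma)
  }

  ann <- data.frame(boulder_id = character(0), x_m = numeric(0),
                    y_m = numeric(0), radius_m = numeric(0),
                    bottom_type = character(0), stringsAsFactors = FALSE)
  if (config$n_boulders > 0) {
    .set_seed(.stage_seed(config$seed, 3))
    a <- config$boulder_diameter / 2
    margin <- 2.0
    pw <- L - 2 * margin; ph <- W - 2 * margin
    if (pw <= 0 || ph <= 0) {
      stop("boulders requested exceed placeable area: extent too small for margins")
    }
    # decide group sizes up front: piles of 2-4 until the pile share is used
    n_pile <- round(config$pile_fraction * config$n_boulders)
    sizes <- integer(0)
    while (n_pile >= 2L) {
      k <- min(sample(2:4, 1L), n_pile)
      sizes <- c(sizes, k)
      n_pile <- n_pile - k
    }
    sizes <- sample(c(sizes, rep(1L, config$n_boulders - sum(sizes))))
    ngroups <- length(sizes)
    # installed boulders follow a planned, jittered layout; grid slots carry
    # the requested density (real sites run ~0.7 boulders per m^2)
    s <- sqrt(pw * ph / ngroups)
    nsx <- max(floor(pw / s), 1L); nsy <- max(floor(ph / s), 1L)
    while (nsx * nsy < ngroups) {
      s <- s * 0.97
      nsx <- max(floor(pw / s), 1L); nsy <- max(floor(ph / s), 1L)
    }
    if (s < 0.75 * config$boulder_diameter) {
      stop("boulders requested exceed placeable area")
    }
    slots <- sample(nsx * nsy)[seq_len(ngroups)]
    sx <- margin + ((slots - 1L) %% nsx + 0.5) * pw / nsx
    sy <- margin + ((slots - 1L) %/% nsx + 0.5) * ph / nsy
    jit <- 0.2 * min(s, 1)
    sx <- sx + stats::runif(ngroups, -jit, jit)
    sy <- sy + stats::runif(ngroups, -jit, jit)
    bid <- 0L
    for (g in seq_len(ngroups)) {
      k <- sizes[g]
      ctr <- c(sx[g], sy[g])
      if (k == 1L) {
        Z <- .add_cap(Z, X, Y, ctr[1], ctr[2], a, a)
        maxr <- a
      } else {
        offs <- matrix(stats::runif(2 * (k - 1L), -0.45, 0.45), ncol = 2)
        Z <- .add_cap(Z, X, Y, ctr[1], ctr[2], a, 1.5 * a)  # raised centre
        maxr <- a
        for (j in seq_len(k - 1L)) {
          Z <- .add_cap(Z, X, Y, ctr[1] + offs[j, 1], ctr[2] + offs[j, 2], a, a)
          maxr <- max(maxr, sqrt(sum(offs[j, ]^2)) + a)
        }
      }
      for (j in seq_len(k)) {
        bid <- bid + 1L
        ann <- rbind(ann, data.frame(
          boulder_id = sprintf("B%04d", bid),
          x_m = ctr[1] + (j - 1L) * 1e-6,  # pile members share a centre;
          y_m = ctr[2],                    # offsets keep coordinates unique
          radius_m = maxr,
          bottom_type = if (on_ridge(ctr[1])) "cobble" else "sand",
          stringsAsFactors = FALSE))
      }
    }
  }

  V <- cbind(rep(X, times = ny), rep(Y, each = nx), as.vector(Z))
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  mesh <- seafloor_mesh(V, F)
  anns <- if (nrow(ann)) {
    boulder_annotations(ann$boulder_id, ann$x_m, ann$y_m, ann$radius_m,
                        ann$bottom_type)
  } else {
    structure(ann, class = c("boulder_annotations", "data.frame"))
  }
  list(mesh = mesh, annotations = anns, declared_vertex_count = nx * ny)
}

#' Species presence model
#'
#' Independent per-species Bernoulli presence with bottom-type-specific
#' probabilities, optionally shifted on the logit scale by the geomorphic
#' indicators. Default probabilities are the observed per-bottom prevalences
#' of the five scored taxa at the surveyed reef; covariate effects default to
#' zero (bottom type only).
#'
#' @param p_sand,p_cobble named numeric vectors of presence probabilities for
#'   `u_pinnatifida`, `perennial_sargassum`, `s_horneri`, `c_sinuosa`,
#'   `coralline`.
#' @param beta_rh,beta_sc named numeric vectors: logit shift per metre of
#'   relative height / per unit surface complexity (names as above; missing
#'   names mean 0).
#' @return list of class `presence_model`.
#' @export
presence_model <- function(
    p_sand = c(u_pinnatifida = 0.584, perennial_sargassum = 0.396,
               s_horneri = 0.056, c_sinuosa = 0.793, coralline = 0.264),
    p_cobble = c(u_pinnatifida = 0.057, perennial_sargassum = 0.045,
                 s_horneri = 0.002, c_sinuosa = 0.797, coralline = 0.011),
    beta_rh = numeric(0), beta_sc = numeric(0)) {
  full <- function(v) {
    out <- stats::setNames(rep(0, length(.species_fields)), .species_fields)
    out[names(v)] <- v
    out
  }
  p_sand <- full(p_sand); p_cobble <- full(p_cobble)
  if (any(p_sand < 0 | p_sand > 1 | p_cobble < 0 | p_cobble > 1)) {
    stop("presence probabilities must lie in [0, 1]")
  }
  structure(list(p_sand = p_sand, p_cobble = p_cobble,
                 beta_rh = full(beta_rh), beta_sc = full(beta_sc)),
            class = "presence_model")
}

#' Generate species-presence records
#'
#' Draws each species independently per boulder from its bottom-type
#' probability, shifted on the logit scale by `beta_rh * relative_height +
#' beta_sc * surface_complexity` when nonzero coefficients are supplied (the
#' boulder table must then carry indicator columns). Deterministic given
#' `seed`.
#'
#' @param boulders a [boulder_annotations()] table, optionally carrying
#'   `relative_height` / `surface_complexity` columns (e.g. merged from
#'   [boulder_indicators()]).
#' @param model a [presence_model()].
#' @param seed integer seed.
#' @return records data.frame in the internal schema accepted by
#'   [classify_records()] and [write_s8_table()].
#' @export
generate_presence <- function(boulders, model = presence_model(), seed = 1L) {
  stopifnot(inherits(model, "presence_model"))
  n <- nrow(boulders)
  needs_cov <- any(model$beta_rh != 0) || any(model$beta_sc != 0)
  if (needs_cov &&
      !all(c("relative_height", "surface_complexity") %in% names(boulders))) {
    stop("covariate effects requested but boulders carry no indicator columns")
  }
  .set_seed(.stage_seed(seed, 4))
  out <- data.frame(boulder_id = as.character(boulders$boulder_id),
                    stringsAsFactors = FALSE)
  sandy <- boulders$bottom_type == "sand"
  for (f in .species_fields) {
    p <- ifelse(sandy, model$p_sand[[f]], model$p_cobble[[f]])
    if (needs_cov && (model$beta_rh[[f]] != 0 || model$beta_sc[[f]] != 0)) {
      eta <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
        model$beta_rh[[f]] * boulders$relative_height +
        model$beta_sc[[f]] * boulders$surface_complexity
      p <- stats::plogis(eta)
      p[boulders$relative_height %in% NA] <- NA
    }
    draw <- stats::runif(n) < p
    draw[is.na(p)] <- NA
    out[[f]] <- draw
  }
  out$bottom_type <- factor(as.character(boulders$bottom_type),
                            c("sand", "cobble"))
  for (f in c("relative_height", "surface_complexity")) {
    if (f %in% names(boulders)) out[[f]] <- boulders[[f]]
  }
  out
}

.flat_mesh <- function(L, W, sp, depth) {
  X <- seq(0, L, by = sp); Y <- seq(0, W, by = sp)
  nx <- length(X); ny <- length(Y)
  V <- cbind(rep(X, times = ny), rep(Y, each = nx), -depth)
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  F <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  seafloor_mesh(V, F)
}

#' Deterministic test fixtures
#'
#' Small (<= 5,000 vertex) scenes used across the test suite:
#' `flat_plane` (featureless flat bottom), `single_boulder` (one hemisphere
#' on flat sand), `pile` (a stacked 3-cap pile), `ridge_valley` (sand
#' boulders in a valley enclosed by cobble ridges) and `tiny_scene`
#' (a complete miniature survey: terrain, boulders, presence records).
#'
#' @param name fixture name.
#' @param seed integer seed for the stochastic fixtures.
#' @return list with `mesh`, `annotations` and `presence` (zero-row /
#'   `NULL` where the fixture has no boulders).
#' @export
make_fixture <- function(name = c("flat_plane", "single_boulder", "pile",
                                  "ridge_valley", "tiny_scene"), seed = 1L) {
  name <- match.arg(name)
  empty_ann <- structure(
    data.frame(boulder_id = character(0), x_m = numeric(0), y_m = numeric(0),
               radius_m = numeric(0),
               bottom_type = factor(character(0), c("sand", "cobble")),
               stringsAsFactors = FALSE),
    class = c("boulder_annotations", "data.frame"))
  if (name == "flat_plane") {
    return(list(mesh = .flat_mesh(12, 12, 0.5, 6), annotations = empty_ann,
                presence = NULL))
  }
  if (name %in% c("single_boulder", "pile")) {
    mesh <- .flat_mesh(10, 10, 0.15, 6)
    V <- mesh$vertices
    add <- function(V, cx, cy, a, h) {
      Rs <- (a^2 + h^2) / (2 * h)
      r2 <- (V[, 1] - cx)^2 + (V[, 2] - cy)^2
      dz <- sqrt(pmax(Rs^2 - r2, 0)) - (Rs - h)
      dz[r2 > a^2] <- 0
      V[, 3] <- pmax(V[, 3], -6 + dz)
      V
    }
    if (name == "single_boulder") {
      V <- add(V, 5, 5, 0.5, 0.5)
      V <- rbind(V, c(5, 5, -5.5))  # exact apex vertex
      ann <- boulder_annotations("B0001", 5, 5, 0.5, "sand")
    } else {
      V <- add(V, 5, 5, 0.5, 0.75)
      V <- add(V, 5.35, 4.8, 0.5, 0.5)
      V <- add(V, 4.7, 5.3, 0.5, 0.5)
      V <- rbind(V, c(5, 5, -6 + 0.75))
      ann <- boulder_annotations("B0001", 5, 5, 0.95, "sand")
    }
    mesh2 <- seafloor_mesh(V, mesh$faces)
    pres <- generate_presence(ann, presence_model(), seed = seed)
    return(list(mesh = mesh2, annotations = ann, presence = pres))
  }
  if (name == "ridge_valley") {
    cfg <- terrain_config(extent = c(20, 10), depth_range = c(5.0, 7.4),
                          ridge_count = 2, ridge_sigma = 1.0,
                          cobbles_per_ridge = 25, n_boulders = 8,
                          pile_fraction = 0.25, mesh_spacing = 0.25,
                          noise_sd = 0.05, seed = 100 + seed)
    tr <- generate_terrain(cfg)
    pres <- generate_presence(tr$annotations, presence_model(), seed = seed)
    return(list(mesh = tr$mesh, annotations = tr$annotations, presence = pres))
  }
  # tiny_scene
  cfg <- terrain_config(extent = c(16, 8), depth_range = c(5.5, 7.4),
                        ridge_count = 1, ridge_sigma = 1.2,
                        cobbles_per_ridge = 20, n_boulders = 12,
                        pile_fraction = 0.25, mesh_spacing = 0.25,
                        noise_sd = 0.05, seed = 200 + seed)
  tr <- generate_terrain(cfg)
  pres <- generate_presence(tr$annotations, presence_model(), seed = seed)
  list(mesh = tr$mesh, annotations = tr$annotations, presence = pres)
}
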