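# Independent, unoptimised reference implementations used as oracles.

# exhaustive all-pairs relative height
oracle_relative_height <- function(V, i, radius = 1.5) {
  d <- sqrt((V[, 1] - V[i, 1])^2 + (V[, 2] - V[i, 2])^2 + (V[, 3] - V[i, 3])^2)
  V[i, 3] - min(V[d <= radius, 3])
}

# exhaustive cell-by-cell box counting
oracle_surface_complexity <- function(V, i, window = 3, cell = 0.5, dims = 3) {
  ctr <- V[i, seq_len(dims)]
  lo <- ctr - window / 2
  m <- round(window / cell)
  P <- V[, seq_len(dims), drop = FALSE]
  grid <- expand.grid(rep(list(seq_len(m) - 1L), dims))
  occupied <- 0L
  for (g in seq_len(nrow(grid))) {
    inside <- rep(TRUE, nrow(P))
    for (k in seq_len(dims)) {
      a <- lo[k] + grid[g, k] * cell
      inside <- inside & P[, k] >= a & P[, k] < a + cell
    }
    if (any(inside)) occupied <- occupied + 1L
  }
  occupied / m^dims
}

# even-odd ray casting point-in-polygon (boundary not guaranteed)
oracle_point_in_poly <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

dist_to_poly_edges <- function(pt, poly) {
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    d <- min(d, sqrt(sum((pt - (a + t * ab))^2)))
  }
  d
}

# textbook Welch / Pearson formulas
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), n - 2))
}

# published scoresheet as wildcard patterns (u, p, h, c, r; NA = either),
# applied first-match in published order: an implementation-independent
# expansion of the classification rules over all 32 combinations
oracle_scoresheet <- function() {
  rows <- list(
    list(pat = c(1, 1, NA, NA, NA), score = 6L, community = "sargassum_u_pinnatifida"),
    list(pat = c(0, 1, NA, NA, NA), score = 5L, community = "sargassum"),
    list(pat = c(NA, 0, 1, NA, NA), score = 4L, community = "s_horneri"),
    list(pat = c(1, 0, 0, NA, NA), score = 3L, community = "u_pinnatifida"),
    list(pat = c(0, 0, 0, NA, 1), score = 2L, community = "coralline"),
    list(pat = c(0, 0, 0, 1, 0), score = 1L, community = "c_sinuosa"),
    list(pat = c(0, 0, 0, 0, 0), score = 0L, community = "bare_rock"))
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  colnames(combos) <- c("u", "p", "h", "c", "r")
  out <- data.frame(combos, score = NA_integer_, community = NA_character_)
  for (i in seq_len(nrow(combos))) {
    for (row in rows) {
      sel <- !is.na(row$pat)
      if (all(combos[i, sel] == row$pat[sel])) {
        out$score[i] <- row$score
        out$community[i] <- row$community
        break
      }
    }
  }
  out
}
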