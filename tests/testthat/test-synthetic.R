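test_that("terrain generation is deterministic in the seed", {
  cfg <- terrain_config(extent = c(16, 8), mesh_spacing = 0.25, ridge_count = 1,
                        n_boulders = 10, seed = 71)
  a <- generate_terrain(cfg)
  b <- generate_terrain(cfg)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  p1 <- generate_presence(a$annotations, presence_model(), seed = 5)
  p2 <- generate_presence(b$annotations, presence_model(), seed = 5)
  expect_identical(p1, p2)
})

test_that("zero boulders yields a mesh with empty annotations", {
  tr <- generate_terrain(terrain_config(extent = c(10, 6), mesh_spacing = 0.5,
                                        n_boulders = 0))
  expect_equal(nrow(tr$annotations), 0L)
  expect_gt(nrow(tr$mesh$vertices), 0L)
})

test_that("an isolated boulder's summit relative height is near the cap height", {
  cfg <- terrain_config(extent = c(8, 8), depth_range = c(6, 6.2),
                        ridge_count = 0, n_boulders = 1, pile_fraction = 0,
                        mesh_spacing = 0.05, noise_sd = 0, seed = 72)
  tr <- generate_terrain(cfg)
  expect_equal(nrow(tr$annotations), 1L)
  sv <- summit_vertex(tr$mesh, tr$annotations[1, ])
  rh <- relative_height(tr$mesh, sv)
  expect_gte(rh, 0.45)
  expect_lte(rh, 0.55)
})

test_that("degenerate presence probabilities produce all-absent / all-present draws", {
  ann <- boulder_annotations(sprintf("B%03d", 1:50), runif(50, 0, 10),
                             runif(50, 0, 10), 0.5,
                             sample(c("sand", "cobble"), 50, TRUE))
  zero <- presence_model(p_sand = c(c_sinuosa = 0), p_cobble = c(c_sinuosa = 0))
  rec0 <- generate_presence(ann, zero, seed = 1)
  expect_false(any(as.matrix(rec0[, c("u_pinnatifida", "perennial_sargassum",
                                      "s_horneri", "c_sinuosa", "coralline")])))
  one <- presence_model(p_sand = c(c_sinuosa = 1), p_cobble = c(c_sinuosa = 1))
  rec1 <- generate_presence(ann, one, seed = 1)
  expect_true(all(rec1$c_sinuosa))
})

test_that("empirical prevalences recover the model probabilities at n = 10^4", {
  n <- 10000L
  for (bt in c("sand", "cobble")) {
    ann <- boulder_annotations(sprintf("B%05d", 1:n), runif(n, 0, 80),
                               runif(n, 0, 20), 0.5, bt)
    model <- presence_model()
    rec <- generate_presence(ann, model, seed = 73)
    probs <- if (bt == "sand") model$p_sand else model$p_cobble
    for (sp in names(probs)) {
      p <- probs[[sp]]
      se <- sqrt(p * (1 - p) / n)
      expect_lte(abs(mean(rec[[sp]]) - p), max(3 * se, 3 / n),
                 label = sprintf("%s prevalence on %s", sp, bt))
    }
  }
})

test_that("a planted relative-height effect is recovered on the cobble stratum", {
  # positive logit coefficient on relative height for perennial Sargassum;
  # power over seeded replicates at the surveyed sample sizes
  n_sand <- 550L; n_cobble <- 561L
  model <- presence_model(beta_rh = c(perennial_sargassum = 2.0))
  hits <- 0L
  reps <- 50L
  for (rep in seq_len(reps)) {
    set.seed(8000 + rep)
    ann <- boulder_annotations(
      sprintf("B%04d", seq_len(n_sand + n_cobble)),
      runif(n_sand + n_cobble, 0, 80), runif(n_sand + n_cobble, 0, 20), 0.5,
      c(rep("sand", n_sand), rep("cobble", n_cobble)))
    ann$relative_height <- runif(nrow(ann), 0.2, 1.4)
    ann$surface_complexity <- runif(nrow(ann), 0.15, 0.8)
    rec <- generate_presence(ann, model, seed = 8000 + rep)
    an <- run_full_analysis(rec)
    cr <- an$correlations[["relative_height.cobble"]]
    if (!is.null(cr) && cr$r > 0 && cr$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("fixtures expose the expected geomorphic contrasts", {
  single <- make_fixture("single_boulder")
  pile <- make_fixture("pile")
  sc_single <- surface_complexity(single$mesh,
                                  summit_vertex(single$mesh, single$annotations[1, ]))
  sc_pile <- surface_complexity(pile$mesh,
                                summit_vertex(pile$mesh, pile$annotations[1, ]))
  expect_gt(sc_pile, sc_single)

  rv <- make_fixture("ridge_valley")
  expect_setequal(as.character(unique(rv$annotations$bottom_type)),
                  c("sand", "cobble"))
  expect_error(make_fixture("no_such_fixture"))
})

test_that("the miniature scene runs the whole pipeline end to end", {
  fx <- make_fixture("tiny_scene")
  expect_lte(nrow(fx$mesh$vertices), 5000L)
  ind <- boulder_indicators(fx$mesh, fx$annotations)
  rec <- merge_indicators(fx$presence, ind)
  an <- run_full_analysis(rec)
  expect_s3_class(an, "reef_analysis")
  expect_equal(an$n, nrow(fx$annotations))
  expect_output(print(an), "Species prevalence")
})

test_that("impossible boulder densities are refused", {
  expect_error(generate_terrain(terrain_config(extent = c(5, 5),
                                               mesh_spacing = 0.5,
                                               n_boulders = 100)),
               "placeable area")
})
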