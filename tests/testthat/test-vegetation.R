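test_that("classification is total over all 32 combinations and matches the scoresheet", {
  oracle <- oracle_scoresheet()
  got <- classify_vegetation(oracle$u == 1, oracle$p == 1, oracle$h == 1,
                             oracle$c == 1, oracle$r == 1)
  expect_equal(got$score, oracle$score)
  expect_equal(as.character(got$community), oracle$community)
  # scores and communities correspond bijectively
  expect_equal(nrow(unique(got[, c("community", "score")])), 7L)
  expect_error(classify_vegetation(NA, TRUE, TRUE, TRUE, TRUE), "incomplete")
})

test_that("spot combinations map to their published communities", {
  expect_equal(classify_vegetation(TRUE, TRUE, TRUE, TRUE, TRUE)$score, 6L)
  expect_equal(classify_vegetation(FALSE, FALSE, FALSE, FALSE, FALSE)$score, 0L)
  g <- classify_vegetation(TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(g$score, 4L)
  expect_equal(as.character(g$community), "s_horneri")
  g1 <- classify_vegetation(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(g1$score, 1L)
  expect_equal(as.character(g1$community), "c_sinuosa")
})

test_that("the rich/poor dichotomy partitions all seven scores at the score-3 boundary", {
  d <- richness_dichotomy(0:6)
  expect_equal(as.character(d), c(rep("poor", 3), rep("rich", 4)))
  expect_error(richness_dichotomy(7), "out of range")
  expect_error(richness_dichotomy(-1), "out of range")
})

test_that("presence tables round-trip through the S8 CSV schema", {
  fx <- make_fixture("tiny_scene")
  f <- withr::local_tempfile(fileext = ".csv")
  write_s8_table(fx$presence, f)
  back <- read_s8_table(f)
  expect_equal(nrow(back), nrow(fx$presence))
  for (col in c("u_pinnatifida", "perennial_sargassum", "s_horneri",
                "c_sinuosa", "coralline")) {
    expect_identical(back[[col]], fx$presence[[col]])
  }
  expect_identical(as.character(back$bottom_type),
                   as.character(fx$presence$bottom_type))
  expect_equal(back$relative_height, fx$presence$relative_height,
               tolerance = 1e-9)
})

test_that("unicode minus and ascii hyphen parse identically", {
  hdr <- paste("U. pinnatifida,Perennial Sargassum spp.,S. horneri,",
               "C. sinuosa,Geniculate coralline red algae,Bottom type",
               sep = "")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "+,-,-,+,-,sand", "-,-,-,-,-,cobble", "+,+,-,+,+,sand"),
             f1, useBytes = TRUE)
  con <- file(f2, "w", encoding = "UTF-8")
  writeLines(c(hdr, "+,−,−,+,−,sand", "−,−,−,−,−,cobble",
               "+,+,−,+,+,sand"), con)
  close(con)
  r1 <- read_s8_table(f1)
  r2 <- read_s8_table(f2)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3L)
  expect_identical(r1$u_pinnatifida, c(TRUE, FALSE, TRUE))
})

test_that("schema violations are reported with their column or token", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("U. pinnatifida,Bottom type", "+,sand"), f)
  expect_error(read_s8_table(f), "missing column")
  hdr <- paste("U. pinnatifida,Perennial Sargassum spp.,S. horneri,",
               "C. sinuosa,Geniculate coralline red algae,Bottom type", sep = "")
  writeLines(c(hdr, "x,-,-,+,-,sand"), f)
  expect_error(read_s8_table(f), "unknown presence token")
  writeLines(c(hdr, "+,-,-,+,-,mud"), f)
  expect_error(read_s8_table(f), "unknown bottom type")
})

test_that("prevalence counts and percentages stratify by bottom type", {
  rec <- data.frame(
    boulder_id = as.character(1:10),
    u_pinnatifida = c(rep(TRUE, 4), rep(FALSE, 6)),
    perennial_sargassum = FALSE, s_horneri = FALSE,
    c_sinuosa = c(rep(TRUE, 9), FALSE), coralline = FALSE,
    bottom_type = factor(rep(c("sand", "cobble"), each = 5), c("sand", "cobble")))
  tab <- tabulate_prevalence(rec)
  up <- tab[tab$species == "U. pinnatifida", ]
  expect_equal(up$overall_n, 4L)
  expect_equal(up$overall_pct, 40.0)
  expect_equal(up$sand_n, 4L)
  expect_equal(up$cobble_n, 0L)
  allfalse <- rec
  for (f in c("u_pinnatifida", "c_sinuosa")) allfalse[[f]] <- FALSE
  expect_true(all(tabulate_prevalence(allfalse)$overall_n == 0L))
})

test_that("community counts partition the records, overall and within strata", {
  set.seed(51)
  n <- 200L
  rec <- data.frame(
    boulder_id = as.character(1:n),
    u_pinnatifida = runif(n) < 0.4, perennial_sargassum = runif(n) < 0.25,
    s_horneri = runif(n) < 0.1, c_sinuosa = runif(n) < 0.7,
    coralline = runif(n) < 0.2,
    bottom_type = factor(sample(c("sand", "cobble"), n, TRUE), c("sand", "cobble")))
  tabs <- tabulate_communities(rec)
  expect_equal(sum(tabs$communities$overall_n), n)
  expect_equal(sum(tabs$communities$sand_n), sum(rec$bottom_type == "sand"))
  expect_equal(sum(tabs$communities$cobble_n), sum(rec$bottom_type == "cobble"))
  # combination rows partition each community's count
  for (i in seq_len(nrow(tabs$communities))) {
    comm <- tabs$communities$community[i]
    expect_equal(sum(tabs$combinations$total_n[tabs$combinations$community == comm]),
                 tabs$communities$overall_n[i])
  }
  # five records of the pure-sinuosa pattern land in the sinuosa community
  rec5 <- data.frame(boulder_id = as.character(1:5), u_pinnatifida = FALSE,
                     perennial_sargassum = FALSE, s_horneri = FALSE,
                     c_sinuosa = TRUE, coralline = FALSE,
                     bottom_type = factor("sand", c("sand", "cobble")))
  t5 <- tabulate_communities(rec5)
  expect_equal(t5$communities$overall_n[t5$communities$community == "c_sinuosa"], 5L)
})
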