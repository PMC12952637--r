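#' Vegetation community levels and scores
#'
#' The seven community types, ordered by vegetation score 0-6. The score
#' ranks community quality by persistence, canopy size and structure: bare
#' rock (0), ephemeral *Colpomenia sinuosa* (1), geniculate coralline red
#' algae (2), annual *Undaria pinnatifida* (3), the large annual *Sargassum
#' horneri* (4), perennial *Sargassum* spp. (5), and the layered perennial
#' *Sargassum* + *U. pinnatifida* community (6).
#' @name community_levels
NULL

.community_levels <- c("bare_rock", "c_sinuosa", "coralline", "u_pinnatifida",
                       "s_horneri", "sargassum", "sargassum_u_pinnatifida")

.community_display <- c(
  bare_rock = "Bare rock",
  c_sinuosa = "C. sinuosa community",
  coralline = "Coralline red algae community",
  u_pinnatifida = "U. pinnatifida community",
  s_horneri = "S. horneri community",
  sargassum = "Sargassum community",
  sargassum_u_pinnatifida = "Sargassum and U. pinnatifida community")

.species_fields <- c("u_pinnatifida", "perennial_sargassum", "s_horneri",
                     "c_sinuosa", "coralline")

.species_display <- c(
  u_pinnatifida = "U. pinnatifida",
  perennial_sargassum = "Perennial Sargassum spp.",
  s_horneri = "S. horneri",
  c_sinuosa = "C. sinuosa",
  coralline = "Geniculate coralline red algae")

#' Classify species presence into a vegetation community and score
#'
#' Deterministic priority cascade over the five presence flags, total over
#' all 32 combinations: perennial *Sargassum* together with *U. pinnatifida*
#' gives score 6; perennial *Sargassum* alone 5; otherwise *S. horneri* 4;
#' otherwise *U. pinnatifida* 3; otherwise coralline algae 2; otherwise
#' *C. sinuosa* 1; nothing present is bare rock, 0. Scores and community
#' labels correspond bijectively.
#'
#' All arguments are logical vectors recycled to a common length.
#'
#' @param u_pinnatifida,perennial_sargassum,s_horneri,c_sinuosa,coralline
#'   presence flags (no `NA`s allowed).
#' @return data.frame with `community` (factor over the seven levels, see
#'   [community_levels]) and integer `score` (0-6).
#' @examples
#' classify_vegetation(TRUE, TRUE, TRUE, TRUE, TRUE)   # score 6
#' classify_vegetation(FALSE, FALSE, FALSE, FALSE, FALSE) # bare rock
#' @export
classify_vegetation <- function(u_pinnatifida, perennial_sargassum, s_horneri,
                                c_sinuosa, coralline) {
  n <- max(length(u_pinnatifida), length(perennial_sargassum),
           length(s_horneri), length(c_sinuosa), length(coralline))
  u <- rep_len(as.logical(u_pinnatifida), n)
  p <- rep_len(as.logical(perennial_sargassum), n)
  h <- rep_len(as.logical(s_horneri), n)
  s <- rep_len(as.logical(c_sinuosa), n)
  r <- rep_len(as.logical(coralline), n)
  if (anyNA(c(u, p, h, s, r))) stop("incomplete presence flags: NA not allowed")
  score <- ifelse(p & u, 6L,
           ifelse(p, 5L,
           ifelse(h, 4L,
           ifelse(u, 3L,
           ifelse(r, 2L,
           ifelse(s, 1L, 0L))))))
  data.frame(community = factor(.community_levels[score + 1L],
                                levels = .community_levels),
             score = as.integer(score))
}

#' Classify a records table in place
#'
#' Adds/overwrites `community` and `score` columns computed from the five
#' presence columns.
#'
#' @param records data.frame with logical columns `u_pinnatifida`,
#'   `perennial_sargassum`, `s_horneri`, `c_sinuosa`, `coralline`.
#' @return `records` with `community` and `score` columns.
#' @export
classify_records <- function(records) {
  miss <- setdiff(.species_fields, names(records))
  if (length(miss)) stop("records missing presence columns: ",
                         paste(miss, collapse = ", "))
  cl <- classify_vegetation(records$u_pinnatifida, records$perennial_sargassum,
                            records$s_horneri, records$c_sinuosa,
                            records$coralline)
  records$community <- cl$community
  records$score <- cl$score
  records
}

#' Rich/poor dichotomy of the vegetation score
#'
#' Binarises the ordinal score: >= 3 is rich (annual/perennial canopy
#' formers present), <= 2 is poor (bare rock, ephemeral or crustose cover).
#'
#' @param score integer vector with values in 0-6.
#' @return factor with levels `poor`, `rich`.
#' @export
richness_dichotomy <- function(score) {
  score <- as.integer(score)
  if (anyNA(score) || any(score < 0L | score > 6L)) {
    stop("score out of range: must be an integer in 0..6")
  }
  factor(ifelse(score >= 3L, "rich", "poor"), levels = c("poor", "rich"))
}

.s8_columns <- c(
  u_pinnatifida = "U. pinnatifida",
  perennial_sargassum = "Perennial Sargassum spp.",
  s_horneri = "S. horneri",
  c_sinuosa = "C. sinuosa",
  coralline = "Geniculate coralline red algae",
  bottom_type = "Bottom type",
  community = "Vegetation type",
  relative_height = "Relative Height",
  surface_complexity = "Surface Complexity")

.parse_presence_token <- function(x, col) {
  x <- trimws(x)
  out <- rep(NA, length(x))
  out[x == "+"] <- TRUE
  out[x %in% c("-", "−", "–")] <- FALSE  # ascii, minus, en dash
  bad <- unique(x[is.na(out)])
  if (length(bad)) {
    stop("unknown presence token in column '", col, "': ",
         paste(sQuote(bad), collapse = ", "))
  }
  as.logical(out)
}

#' Read a species-presence table (S8 schema)
#'
#' The schema has one row per boulder and columns `U. pinnatifida`,
#' `Perennial Sargassum spp.`, `S. horneri`, `C. sinuosa`, `Geniculate
#' coralline red algae` (presence as `"+"` / `"-"`, with the Unicode minus
#' accepted), `Bottom type` (`sand`/`cobble`), and optionally `Vegetation
#' type`, `Relative Height` and `Surface Complexity`. Lines starting with
#' `#` are treated as comments.
#'
#' @param path CSV path (UTF-8).
#' @return data.frame of records: `boulder_id` (from an id column when
#'   present, else the row number), logical presence columns, `bottom_type`
#'   factor, and numeric `relative_height` / `surface_complexity` when the
#'   file carries them.
#' @export
read_s8_table <- function(path) {
  if (!file.exists(path)) stop("presence table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", comment.char = "#")
  need <- .s8_columns[c(.species_fields, "bottom_type")]
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("presence CSV missing column(s): ",
                         paste(sQuote(miss), collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    boulder_id = if ("boulder_id" %in% names(df)) as.character(df$boulder_id)
                 else as.character(seq_len(nrow(df))))
  for (f in .species_fields) {
    out[[f]] <- .parse_presence_token(df[[.s8_columns[[f]]]], .s8_columns[[f]])
  }
  bt <- tolower(trimws(df[[.s8_columns[["bottom_type"]]]]))
  bad <- setdiff(unique(bt), c("sand", "cobble"))
  if (length(bad)) stop("unknown bottom type: ", paste(sQuote(bad), collapse = ", "))
  out$bottom_type <- factor(bt, c("sand", "cobble"))
  for (f in c("relative_height", "surface_complexity")) {
    col <- .s8_columns[[f]]
    if (col %in% names(df)) out[[f]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  out
}

#' Write records in the S8 schema
#'
#' Presence is written as ASCII `"+"` / `"-"` (noted in a leading comment
#' line); community labels use their display names; indicator columns are
#' written when present (blank when `NA`).
#'
#' @param records records table (see [read_s8_table()]); classified columns
#'   are recomputed if absent.
#' @param path output CSV path.
#' @export
write_s8_table <- function(records, path) {
  if (!"community" %in% names(records)) records <- classify_records(records)
  tok <- function(x) ifelse(x, "+", "-")
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    boulder_id = records$boulder_id)
  for (f in .species_fields) df[[.s8_columns[[f]]]] <- tok(records[[f]])
  df[[.s8_columns[["bottom_type"]]]] <- as.character(records$bottom_type)
  df[[.s8_columns[["community"]]]] <-
    unname(.community_display[as.character(records$community)])
  for (f in c("relative_height", "surface_complexity")) {
    if (f %in% names(records)) {
      df[[.s8_columns[[f]]]] <- ifelse(is.na(records[[f]]), "",
                                       format(records[[f]], digits = 10))
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# presence coded as ASCII '+' (present) / '-' (absent)", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-species prevalence table
#'
#' Counts and percentages of boulders on which each of the five scored taxa
#' was present, overall and stratified by bottom type. Percentages are
#' rounded half-up to one decimal.
#'
#' @param records records table with presence columns and `bottom_type`.
#' @return data.frame, one row per species.
#' @export
tabulate_prevalence <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  strata <- list(overall = rep(TRUE, nrow(records)),
                 sand = records$bottom_type == "sand",
                 cobble = records$bottom_type == "cobble")
  out <- data.frame(species = unname(.species_display[.species_fields]),
                    stringsAsFactors = FALSE)
  for (s in names(strata)) {
    sel <- strata[[s]]
    n <- sum(sel)
    cnt <- vapply(.species_fields, function(f) sum(records[[f]][sel]), 0L)
    out[[paste0(s, "_n")]] <- unname(cnt)
    out[[paste0(s, "_pct")]] <-
      if (n > 0) .round_half_up(100 * unname(cnt) / n, 1L) else NA_real_
  }
  attr(out, "totals") <- vapply(strata, sum, 0L)
  out
}

#' Community and combination tables
#'
#' Counts and percentages per community type (overall and by bottom type),
#' plus the per-combination breakdown: one row per observed 5-flag presence
#' pattern with sand/cobble/total counts and the community it classifies to.
#'
#' @param records records table; classified columns are recomputed if absent.
#' @return list with `communities` (one row per community, descending score)
#'   and `combinations` data.frames.
#' @export
tabulate_communities <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  if (!"community" %in% names(records)) records <- classify_records(records)
  strata <- list(overall = rep(TRUE, nrow(records)),
                 sand = records$bottom_type == "sand",
                 cobble = records$bottom_type == "cobble")
  lev <- rev(.community_levels)  # descending score, like the published layout
  comm <- data.frame(community = lev, score = 6:0,
                     label = unname(.community_display[lev]),
                     stringsAsFactors = FALSE)
  for (s in names(strata)) {
    sel <- strata[[s]]
    n <- sum(sel)
    cnt <- as.integer(table(factor(records$community[sel], levels = lev)))
    comm[[paste0(s, "_n")]] <- cnt
    comm[[paste0(s, "_pct")]] <-
      if (n > 0) .round_half_up(100 * cnt / n, 1L) else NA_real_
  }
  pat <- do.call(paste, c(lapply(.species_fields, function(f)
    ifelse(records[[f]], "+", "-")), list(sep = "")))
  agg <- data.frame(pattern = pat,
                    sand = records$bottom_type == "sand",
                    community = records$community, score = records$score)
  u <- unique(agg[, c("pattern", "community", "score")])
  u$sand_n <- vapply(u$pattern, function(p) sum(agg$pattern == p & agg$sand), 0L)
  u$cobble_n <- vapply(u$pattern, function(p) sum(agg$pattern == p & !agg$sand), 0L)
  u$total_n <- u$sand_n + u$cobble_n
  u <- u[order(-u$score, u$pattern, method = "radix"), , drop = FALSE]
  rownames(u) <- NULL
  list(communities = comm, combinations = u)
}
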