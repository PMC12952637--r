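#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (wrapping [stats::t.test()]).
#'
#' @param a,b numeric samples (each of size >= 2, finite values; at least one
#'   sample must have nonzero variance).
#' @return list of class `welch_test`: `statistic`, `df`, `p_value`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite sample values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      stop("undefined t statistic: both samples constant with equal means")
    }
    stop("undefined t statistic: both samples have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.2f, p = %.4g (n = %d, %d)\n",
              x$statistic, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Product-moment correlation with the two-sided t-based p-value
#' (wrapping [stats::cor.test()]).
#'
#' @param x,y equal-length numeric samples (n >= 3, both with nonzero
#'   variance).
#' @return list of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite sample values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant sample")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p_value = unname(ht$p.value),
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Mean vegetation score per bottom type
#'
#' @param records classified records with `score` and `bottom_type`.
#' @return list with full-precision `mean_sand` / `mean_cobble`, half-up
#'   1-decimal `rounded` pair, and group sizes `n_sand` / `n_cobble`.
#' @export
mean_scores_by_bottom <- function(records) {
  if (!"score" %in% names(records)) records <- classify_records(records)
  sand <- records$score[records$bottom_type == "sand"]
  cobble <- records$score[records$bottom_type == "cobble"]
  if (length(sand) == 0L) stop("no sand records")
  if (length(cobble) == 0L) stop("no cobble records")
  list(mean_sand = mean(sand), mean_cobble = mean(cobble),
       rounded = c(sand = .round_half_up(mean(sand), 1L),
                   cobble = .round_half_up(mean(cobble), 1L)),
       n_sand = length(sand), n_cobble = length(cobble))
}

.try_cor <- function(x, y) {
  tryCatch(pearson_r(x, y), error = function(e) NULL)
}

.try_welch <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NULL)
  tryCatch(welch_t(a, b), error = function(e) NULL)
}

#' Run the full vegetation-geomorphology analysis
#'
#' Assembles the complete analysis over a classified record table: species
#' prevalence and community tables, mean vegetation score per bottom type
#' with a Welch's t-test of sand vs cobble scores, Pearson correlations of
#' score against each geomorphic indicator (overall and within each bottom
#' type), and Welch's t-tests comparing each indicator between rich
#' (score >= 3) and poor (score <= 2) boulders within each bottom type.
#' The correlation / rich-poor block uses only records with valid indicator
#' values and is skipped with a warning when the table carries no indicators.
#' All p-values are raw (two-sided, no multiplicity correction).
#'
#' @param records records table: presence columns, `bottom_type`, optional
#'   `relative_height`, `surface_complexity` (and `valid` flag).
#' @return object of class `reef_analysis`.
#' @export
run_full_analysis <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  records <- classify_records(records)
  prev <- tabulate_prevalence(records)
  comm <- tabulate_communities(records)
  means <- mean_scores_by_bottom(records)
  score_test <- welch_t(records$score[records$bottom_type == "sand"],
                        records$score[records$bottom_type == "cobble"])

  has_ind <- all(c("relative_height", "surface_complexity") %in% names(records)) &&
    any(stats::complete.cases(records[, c("relative_height", "surface_complexity")]))
  correlations <- NULL
  richpoor <- NULL
  n_valid <- 0L
  if (has_ind) {
    ok <- stats::complete.cases(records[, c("relative_height", "surface_complexity")])
    if ("valid" %in% names(records)) ok <- ok & records$valid %in% TRUE
    rv <- records[ok, , drop = FALSE]
    n_valid <- nrow(rv)
    strata <- list(overall = rep(TRUE, nrow(rv)),
                   sand = rv$bottom_type == "sand",
                   cobble = rv$bottom_type == "cobble")
    correlations <- list()
    for (ind in c("relative_height", "surface_complexity")) {
      for (s in names(strata)) {
        sel <- strata[[s]]
        correlations[[paste(ind, s, sep = ".")]] <-
          .try_cor(rv$score[sel], rv[[ind]][sel])
      }
    }
    rich <- richness_dichotomy(rv$score)
    richpoor <- list()
    for (ind in c("relative_height", "surface_complexity")) {
      for (s in c("sand", "cobble")) {
        sel <- strata[[s]]
        richpoor[[paste(ind, s, sep = ".")]] <-
          .try_welch(rv[[ind]][sel & rich == "rich"],
                     rv[[ind]][sel & rich == "poor"])
      }
    }
  } else {
    warning("records carry no geomorphic indicators: ",
            "correlation and rich/poor blocks skipped")
  }

  structure(list(
    n = nrow(records),
    n_sand = sum(records$bottom_type == "sand"),
    n_cobble = sum(records$bottom_type == "cobble"),
    n_valid_indicators = n_valid,
    prevalence = prev,
    communities = comm$communities,
    combinations = comm$combinations,
    mean_scores = means,
    score_test = score_test,
    correlations = correlations,
    rich_poor = richpoor,
    records = records), class = "reef_analysis")
}

#' @export
print.reef_analysis <- function(x, ...) {
  cat(sprintf("Boulder-reef vegetation analysis: %d boulders (%d sand, %d cobble)\n\n",
              x$n, x$n_sand, x$n_cobble))
  cat("Species prevalence (n, % of stratum):\n")
  p <- x$prevalence
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-30s total %4d (%5.1f%%)  sand %4d (%5.1f%%)  cobble %4d (%5.1f%%)\n",
                p$species[i], p$overall_n[i], p$overall_pct[i],
                p$sand_n[i], p$sand_pct[i], p$cobble_n[i], p$cobble_pct[i]))
  }
  cat("\nVegetation communities (n, % of stratum):\n")
  cm <- x$communities
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  [%d] %-40s total %4d (%5.1f%%)  sand %4d  cobble %4d\n",
                cm$score[i], cm$label[i], cm$overall_n[i], cm$overall_pct[i],
                cm$sand_n[i], cm$cobble_n[i]))
  }
  ms <- x$mean_scores
  cat(sprintf("\nMean vegetation score: sand %.1f (n=%d), cobble %.1f (n=%d)\n",
              ms$rounded["sand"], ms$n_sand, ms$rounded["cobble"], ms$n_cobble))
  st <- x$score_test
  cat(sprintf("  Welch's t-test sand vs cobble: t = %.3f, df = %.1f, p = %s\n",
              st$statistic, st$df, format.pval(st$p_value, digits = 3)))
  if (!is.null(x$correlations)) {
    cat(sprintf("\nScore vs geomorphic indicators (%d boulders with valid indicators):\n",
                x$n_valid_indicators))
    for (nm in names(x$correlations)) {
      cr <- x$correlations[[nm]]
      if (is.null(cr)) next
      cat(sprintf("  %-32s r = %6.3f, p = %s (n = %d)\n", nm, cr$r,
                  format.pval(cr$p_value, digits = 3), cr$n))
    }
    cat("\nRich (score >= 3) vs poor (score <= 2), indicator comparisons:\n")
    for (nm in names(x$rich_poor)) {
      w <- x$rich_poor[[nm]]
      if (is.null(w)) {
        cat(sprintf("  %-32s not testable (group too small)\n", nm))
      } else {
        cat(sprintf("  %-32s t = %6.3f, df = %6.1f, p = %s (rich %d, poor %d)\n",
                    nm, w$statistic, w$df, format.pval(w$p_value, digits = 3),
                    w$n_a, w$n_b))
      }
    }
  } else {
    cat("\n(no geomorphic indicators supplied; correlation block omitted)\n")
  }
  cat("\nAll p-values are raw two-sided values; no multiplicity correction.\n")
  invisible(x)
}

#' @export
summary.reef_analysis <- function(object, ...) {
  s <- list(
    n = object$n, n_sand = object$n_sand, n_cobble = object$n_cobble,
    mean_score_sand = object$mean_scores$mean_sand,
    mean_score_cobble = object$mean_scores$mean_cobble,
    score_test_p = object$score_test$p_value,
    correlations = if (is.null(object$correlations)) NULL else
      do.call(rbind, lapply(names(object$correlations), function(nm) {
        cr <- object$correlations[[nm]]
        if (is.null(cr)) return(NULL)
        data.frame(comparison = nm, r = cr$r, p_value = cr$p_value, n = cr$n)
      })))
  class(s) <- "summary.reef_analysis"
  s
}

#' @export
print.summary.reef_analysis <- function(x, ...) {
  cat(sprintf("reef_analysis: %d boulders (%d sand / %d cobble)\n",
              x$n, x$n_sand, x$n_cobble))
  cat(sprintf("mean score sand %.2f vs cobble %.2f (Welch p = %s)\n",
              x$mean_score_sand, x$mean_score_cobble,
              format.pval(x$score_test_p, digits = 3)))
  if (!is.null(x$correlations)) {
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Histograms of vegetation scores by bottom type
#'
#' @param x a `reef_analysis`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.reef_analysis <- function(x, ...) {
  rec <- x$records
  tab <- rbind(sand = table(factor(rec$score[rec$bottom_type == "sand"], 0:6)),
               cobble = table(factor(rec$score[rec$bottom_type == "cobble"], 0:6)))
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(tab["sand", ], main = "Sandy bottom",
                    xlab = "Vegetation score", ylab = "Boulders", ...)
  graphics::barplot(tab["cobble", ], main = "Cobble/boulder bottom",
                    xlab = "Vegetation score", ylab = "Boulders", ...)
  invisible(x)
}

.test_to_list <- function(w) {
  if (is.null(w)) return(NULL)
  unclass(w)
}

#' Serialise an analysis report
#'
#' `report_json()` writes the full report as structured JSON;
#' `report_text()` writes the human-readable summary (the `print` output).
#'
#' @param analysis a `reef_analysis`.
#' @param path output path.
#' @export
report_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "reef_analysis"))
  out <- list(
    n = analysis$n, n_sand = analysis$n_sand, n_cobble = analysis$n_cobble,
    n_valid_indicators = analysis$n_valid_indicators,
    prevalence = analysis$prevalence,
    communities = analysis$communities,
    combinations = analysis$combinations,
    mean_scores = analysis$mean_scores,
    score_test = .test_to_list(analysis$score_test),
    correlations = lapply(analysis$correlations, .test_to_list),
    rich_poor = lapply(analysis$rich_poor, .test_to_list),
    note = "raw two-sided p-values; no multiplicity correction")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname report_json
#' @export
report_text <- function(analysis, path) {
  stopifnot(inherits(analysis, "reef_analysis"))
  txt <- utils::capture.output(print(analysis))
  writeLines(txt, path)
  invisible(path)
}
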