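#' Pearson and Spearman correlation with degenerate-input flagging
#'
#' Thin wrappers around [stats::cor()] that return `NA` (with a warning)
#' instead of propagating `NaN` when either vector is constant, and insist on
#' complete pairs of length >= 3. Spearman uses mid-ranks for ties (the
#' [stats::cor()] convention).
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return the correlation coefficient in \[-1, 1\], with attribute `"n"`
#'   (complete pairs used), or `NA` if undefined.
#' @export
pearson_r <- function(x, y) .cor_flagged(x, y, "pearson")

#' @rdname pearson_r
#' @export
spearman_r <- function(x, y) .cor_flagged(x, y, "spearman")

.cor_flagged <- function(x, y, method) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("correlation undefined: zero variance")
    return(structure(NA_real_, n = length(x)))
  }
  structure(stats::cor(x, y, method = method), n = length(x))
}

#' Activity-class counts
#'
#' Counts of guides with mean efficiency strictly above `hi` and strictly
#' below `lo` percent. The inequalities are strict: a mean of exactly `hi`
#' or `lo` falls in neither class.
#'
#' @param guides a `guide_set`.
#' @param hi,lo class thresholds in percent.
#' @return list with `n_high`, `n_low`, `n_total`.
#' @export
class_counts <- function(guides, hi = 75, lo = 25) {
  stopifnot(inherits(guides, "guide_set"))
  m <- guides$mean_efficiency
  list(n_high = sum(m > hi), n_low = sum(m < lo), n_total = length(m))
}

#' GC content versus efficiency
#'
#' GC percentage is computed over protospacer positions 1-20 only (the PAM
#' is excluded) and correlated (Pearson) with mean efficiency.
#'
#' @param guides a `guide_set` with >= 3 guides.
#' @return list with `gc_percent` (named per guide), `gc_range`, `r`, `p`
#'   and `n`; `r`/`p` are `NA` (flagged by warning) when GC is constant.
#' @export
gc_association <- function(guides) {
  stopifnot(inherits(guides, "guide_set"))
  if (nrow(guides) < 3L) stop("need at least 3 guides")
  gc <- vapply(strsplit(guides$protospacer, "", fixed = TRUE),
               function(ch) 100 * sum(ch %in% c("G", "C")) / 20, 0)
  names(gc) <- guides$name
  if (stats::var(gc) == 0 || stats::var(guides$mean_efficiency) == 0) {
    warning("GC association undefined: zero variance")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(gc, guides$mean_efficiency, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(gc_percent = gc, gc_range = range(gc), r = r, p = p, n = length(gc))
}

#' Sense versus antisense strand test
#'
#' Pooled two-sample Student's t test (two-sided) on mean efficiencies
#' grouped by the target strand. Undefined (flagged with `defined = FALSE`)
#' when either strand has fewer than 2 guides.
#'
#' @param guides a `guide_set` with a `strand` column.
#' @return list with `t`, `df`, `p`, `defined`, `n_sense`, `n_antisense`.
#' @export
strand_test <- function(guides) {
  stopifnot(inherits(guides, "guide_set"))
  m <- guides$mean_efficiency
  s <- m[!is.na(guides$strand) & guides$strand == "sense"]
  a <- m[!is.na(guides$strand) & guides$strand == "antisense"]
  res <- if (length(s) < 2L || length(a) < 2L) {
    list(t = NA_real_, df = NA_real_, p = NA_real_, defined = FALSE)
  } else {
    kp_t_test(s, a)
  }
  c(res, list(n_sense = length(s), n_antisense = length(a)))
}

#' Benchmark external design-tool scores against measured efficiency
#'
#' Joins per-guide tool scores to the set by guide name and reports the
#' Spearman rank correlation of each tool's scores with measured mean
#' efficiencies, dropping missing scores pairwise. Tools joining fewer than
#' 3 guides or with constant scores are excluded with a warning.
#'
#' @param guides a `guide_set`.
#' @param tool_scores data frame with a `name` column plus one numeric
#'   column per tool.
#' @param tools which tool columns to use; default all non-`name` columns.
#' @return data frame with columns `tool`, `r_spearman`, `n`.
#' @export
compare_tools <- function(guides, tool_scores, tools = NULL) {
  stopifnot(inherits(guides, "guide_set"), is.data.frame(tool_scores))
  if (!"name" %in% names(tool_scores)) {
    stop("tool_scores must have a 'name' column")
  }
  if (is.null(tools)) tools <- setdiff(names(tool_scores), "name")
  idx <- match(guides$name, tool_scores$name)
  rows <- list()
  for (tool in tools) {
    sc <- suppressWarnings(as.numeric(tool_scores[[tool]]))[idx]
    ok <- is.finite(sc)
    if (sum(ok) < 3L) {
      warning("tool '", tool, "' joins fewer than 3 guides; excluded")
      next
    }
    if (stats::var(sc[ok]) == 0) {
      warning("tool '", tool, "' has constant scores; excluded")
      next
    }
    r <- suppressWarnings(spearman_r(sc[ok], guides$mean_efficiency[ok]))
    rows[[tool]] <- data.frame(tool = tool, r_spearman = as.numeric(r),
                               n = sum(ok), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(tool = character(), r_spearman = numeric(),
                      n = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset-level evaluation report
#'
#' Bundles the quantitative summaries of a guide-efficiency study: summary
#' statistics and activity-class counts, the GC-content and strand checks,
#' optional cross-condition correlations (e.g. two Cas9 variants measured on
#' the same guides, matched by name), and optional design-tool benchmarking.
#' When a fitted model is supplied, its CRISPR-kp scores for the set are
#' correlated too; on the model's own training set this is labelled
#' in-sample.
#'
#' @param guides a `guide_set`.
#' @param guides2 optional second `guide_set` on the same guides (matched by
#'   name) for cross-condition Pearson/Spearman correlations.
#' @param tool_scores optional data frame for [compare_tools()].
#' @param fit optional `"crisprkp"` model to score `guides` with.
#' @param in_sample logical: was `fit` trained on `guides`? Labelled in the
#'   report to discourage over-reading in-sample correlations.
#' @return an object of class `"kp_evaluation"` (a list) with a print
#'   method.
#' @export
evaluate_guides <- function(guides, guides2 = NULL, tool_scores = NULL,
                            fit = NULL, in_sample = FALSE) {
  stopifnot(inherits(guides, "guide_set"))
  report <- list(
    condition = attr(guides, "condition_label"),
    n = nrow(guides),
    mean_efficiency = mean(guides$mean_efficiency),
    class_counts = class_counts(guides),
    gc = gc_association(guides),
    strand = strand_test(guides),
    cross_condition = NULL, tools = NULL, kp = NULL
  )
  if (!is.null(guides2)) {
    stopifnot(inherits(guides2, "guide_set"))
    common <- intersect(guides$name, guides2$name)
    if (length(common) < 3L) stop("fewer than 3 guides shared by name")
    x <- guides$mean_efficiency[match(common, guides$name)]
    y <- guides2$mean_efficiency[match(common, guides2$name)]
    report$cross_condition <- list(
      label_x = attr(guides, "condition_label"),
      label_y = attr(guides2, "condition_label"),
      r_pearson = as.numeric(pearson_r(x, y)),
      r_spearman = as.numeric(spearman_r(x, y)),
      n = length(common)
    )
  }
  if (!is.null(tool_scores)) {
    report$tools <- compare_tools(guides, tool_scores)
  }
  if (!is.null(fit)) {
    scores <- predict(fit, guides)
    report$kp <- list(
      r_spearman = as.numeric(spearman_r(scores, guides$mean_efficiency)),
      n = nrow(guides),
      in_sample = in_sample,
      score_range = range(scores)
    )
  }
  class(report) <- "kp_evaluation"
  report
}

#' @export
print.kp_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation%s: n = %d crRNAs\n",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$n))
  cat(sprintf("  mean efficiency: %.1f%%; >75%%: %d, <25%%: %d\n",
              x$mean_efficiency, x$class_counts$n_high, x$class_counts$n_low))
  cat(sprintf("  GC content (positions 1-20): %.0f-%.0f%%, r = %s (p = %s)\n",
              x$gc$gc_range[1], x$gc$gc_range[2],
              .fmt(x$gc$r), .fmt(x$gc$p)))
  if (isTRUE(x$strand$defined)) {
    cat(sprintf("  sense (%d) vs antisense (%d): Student's p = %.3f\n",
                x$strand$n_sense, x$strand$n_antisense, x$strand$p))
  } else {
    cat(sprintf("  strand test undefined (sense %d, antisense %d)\n",
                x$strand$n_sense, x$strand$n_antisense))
  }
  if (!is.null(x$cross_condition)) {
    cc <- x$cross_condition
    cat(sprintf("  %s vs %s (n = %d): r_p = %.3f, r_s = %.3f\n",
                cc$label_x, cc$label_y, cc$n, cc$r_pearson, cc$r_spearman))
  }
  if (!is.null(x$tools) && nrow(x$tools)) {
    cat("  design-tool Spearman r vs measured efficiency:\n")
    cat(sprintf("    %-20s r_s = %+.3f (n = %d)\n",
                x$tools$tool, x$tools$r_spearman, x$tools$n), sep = "")
  }
  if (!is.null(x$kp)) {
    cat(sprintf("  CRISPR-kp%s: r_s = %.3f (n = %d), scores in [%.1f, %.1f]\n",
                if (x$kp$in_sample) " (in-sample)" else "",
                x$kp$r_spearman, x$kp$n,
                x$kp$score_range[1], x$kp$score_range[2]))
  }
  invisible(x)
}

.fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
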