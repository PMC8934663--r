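#' @export
print.crisprkp <- function(x, ...) {
  cat("Position-specific mononucleotide feature model\n")
  if (nzchar(x$condition)) cat(sprintf("  condition: %s\n", x$condition))
  cat(sprintf("  guides: %d (weights: %s), test: %s %s\n",
              x$n_guides, x$weight_source, x$test, x$alternative))
  tf <- top_features(x, 5)
  if (nrow(tf)) {
    cat("  top features:\n")
    cat(sprintf("    %2d-%s (%s)  p = %.3g  score = %+.2f\n",
                tf$position, tf$nucleotide, tf$direction, tf$p,
                tf$signed_score), sep = "")
  } else {
    cat("  no informative features (all p >= 1)\n")
  }
  invisible(x)
}

#' @export
summary.crisprkp <- function(object, k = 10, ...) {
  f <- object$features
  defined <- !is.na(object$features$p)
  structure(list(
    condition = object$condition,
    n_guides = object$n_guides,
    test = object$test,
    alternative = object$alternative,
    n_defined = sum(defined),
    n_sig = table(factor(f$sig_flag[defined],
                         levels = c("none", "p<0.0125", "p<0.0025"))),
    top = top_features(object, k),
    score_extrema = kp_score_extrema(object)
  ), class = "summary.crisprkp")
}

#' @export
print.summary.crisprkp <- function(x, ...) {
  cat(sprintf("Feature model%s: %d guides, %s %s t test\n",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$n_guides, x$test, x$alternative))
  cat(sprintf("  %d of 92 cells defined; significant after per-position Bonferroni: %d at p<0.0125, %d at p<0.0025\n",
              x$n_defined, x$n_sig[["p<0.0125"]], x$n_sig[["p<0.0025"]]))
  cat(sprintf("  attainable CRISPR-kp score range: [%.1f, %.1f]\n",
              x$score_extrema[1], x$score_extrema[2]))
  if (nrow(x$top)) {
    cat("  top features:\n")
    print(x$top[, c("position", "nucleotide", "direction", "t", "p",
                    "signed_score", "sig_flag")], row.names = FALSE,
          digits = 4)
  }
  invisible(x)
}

#' Signed-score matrix of a fitted feature model
#'
#' @param object a `"crisprkp"` fit.
#' @param ... unused.
#' @return a 4 x 23 numeric matrix (rows A/C/G/T, columns positions 1-23) of
#'   signed `-log10(p)` scores; undefined cells are 0.
#' @export
coef.crisprkp <- function(object, ...) {
  f <- object$features
  m <- matrix(0, nrow = 4, ncol = N_POSITIONS,
              dimnames = list(NUCLEOTIDES, as.character(seq_len(N_POSITIONS))))
  m[cbind(match(f$nucleotide, NUCLEOTIDES), f$position)] <- f$signed_score
  m
}

# validate query targets; N allowed only at position 21
.validate_queries <- function(sequences) {
  sequences <- toupper(as.character(sequences))
  problem <- function(s) {
    if (is.na(s)) return("missing sequence")
    if (nchar(s) != 23L) return("not 23 nt")
    if (substr(s, 22, 23) != "GG") return("PAM positions 22-23 must be GG")
    if (grepl("[^ACGT]", substr(s, 1, 20))) {
      return("protospacer positions 1-20 must be A/C/G/T")
    }
    if (!substr(s, 21, 21) %in% c(NUCLEOTIDES, "N")) {
      return("PAM position 21 must be A/C/G/T or N")
    }
    NA_character_
  }
  vapply(sequences, problem, "", USE.NAMES = FALSE)
}

#' Score sequences against a signed-score matrix
#'
#' The lookup-and-sum at the heart of the CRISPR-kp score: for each position
#' 1-23, take the signed score of the (position, nucleotide) cell the query
#' selects and sum. An `N` at PAM position 21 contributes 0; positions 22-23
#' contribute whatever the matrix holds there (0 for a fitted model, since
#' those cells are undefined).
#'
#' @param scores a 4 x 23 matrix as returned by [coef.crisprkp()] or read
#'   back by [read_scoring_table()].
#' @param sequences character vector of 23-nt targets (protospacer + NGG).
#' @return numeric matrix, one row per sequence, 23 contribution columns and
#'   attribute `"total"` with the row sums.
#' @export
kp_score_sequences <- function(scores, sequences) {
  stopifnot(is.matrix(scores), nrow(scores) == 4, ncol(scores) == N_POSITIONS)
  sequences <- toupper(as.character(sequences))
  bad <- .validate_queries(sequences)
  if (any(!is.na(bad))) {
    stop("invalid query sequence(s): ",
         paste(sprintf("row %d (%s)", which(!is.na(bad)),
                       bad[!is.na(bad)]), collapse = "; "))
  }
  n <- length(sequences)
  contrib <- matrix(0, nrow = n, ncol = N_POSITIONS,
                    dimnames = list(NULL, paste0("pos", seq_len(N_POSITIONS))))
  if (n) {
    chars <- .sequence_matrix(sequences)
    nt_idx <- match(chars, rownames(scores))       # N -> NA -> 0 contribution
    pos_idx <- rep(seq_len(N_POSITIONS), each = n)
    ok <- !is.na(nt_idx)
    contrib[ok] <- scores[cbind(nt_idx[ok], pos_idx[ok])]
  }
  attr(contrib, "total") <- rowSums(contrib)
  contrib
}

#' Predict CRISPR-kp scores for new target sequences
#'
#' @param object a `"crisprkp"` fit.
#' @param newdata a character vector of 23-nt targets (protospacer + NGG
#'   PAM; `N` accepted at position 21) or a `guide_set`.
#' @param type `"total"` for the summed score per query (the CRISPR-kp
#'   score), `"breakdown"` for a data frame with the 23 per-position
#'   contributions alongside the total.
#' @param ... unused.
#' @return numeric vector of scores, or a breakdown data frame.
#' @examples
#' sim <- simulate_guides(kp_sim_config(n_guides = 30), seed = 7)
#' fit <- crisprkp(sim$guides)
#' predict(fit, target_sequences(sim$guides)[1:3])
#' @export
predict.crisprkp <- function(object, newdata,
                             type = c("total", "breakdown"), ...) {
  type <- match.arg(type)
  nm <- NULL
  if (inherits(newdata, "guide_set")) {
    nm <- newdata$name
    newdata <- target_sequences(newdata)
  } else if (!is.null(names(newdata))) {
    nm <- names(newdata)
  }
  sequences <- toupper(as.character(newdata))
  contrib <- kp_score_sequences(coef(object), sequences)
  total <- attr(contrib, "total")
  if (type == "total") {
    return(stats::setNames(total, nm))
  }
  out <- data.frame(
    name = if (is.null(nm)) paste0("query", seq_along(sequences)) else nm,
    sequence = sequences, total = total,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(unclass(contrib)))
}

#' Score a batch of queries, tolerating invalid rows
#'
#' Unlike [predict.crisprkp()], which rejects the whole batch on any invalid
#' query, this scores the valid rows and reports the invalid ones (by row
#' number, with the reason) in a warning, leaving their scores `NA`.
#'
#' @param object a `"crisprkp"` fit.
#' @param sequences character vector of query targets.
#' @param names optional query names.
#' @return data frame with columns `name`, `sequence`, `valid`, `total` and
#'   23 per-position contribution columns (`NA` for invalid rows).
#' @export
kp_score_table <- function(object, sequences, names = NULL) {
  sequences <- toupper(as.character(sequences))
  if (is.null(names)) {
    names <- if (!is.null(base::names(sequences))) base::names(sequences)
             else sprintf("query%d", seq_along(sequences))
  }
  bad <- .validate_queries(sequences)
  if (any(!is.na(bad))) {
    warning("skipping invalid query row(s): ",
            paste(sprintf("%d (%s)", which(!is.na(bad)), bad[!is.na(bad)]),
                  collapse = "; "))
  }
  contrib <- matrix(NA_real_, nrow = length(sequences), ncol = N_POSITIONS,
                    dimnames = list(NULL, paste0("pos", seq_len(N_POSITIONS))))
  total <- rep(NA_real_, length(sequences))
  ok <- is.na(bad)
  if (any(ok)) {
    sc <- kp_score_sequences(coef(object), sequences[ok])
    contrib[ok, ] <- sc
    total[ok] <- attr(sc, "total")
  }
  cbind(
    data.frame(name = names, sequence = sequences, valid = ok, total = total,
               stringsAsFactors = FALSE),
    as.data.frame(contrib)
  )
}

#' Attainable score range of a fitted model
#'
#' Minimum and maximum CRISPR-kp total over all valid 23-nt queries: the sum
#' over positions of the per-position minimum / maximum signed score
#' (undefined cells contribute 0 and positions 22-23 are fixed GG).
#'
#' @param object a `"crisprkp"` fit.
#' @return numeric vector `c(min, max)`.
#' @export
kp_score_extrema <- function(object) {
  m <- coef(object)
  # at positions 22-23 only G is selectable; elsewhere any nucleotide
  lo <- sum(apply(m[, 1:21, drop = FALSE], 2, min)) + m["G", 22] + m["G", 23]
  hi <- sum(apply(m[, 1:21, drop = FALSE], 2, max)) + m["G", 22] + m["G", 23]
  c(min = lo, max = hi)
}

#' Plot a fitted feature model
#'
#' A text-logo-style display: at each target position the four nucleotides
#' are drawn at their signed `-log10(p)` scores, favored above and disfavored
#' below the axis, with per-position Bonferroni-significant cells emphasised.
#'
#' @param x a `"crisprkp"` fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.crisprkp <- function(x, ...) {
  f <- x$features
  cols <- c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00", T = "#e31a1c")
  ylim <- range(0, f$signed_score, na.rm = TRUE) * 1.15
  graphics::plot(NA, xlim = c(0.5, N_POSITIONS + 0.5), ylim = ylim,
                 xlab = "target position (1-20 protospacer, 21-23 PAM)",
                 ylab = expression(sign %*% -log[10](italic(p))),
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_len(N_POSITIONS))
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(v = 20.5, lty = 2, col = "grey60")
  defined <- f[!is.na(f$p), ]
  graphics::text(defined$position, defined$signed_score, defined$nucleotide,
                 col = cols[defined$nucleotide],
                 font = ifelse(defined$sig_flag == "none", 1, 2),
                 cex = ifelse(defined$sig_flag == "none", 0.8, 1.1))
  invisible(x)
}
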