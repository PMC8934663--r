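NUCLEOTIDES <- c("A", "C", "G", "T")
N_POSITIONS <- 23L
P_FLOOR <- 1e-300  # floor before -log10 so scores stay finite

#' Fit a position-specific mononucleotide feature model
#'
#' For every cell of the 4 nucleotides x 23 positions grid over the full
#' target (20-nt protospacer + NGG PAM), guides carrying that nucleotide at
#' that position are compared against the remaining guides by a two-sample
#' Student's t test on their mean indel frequencies. Each defined cell gets a
#' direction (favored when carriers are more efficient, disfavored when
#' less), a two-sided p-value, a signed score `sign(t) * -log10(p)`, and a
#' per-position Bonferroni significance flag (thresholds 0.05/4 = 0.0125 and
#' 0.01/4 = 0.0025, four nucleotides tested per position). Cells where either
#' group has fewer than 2 guides or the pooled variance vanishes — always the
#' fixed GG at positions 22-23 — are reported as undefined with signed score
#' 0.
#'
#' The fitted object scores new 23-nt targets via [predict.crisprkp()]: the
#' CRISPR-kp score of a query is the sum over positions of the signed scores
#' of the cells its nucleotides select.
#'
#' @param guides a [guide_set()] with at least 4 guides.
#' @param weights optional numeric vector overriding the per-guide weights;
#'   defaults to `guides$mean_efficiency`. Replicates are never pooled as
#'   independent observations: the weight is one value per crRNA.
#' @param var_equal,alternative passed to [kp_t_test()]; the defaults
#'   (pooled variance, two-sided) are the classical Student's t convention.
#' @return An object of class `"crisprkp"`: a list with `features` (the
#'   4 x 23 feature table as a data frame, class `"kp_features"`),
#'   `n_guides`, `condition`, `weight_source`, `test`, `alternative`,
#'   `weights` and `call`.
#' @seealso [top_features()], [predict.crisprkp()], [coef.crisprkp()]
#' @examples
#' sim <- simulate_guides(kp_sim_config(
#'   n_guides = 40, effects = planted_effects(5, "T", 40), noise_sd = 10
#' ), seed = 1)
#' fit <- crisprkp(sim$guides)
#' top_features(fit, 3)
#' @export
crisprkp <- function(guides, weights = NULL, var_equal = TRUE,
                     alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(guides, "guide_set"))
  n <- nrow(guides)
  if (n < 4L) {
    stop("at least 4 guides are required: no cell can have both groups >= 2 ",
         "with fewer")
  }
  if (is.null(weights)) {
    weights <- guides$mean_efficiency
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != n || any(!is.finite(weights))) {
      stop("weights must be one finite value per guide")
    }
  }

  seq_mat <- .sequence_matrix(target_sequences(guides))
  rows <- vector("list", N_POSITIONS * 4L)
  k <- 0L
  for (pos in seq_len(N_POSITIONS)) {
    ch <- seq_mat[, pos]
    for (nt in NUCLEOTIDES) {
      k <- k + 1L
      idx <- ch == nt
      # sorted groups make the floating-point sums independent of guide order,
      # so the fit is exactly permutation-invariant
      res <- kp_t_test(sort(weights[idx]), sort(weights[!idx]),
                       var_equal = var_equal, alternative = alternative)
      rows[[k]] <- data.frame(
        position = pos, nucleotide = nt,
        n_in = sum(idx), n_out = sum(!idx),
        t = res$t, p = res$p,
        direction = if (!res$defined) "undefined"
                    else if (res$t > 0) "favored"
                    else if (res$t < 0) "disfavored"
                    else "undefined",
        signed_score = if (!res$defined) 0
                       else sign(res$t) * -log10(max(res$p, P_FLOOR)),
        sig_flag = "none",
        stringsAsFactors = FALSE
      )
    }
  }
  features <- do.call(rbind, rows)
  features <- bonferroni_flags(features)
  class(features) <- c("kp_features", "data.frame")
  attr(features, "condition") <- attr(guides, "condition_label")
  attr(features, "n_guides") <- n

  structure(list(
    features = features,
    n_guides = n,
    condition = attr(guides, "condition_label"),
    weight_source = attr(guides, "weight_source"),
    test = if (var_equal) "pooled" else "welch",
    alternative = alternative,
    weights = stats::setNames(weights, guides$name),
    call = match.call()
  ), class = "crisprkp")
}

# 23-nt targets -> n x 23 character matrix
.sequence_matrix <- function(targets) {
  stopifnot(all(nchar(targets) == N_POSITIONS))
  matrix(unlist(strsplit(targets, "", fixed = TRUE), use.names = FALSE),
         nrow = length(targets), ncol = N_POSITIONS, byrow = TRUE)
}

#' Split guide weights by the nucleotide at one position
#'
#' The grouping behind each feature-table cell: weights of the guides whose
#' target carries `nucleotide` at `position` versus the rest.
#'
#' @param guides a `guide_set`.
#' @param position integer in 1..23 (1 = 5' end of the protospacer,
#'   21-23 = PAM).
#' @param nucleotide one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return list with numeric vectors `weights_in` and `weights_out`.
#' @export
partition_by_feature <- function(guides, position, nucleotide) {
  stopifnot(inherits(guides, "guide_set"))
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > N_POSITIONS) {
    stop("position must be a single integer in 1..23")
  }
  nucleotide <- match.arg(toupper(nucleotide), NUCLEOTIDES)
  ch <- substr(target_sequences(guides), position, position)
  w <- guides$mean_efficiency
  list(weights_in = w[ch == nucleotide], weights_out = w[ch != nucleotide])
}

#' Per-position Bonferroni significance flags
#'
#' Four nucleotides are tested at each position, so the familywise
#' thresholds are 0.05/4 = 0.0125 and 0.01/4 = 0.0025. Undefined cells are
#' flagged `"none"`.
#'
#' @param features a `kp_features` data frame (or any data frame with
#'   columns `p` and `sig_flag`).
#' @param alphas the two uncorrected levels, divided by `m` per position.
#' @param m number of tests per position.
#' @return the table with `sig_flag` set to `"none"`, `"p<0.0125"` or
#'   `"p<0.0025"` (labels follow the supplied thresholds).
#' @export
bonferroni_flags <- function(features, alphas = c(0.05, 0.01), m = 4) {
  thr <- sort(alphas / m)  # c(strict, loose)
  lab <- paste0("p<", format(thr, trim = TRUE, scientific = FALSE))
  flag <- rep("none", nrow(features))
  ok <- !is.na(features$p)
  flag[ok & features$p < thr[2]] <- lab[2]
  flag[ok & features$p < thr[1]] <- lab[1]
  features$sig_flag <- flag
  features
}

#' Top-ranked sequence features
#'
#' Defined cells ranked by decreasing `-log10(p)` (i.e. increasing p).
#' Cells with p >= 1 carry no information and are excluded, so a null table
#' yields an empty ranking. Ties are broken by position (ascending) then
#' nucleotide (alphabetical).
#'
#' @param object a `"crisprkp"` fit or a `kp_features` table.
#' @param k number of features to return; if larger than the number of
#'   informative cells, all are returned.
#' @return a `kp_features` data frame of at most `k` rows.
#' @export
top_features <- function(object, k = 5) {
  features <- if (inherits(object, "crisprkp")) object$features else object
  stopifnot(is.data.frame(features))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be positive")
  keep <- !is.na(features$p) & features$p < 1
  ranked <- features[keep, , drop = FALSE]
  ord <- order(ranked$p, ranked$position, ranked$nucleotide)
  ranked <- ranked[ord, , drop = FALSE]
  out <- utils::head(ranked, min(as.integer(k), nrow(ranked)))
  rownames(out) <- NULL
  out
}
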