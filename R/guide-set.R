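#' Construct a guide set
#'
#' A guide set holds one crRNA per row: a 20-nt protospacer (written 5'->3',
#' position 1 at the 5' end), a 3-nt NGG PAM occupying positions 21-23 of the
#' full target, an optional target-strand label, and replicate indel-frequency
#' measurements in percent. Per-guide mean efficiency and its standard error
#' are derived from the replicates and act as the weights for all downstream
#' statistics.
#'
#' @param name character vector of unique guide identifiers.
#' @param protospacer character vector of 20-nt sequences over A/C/G/T
#'   (lower case accepted and upper-cased).
#' @param pam character vector of 3-nt PAMs matching NGG. Position 21
#'   (the N) must be a concrete A/C/G/T in a guide set; ambiguous N is only
#'   accepted in query sequences passed to [predict.crisprkp()].
#' @param replicates list of numeric vectors (or a numeric matrix, one row
#'   per guide) of replicate indel frequencies in percent, each in
#'   \[0, 100\]. `NA` cells are dropped, not imputed.
#' @param strand optional character vector, `"sense"` or `"antisense"`
#'   relative to the annotated gene; `NA` allowed.
#' @param condition_label free-text label for the Cas9 variant / delivery
#'   condition (e.g. `"WT Cas9 RNP"`).
#' @param weight_source one of `"ICE"`, `"TIDE"`, `"other"`: the indel
#'   quantification method behind the efficiencies.
#'
#' @return An object of class `"guide_set"`: a data frame with columns
#'   `name`, `protospacer`, `pam`, `strand`, `replicates` (list column),
#'   `mean_efficiency`, `sem`, and attributes `condition_label` and
#'   `weight_source`.
#'
#' @examples
#' gs <- guide_set(
#'   name = c("g1", "g2"),
#'   protospacer = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGA"),
#'   pam = c("TGG", "AGG"),
#'   replicates = list(c(80, 90), c(10, 20))
#' )
#' gs$mean_efficiency
#' @export
guide_set <- function(name, protospacer, pam, replicates,
                      strand = NULL, condition_label = "",
                      weight_source = c("other", "ICE", "TIDE")) {
  weight_source <- match.arg(weight_source)
  name <- as.character(name)
  n <- length(name)
  if (n < 1L) stop("a guide set needs at least one guide")
  if (anyDuplicated(name)) {
    stop("guide names must be unique within a set; duplicated: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  protospacer <- toupper(as.character(protospacer))
  pam <- toupper(as.character(pam))
  if (length(protospacer) != n || length(pam) != n) {
    stop("name, protospacer and pam must have equal length")
  }
  bad <- which(nchar(protospacer) != 20L | grepl("[^ACGT]", protospacer))
  if (length(bad)) {
    stop("invalid protospacer (must be 20 nt over A/C/G/T) for guide(s): ",
         paste(name[bad], collapse = ", "))
  }
  bad <- which(!grepl("^[ACGT]GG$", pam))
  if (length(bad)) {
    stop("PAM must match NGG (concrete N) for guide(s): ",
         paste(name[bad], collapse = ", "))
  }
  if (is.matrix(replicates)) {
    replicates <- lapply(seq_len(nrow(replicates)), function(i) replicates[i, ])
  }
  if (!is.list(replicates) || length(replicates) != n) {
    stop("replicates must be a list (or matrix) with one entry per guide")
  }
  replicates <- lapply(replicates, function(r) as.numeric(r[!is.na(r)]))
  empty <- which(vapply(replicates, length, 1L) == 0L)
  if (length(empty)) {
    stop("no replicate efficiency values for guide(s): ",
         paste(name[empty], collapse = ", "))
  }
  oob <- which(vapply(replicates, function(r) any(r < 0 | r > 100), TRUE))
  if (length(oob)) {
    stop("replicate efficiencies must be percentages in [0, 100]; violated by: ",
         paste(name[oob], collapse = ", "))
  }
  if (is.null(strand)) strand <- rep(NA_character_, n)
  strand <- as.character(strand)
  if (length(strand) != n) stop("strand must have one entry per guide")
  bad <- which(!is.na(strand) & !strand %in% c("sense", "antisense"))
  if (length(bad)) {
    stop("strand must be 'sense', 'antisense' or NA; violated by: ",
         paste(name[bad], collapse = ", "))
  }

  ms <- vapply(replicates, summarize_replicates, c(mean = 0, sem = 0))
  gs <- data.frame(
    name = name, protospacer = protospacer, pam = pam, strand = strand,
    mean_efficiency = ms["mean", ], sem = ms["sem", ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  gs$replicates <- replicates
  gs <- gs[, c("name", "protospacer", "pam", "strand", "replicates",
               "mean_efficiency", "sem")]
  attr(gs, "condition_label") <- condition_label
  attr(gs, "weight_source") <- weight_source
  class(gs) <- c("guide_set", "data.frame")
  gs
}

#' Mean and standard error of replicate efficiencies
#'
#' @param replicates numeric vector of indel frequencies in percent;
#'   `NA` values are dropped.
#' @return named numeric vector `c(mean = , sem = )`; `sem` is the sample
#'   standard deviation divided by `sqrt(n)`, defined as 0 for a single
#'   replicate.
#' @examples
#' summarize_replicates(c(0, 100))  # mean 50, sem 50
#' @export
summarize_replicates <- function(replicates) {
  r <- as.numeric(replicates)
  r <- r[is.finite(r)]
  if (length(r) == 0L) stop("no finite replicate values")
  m <- mean(r)
  s <- if (length(r) == 1L) 0 else stats::sd(r) / sqrt(length(r))
  c(mean = m, sem = s)
}

#' Full 23-nt target sequences of a guide set
#'
#' Protospacer (positions 1-20) concatenated with the PAM (positions 21-23).
#'
#' @param guides a `guide_set`.
#' @return character vector of 23-nt sequences, named by guide.
#' @export
target_sequences <- function(guides) {
  stopifnot(inherits(guides, "guide_set"))
  stats::setNames(paste0(guides$protospacer, guides$pam), guides$name)
}

#' @export
print.guide_set <- function(x, ...) {
  cat(sprintf("Guide set: %d crRNA(s)", nrow(x)))
  cl <- attr(x, "condition_label")
  if (nzchar(cl)) cat(sprintf(" [%s]", cl))
  cat(sprintf(", weights from %s\n", attr(x, "weight_source")))
  df <- as.data.frame(x)
  df$replicates <- vapply(df$replicates, function(r)
    paste(format(r, trim = TRUE), collapse = ","), "")
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.guide_set <- function(object, ...) {
  m <- object$mean_efficiency
  cc <- class_counts(object)
  structure(list(
    n = nrow(object),
    condition_label = attr(object, "condition_label"),
    weight_source = attr(object, "weight_source"),
    mean_of_means = mean(m),
    range = range(m),
    n_high = cc$n_high, n_low = cc$n_low
  ), class = "summary.guide_set")
}

#' @export
print.summary.guide_set <- function(x, ...) {
  cat(sprintf("Guide set '%s' (%s weights): n = %d\n",
              x$condition_label, x$weight_source, x$n))
  cat(sprintf("  mean efficiency %.1f%% (range %.1f-%.1f)\n",
              x$mean_of_means, x$range[1], x$range[2]))
  cat(sprintf("  %d guide(s) > 75%%, %d guide(s) < 25%%\n", x$n_high, x$n_low))
  invisible(x)
}
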