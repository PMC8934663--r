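#' Load a guide-efficiency table
#'
#' Reads a delimited text table with a header row and one crRNA per row.
#' Required columns: `name`, plus either `protospacer` and `pam` or a single
#' 23-nt `target23` (or `target`) column, which is split into positions 1-20
#' and 21-23; and at least one efficiency column — either a single
#' `efficiency` column or replicate columns `rep1`, `rep2`, ... Replicates
#' are aggregated per guide; empty/`NA` cells are dropped, not imputed. An
#' optional `strand` column (`sense`/`antisense`) is carried through.
#'
#' @param path path to a TSV (default) or CSV file; `sep` is inferred from
#'   the extension (`.csv` -> comma) unless given.
#' @param sep field separator; `NULL` to infer.
#' @param condition_label,weight_source stored on the returned set, see
#'   [guide_set()].
#' @return a validated [guide_set()]. Malformed rows abort with an error
#'   naming the row(s); no partial set is returned.
#' @export
load_guide_table <- function(path, sep = NULL, condition_label = "",
                             weight_source = c("other", "ICE", "TIDE")) {
  weight_source <- match.arg(weight_source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = NA, comment.char = ""),
    error = function(e) stop("could not parse table '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("empty guide table: ", path)
  names(df) <- tolower(names(df))
  if (!"name" %in% names(df)) stop("missing required column: name")

  if (all(c("protospacer", "pam") %in% names(df))) {
    proto <- toupper(df$protospacer)
    pam <- toupper(df$pam)
  } else if (any(c("target23", "target") %in% names(df))) {
    tcol <- if ("target23" %in% names(df)) "target23" else "target"
    tg <- toupper(df[[tcol]])
    bad <- which(nchar(tg) != 23L)
    if (length(bad)) {
      stop("column '", tcol, "' must hold 23-nt sequences; bad row(s): ",
           paste(bad, collapse = ", "))
    }
    proto <- substr(tg, 1, 20)
    pam <- substr(tg, 21, 23)
  } else {
    stop("missing required columns: either protospacer+pam or target23")
  }

  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(rep_cols)) {
    rep_cols <- rep_cols[order(as.integer(sub("^rep", "", rep_cols)))]
    reps <- lapply(seq_len(nrow(df)), function(i)
      suppressWarnings(as.numeric(unlist(df[i, rep_cols]))))
  } else if ("efficiency" %in% names(df)) {
    reps <- lapply(suppressWarnings(as.numeric(df$efficiency)), identity)
  } else {
    stop("missing required column: efficiency (or rep1..repK)")
  }

  strand <- if ("strand" %in% names(df)) tolower(df$strand) else NULL
  guide_set(name = df$name, protospacer = proto, pam = pam,
            replicates = reps, strand = strand,
            condition_label = condition_label, weight_source = weight_source)
}

#' Write a guide set as a tab-delimited table
#'
#' Columns: `name`, `protospacer`, `pam`, `strand`, `rep1..repK` (ragged
#' replicate lists are padded with `NA`, which the reader drops). The file
#' round-trips through [load_guide_table()].
#'
#' @param guides a `guide_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_guide_table <- function(guides, path) {
  stopifnot(inherits(guides, "guide_set"))
  kmax <- max(vapply(guides$replicates, length, 1L))
  reps <- vapply(guides$replicates,
                 function(r) c(r, rep(NA_real_, kmax - length(r))),
                 numeric(kmax))
  reps <- if (kmax == 1L) matrix(reps, ncol = 1L) else t(reps)
  colnames(reps) <- paste0("rep", seq_len(kmax))
  df <- data.frame(name = guides$name, protospacer = guides$protospacer,
                   pam = guides$pam, strand = guides$strand,
                   stringsAsFactors = FALSE)
  df <- cbind(df, .format_num_cols(as.data.frame(reps)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# full-precision text rendering of numeric columns (lossless round-trip)
.format_num_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}

FEATURE_COLUMNS <- c("position", "nucleotide", "n_in", "n_out", "t", "p",
                     "direction", "signed_score", "sig_flag")

#' Write / read a feature table
#'
#' Serializes all 92 (position, nucleotide) cells as TSV in fixed column
#' order (`position`, `nucleotide`, `n_in`, `n_out`, `t`, `p`, `direction`,
#' `signed_score`, `sig_flag`). Undefined cells keep explicit `NA` markers in
#' `t` and `p` and a 0 `signed_score`. Numeric columns are written at full
#' precision, so the pair round-trips losslessly.
#'
#' @param features a `kp_features` data frame (or a `"crisprkp"` fit, whose
#'   table is taken).
#' @param path file path.
#' @return `write_feature_table()` invisibly returns `path`;
#'   `read_feature_table()` returns a `kp_features` data frame.
#' @export
write_feature_table <- function(features, path) {
  if (inherits(features, "crisprkp")) features <- features$features
  stopifnot(is.data.frame(features))
  if (!all(FEATURE_COLUMNS %in% names(features))) {
    stop("feature table is missing column(s): ",
         paste(setdiff(FEATURE_COLUMNS, names(features)), collapse = ", "))
  }
  if (nrow(features) != 92L) {
    stop("feature table must hold all 92 cells (4 nucleotides x 23 positions)")
  }
  df <- .format_num_cols(as.data.frame(features)[, FEATURE_COLUMNS])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(position = "integer",
                                         nucleotide = "character",
                                         n_in = "integer", n_out = "integer",
                                         t = "numeric", p = "numeric",
                                         direction = "character",
                                         signed_score = "numeric",
                                         sig_flag = "character"))
  if (!identical(names(df), FEATURE_COLUMNS)) {
    stop("not a feature table: expected columns ",
         paste(FEATURE_COLUMNS, collapse = ", "))
  }
  class(df) <- c("kp_features", "data.frame")
  df
}

#' Export / import a portable scoring sheet
#'
#' A 23-row x 4-column matrix of signed `-log10(p)` scores (rows = target
#' positions, columns = A/C/G/T), sufficient for any spreadsheet to
#' reproduce CRISPR-kp scores by lookup-and-sum. Re-imported sheets score
#' identically to the in-memory model via [kp_score_sequences()].
#'
#' @param object a `"crisprkp"` fit or a 4 x 23 matrix from
#'   [coef.crisprkp()].
#' @param path file path.
#' @return `export_scoring_table()` invisibly returns `path`;
#'   `read_scoring_table()` returns the 4 x 23 matrix.
#' @export
export_scoring_table <- function(object, path) {
  m <- if (inherits(object, "crisprkp")) coef(object) else object
  stopifnot(is.matrix(m), identical(rownames(m), NUCLEOTIDES),
            ncol(m) == N_POSITIONS)
  df <- data.frame(position = seq_len(N_POSITIONS), t(m))
  utils::write.table(.format_num_cols(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname export_scoring_table
#' @export
read_scoring_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!identical(names(df), c("position", NUCLEOTIDES)) ||
      nrow(df) != N_POSITIONS) {
    stop("not a scoring sheet: expected 23 rows of position, A, C, G, T")
  }
  m <- t(as.matrix(df[, NUCLEOTIDES]))
  dimnames(m) <- list(NUCLEOTIDES, as.character(df$position))
  m
}
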