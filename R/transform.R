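#' Remove unclassifiable taxa and non-weed rows
#'
#' Before the attribute transform, the count table is reduced to classifiable
#' weed seeds only: grain, rachis and other non-weed rows are dropped, as are
#' weed taxa whose attribute code is [UNCLASSIFIED]. Removed taxa are
#' reported via a message.
#'
#' @param table a [count_table()].
#' @return A [count_table()] containing only coded weed taxa.
#' @export
drop_unclassified <- function(table) {
  stopifnot(inherits(table, "count_table"))
  keep <- table$item_category == "weed" &
    table$attribute_code %in% ATTRIBUTE_CODES
  removed <- taxon_ids(table)[!keep]
  if (length(removed))
    message("drop_unclassified: removed ", length(removed), " taxa: ",
            paste(removed, collapse = ", "))
  subset_count_table(table, i = which(keep))
}

#' Attribute-score transform of weed-seed counts
#'
#' Converts classifiable weed-seed counts into the six attribute-category
#' scores used by the discriminant models. For sample s with classifiable
#' weed total N_s, each taxon i contributes sqrt(100 * n_is / N_s) — the
#' square root of its within-sample percentage — and the contributions are
#' summed by attribute code. The square root damps the dominance of abundant
#' taxa while the percentage base makes scores compositional (invariant to
#' uniform rescaling of a sample's counts).
#'
#' Note the sum is of per-taxon square roots, not the square root of the
#' summed percentage: two taxa of the same code at 50% each score
#' sqrt(50) + sqrt(50) ~ 14.14, not 10.
#'
#' @param table a [count_table()] containing only classifiable weed taxa
#'   (apply [drop_unclassified()] first; other rows trigger an error).
#' @return An `attribute_matrix`: numeric matrix, samples x 6, columns in the
#'   fixed order [ATTRIBUTE_CODES].
#' @export
attribute_transform <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (any(table$item_category != "weed") ||
      any(!table$attribute_code %in% ATTRIBUTE_CODES))
    stop("table contains non-weed or unclassified taxa; ",
         "apply drop_unclassified() first", call. = FALSE)
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("sample(s) with no classifiable weed seeds: ",
         paste(sample_ids(table)[totals == 0], collapse = ", "),
         "; filter them out first (filter_min_items)", call. = FALSE)
  pct_root <- sqrt(sweep(table$counts, 2L, totals / 100, "/"))
  scores <- vapply(ATTRIBUTE_CODES, function(code) {
    colSums(pct_root[table$attribute_code == code, , drop = FALSE])
  }, numeric(ncol(table$counts)))
  scores <- matrix(scores, nrow = ncol(table$counts),
                   dimnames = list(sample_ids(table), ATTRIBUTE_CODES))
  attribute_matrix(scores)
}

#' Construct an attribute-score matrix
#'
#' @param scores numeric matrix, samples x 6, with columns (in order)
#'   [ATTRIBUTE_CODES]; row names are sample ids.
#' @return The matrix with class `attribute_matrix`.
#' @export
attribute_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(ATTRIBUTE_CODES))
    stop("attribute matrix must have ", length(ATTRIBUTE_CODES), " columns",
         call. = FALSE)
  if (is.null(colnames(scores))) {
    colnames(scores) <- ATTRIBUTE_CODES
  } else if (!identical(colnames(scores), ATTRIBUTE_CODES)) {
    if (!setequal(colnames(scores), ATTRIBUTE_CODES))
      stop("attribute matrix columns must be ",
           paste(ATTRIBUTE_CODES, collapse = ", "), call. = FALSE)
    scores <- scores[, ATTRIBUTE_CODES, drop = FALSE]
  }
  rn <- rownames(scores)
  if (nrow(scores) > 0L && (is.null(rn) || length(rn) != nrow(scores)))
    rownames(scores) <- paste0("sample", seq_len(nrow(scores)))
  if (anyNA(scores) || any(scores < 0))
    stop("attribute scores must be non-negative and finite", call. = FALSE)
  class(scores) <- c("attribute_matrix", class(matrix()))
  scores
}

#' Write an attribute matrix as CSV (samples as rows, six code columns)
#'
#' @param x an `attribute_matrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_attribute_matrix <- function(x, path) {
  df <- data.frame(sample = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an attribute matrix from CSV
#'
#' @param path CSV with a `sample` column and the six code columns.
#' @return An `attribute_matrix`.
#' @export
read_attribute_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df))
    stop("expected a 'sample' column in ", path, call. = FALSE)
  m <- as.matrix(df[ATTRIBUTE_CODES])
  rownames(m) <- as.character(df$sample)
  attribute_matrix(m)
}
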