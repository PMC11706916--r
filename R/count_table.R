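#' Construct a sample-by-taxon count table
#'
#' The basic container for archaeobotanical count data: an integer matrix of
#' counts with taxa as rows and samples as columns, an item category per
#' taxon (`grain`, `rachis`, `weed` or `other`) and, for weed taxa, a
#' functional attribute code (one of [ATTRIBUTE_CODES] or [UNCLASSIFIED]).
#'
#' @param counts numeric matrix, taxa x samples, non-negative integers.
#'   Dimnames give taxon and sample ids.
#' @param item_category character vector, one entry per taxon, each one of
#'   `"grain"`, `"rachis"`, `"weed"`, `"other"`.
#' @param attribute_code character vector, one entry per taxon. Must be `NA`
#'   for non-weed taxa; for weed taxa any string is accepted and normalised
#'   (invalid or blank codes become [UNCLASSIFIED]).
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, item_category, attribute_code = NULL) {
  counts <- as.matrix(counts)
  rn <- rownames(counts)
  cn <- colnames(counts)
  if (is.null(rn) || length(rn) != nrow(counts))
    rn <- paste0("taxon", seq_len(nrow(counts)))
  if (is.null(cn) || length(cn) != ncol(counts))
    cn <- paste0("sample", seq_len(ncol(counts)))
  dimnames(counts) <- list(if (nrow(counts)) rn, if (ncol(counts)) cn)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integral", call. = FALSE)
  item_category <- as.character(item_category)
  if (length(item_category) == 1L)
    item_category <- rep(item_category, nrow(counts))
  if (length(item_category) != nrow(counts))
    stop("item_category must have one entry per taxon", call. = FALSE)
  bad_cat <- setdiff(item_category, c("grain", "rachis", "weed", "other"))
  if (length(bad_cat))
    stop("unknown item category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  is_weed <- item_category == "weed"
  code <- rep(NA_character_, nrow(counts))
  if (is.null(attribute_code)) {
    code[is_weed] <- UNCLASSIFIED
  } else {
    if (length(attribute_code) != nrow(counts))
      stop("attribute_code must have one entry per taxon", call. = FALSE)
    if (any(!is.na(attribute_code[!is_weed]) &
            nzchar(trimws(attribute_code[!is_weed]))))
      stop("non-weed taxa must not carry attribute codes", call. = FALSE)
    code[is_weed] <- normalise_code(attribute_code[is_weed])
  }
  structure(
    list(counts = counts, item_category = item_category,
         attribute_code = code),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$item_category)
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nw <- sum(x$item_category == "weed" & x$attribute_code != UNCLASSIFIED,
            na.rm = TRUE)
  cat(sprintf("  classifiable weed taxa: %d\n", nw))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(x) colnames(x$counts)
taxon_ids <- function(x) rownames(x$counts)

# subset helper keeping metadata aligned; i = taxa, j = samples
subset_count_table <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$counts))
  if (is.null(j)) j <- seq_len(ncol(x$counts))
  structure(
    list(counts = x$counts[i, j, drop = FALSE],
         item_category = x$item_category[i],
         attribute_code = x$attribute_code[i]),
    class = "count_table"
  )
}

#' Read a count table from CSV
#'
#' Reads the standard supplementary-table layout: taxa as rows, one column of
#' attribute codes, and sample count columns from a named column onwards.
#' Blank cells in the count region are zeros; blank or unrecognised codes are
#' mapped to [UNCLASSIFIED] with a warning. A transposed layout (samples as
#' rows) is accepted via `transposed = TRUE`.
#'
#' @param path path to a UTF-8, comma-separated file with a header row. The
#'   first column must hold taxon (or, if transposed, sample) identifiers.
#' @param code_column name of the column holding seed attribute codes.
#' @param first_sample_column name of the first sample column; all columns
#'   from it (inclusive) to the right are treated as samples.
#' @param category_column optional name of a column giving the item category
#'   per taxon (`grain` / `rachis` / `weed` / `other`; the single letter `N`
#'   is read as `other`). When absent, every taxon with a non-blank code cell
#'   available is treated as a weed.
#' @param transposed logical; if `TRUE` the file has samples as rows and
#'   taxa as columns (no code column is read in this orientation and all
#'   taxa are treated as weeds; supply codes separately).
#' @return A [count_table()].
#' @export
read_counts <- function(path, code_column, first_sample_column,
                        category_column = NULL, transposed = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (transposed) {
    ids <- as.character(raw[[1L]])
    mat <- t(as.matrix(raw[-1L]))
    colnames(mat) <- ids
    return(build_count_table_from_matrix(mat, path))
  }
  cols <- colnames(raw)
  if (!code_column %in% cols)
    stop("code column '", code_column, "' not found in ", path, call. = FALSE)
  if (!first_sample_column %in% cols)
    stop("first sample column '", first_sample_column, "' not found in ",
         path, call. = FALSE)
  if (!is.null(category_column) && !category_column %in% cols)
    stop("category column '", category_column, "' not found in ", path,
         call. = FALSE)

  taxa <- as.character(raw[[1L]])
  from <- match(first_sample_column, cols)
  sample_cols <- cols[from:length(cols)]
  mat <- as.matrix(raw[sample_cols])
  if (nrow(raw) == 0L) {
    mat <- matrix(0, 0L, length(sample_cols),
                  dimnames = list(character(), sample_cols))
    return(count_table(mat, character()))
  }
  mat[mat == "" | is.na(mat)] <- "0"
  num <- suppressWarnings(apply(mat, 2L, function(v) as.numeric(v)))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(taxa, sample_cols))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                 taxa[bad[1L]], sample_cols[bad[2L]]), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 taxa[bad[1L]], sample_cols[bad[2L]]), call. = FALSE)
  }

  raw_codes <- as.character(raw[[code_column]])
  if (is.null(category_column)) {
    category <- rep("weed", length(taxa))
  } else {
    cat_raw <- tolower(trimws(as.character(raw[[category_column]])))
    category <- ifelse(cat_raw %in% c("grain", "rachis", "weed"), cat_raw,
                       "other")
  }
  is_weed <- category == "weed"
  codes <- rep(NA_character_, length(taxa))
  codes[is_weed] <- normalise_code(raw_codes[is_weed])
  n_unc <- sum(codes[is_weed] == UNCLASSIFIED)
  if (n_unc > 0L)
    warning(sprintf("%d weed taxa have blank or unrecognised codes; mapped to %s",
                    n_unc, UNCLASSIFIED), call. = FALSE)
  count_table(num, category, codes)
}

build_count_table_from_matrix <- function(mat, path) {
  storage.mode(mat) <- "double"
  mat[is.na(mat)] <- 0
  if (any(mat < 0))
    stop("negative count in ", path, call. = FALSE)
  count_table(mat, "weed")
}

#' Read a grain/rachis/weeds totals table
#'
#' Reads per-sample totals of grain, rachis nodes and weed seeds (samples as
#' rows, three category columns) as used for ternary plotting.
#'
#' @param path CSV path. Column names are matched case-insensitively against
#'   `sample`, `grain`, `rachis`, `weeds` (a `weed` column is also accepted).
#' @return A `triplot_table`: data frame with columns `sample`, `grain`,
#'   `rachis`, `weeds`.
#' @export
read_triplot_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  nm <- tolower(colnames(raw))
  pick <- function(what) {
    i <- match(what, nm)
    if (is.na(i) && what == "weeds") i <- match("weed", nm)
    if (is.na(i)) stop("column '", what, "' not found in ", path,
                       call. = FALSE)
    i
  }
  out <- data.frame(
    sample = as.character(raw[[pick("sample")]]),
    grain = as.numeric(raw[[pick("grain")]]),
    rachis = as.numeric(raw[[pick("rachis")]]),
    weeds = as.numeric(raw[[pick("weeds")]]),
    stringsAsFactors = FALSE
  )
  triplot_table(out)
}

#' Construct a grain/rachis/weeds totals table
#'
#' @param x data frame with columns `sample`, `grain`, `rachis`, `weeds`
#'   (non-negative totals).
#' @return `x` validated, with class `triplot_table` prepended.
#' @export
triplot_table <- function(x) {
  need <- c("sample", "grain", "rachis", "weeds")
  if (!all(need %in% colnames(x)))
    stop("triplot table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[need]
  if (any(is.na(x[-1L])) || any(as.matrix(x[-1L]) < 0))
    stop("grain/rachis/weeds totals must be non-negative", call. = FALSE)
  class(x) <- c("triplot_table", "data.frame")
  x
}

#' Drop samples below a minimum item count
#'
#' Retains samples whose basis count reaches `threshold`, preserving order.
#' The ids of dropped samples are reported via a message and attached as the
#' `"dropped"` attribute, so iterative cleaning remains auditable.
#'
#' @param x a [count_table()] or [triplot_table()].
#' @param threshold minimum number of items (>= 1).
#' @param basis counting basis: `"total_items"` (all items in the sample) or
#'   `"classifiable_weed_seeds"` (weed taxa with a valid attribute code only).
#'   A `triplot_table` always uses its grain+rachis+weeds total.
#' @return The filtered object, with attribute `dropped` (character vector of
#'   removed sample ids).
#' @export
filter_min_items <- function(x, threshold,
                             basis = c("total_items",
                                       "classifiable_weed_seeds")) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop("threshold must be a single number >= 1", call. = FALSE)
  UseMethod("filter_min_items")
}

#' @export
filter_min_items.count_table <- function(x, threshold,
                                         basis = c("total_items",
                                                   "classifiable_weed_seeds")) {
  basis <- match.arg(basis)
  keep_taxa <- if (basis == "total_items") {
    rep(TRUE, nrow(x$counts))
  } else {
    x$item_category == "weed" & x$attribute_code %in% ATTRIBUTE_CODES
  }
  totals <- colSums(x$counts[keep_taxa, , drop = FALSE])
  keep <- totals >= threshold
  dropped <- sample_ids(x)[!keep]
  if (length(dropped))
    message("filter_min_items: dropped ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  out <- subset_count_table(x, j = which(keep))
  attr(out, "dropped") <- dropped
  out
}

#' @export
filter_min_items.triplot_table <- function(x, threshold, basis = "total_items") {
  totals <- x$grain + x$rachis + x$weeds
  keep <- totals >= threshold
  dropped <- x$sample[!keep]
  if (length(dropped))
    message("filter_min_items: dropped ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triplot_table", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Label samples by dominant crop
#'
#' Screens samples for crop dominance before triplot or discriminant
#' analysis: a sample is labelled with the crop group whose share of all crop
#' items reaches `threshold`, and `"mixed"` otherwise. A union group (by
#' default free-threshing cereal = wheat + barley) is evaluated when no
#' single group reaches the threshold on its own. Weeds and other non-crop
#' items are excluded from the denominator.
#'
#' @param table a [count_table()].
#' @param crop_groups named list mapping crop-group name to a character
#'   vector of taxon ids; groups must not share taxa.
#' @param threshold dominance threshold, a fraction in (0, 1]; default 0.80.
#' @param unions named list of union groups evaluated only when no single
#'   group dominates; each element names the member groups. Default:
#'   `list("free-threshing cereal" = c("wheat", "barley"))` (applied only
#'   when both members exist in `crop_groups`).
#' @return data frame with columns `sample`, `label`, `crop_items`.
#' @export
classify_dominance <- function(table, crop_groups, threshold = 0.80,
                               unions = list(
                                 "free-threshing cereal" = c("wheat", "barley"))) {
  stopifnot(inherits(table, "count_table"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  all_taxa <- unlist(crop_groups, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("crop_groups must not share taxa", call. = FALSE)
  grp_counts <- vapply(crop_groups, function(tx) {
    colSums(table$counts[taxon_ids(table) %in% tx, , drop = FALSE])
  }, numeric(ncol(table$counts)))
  if (is.null(dim(grp_counts)))
    grp_counts <- matrix(grp_counts, nrow = 1L,
                         dimnames = list(NULL, names(crop_groups)))
  total <- rowSums(grp_counts)
  labels <- character(length(total))
  for (i in seq_along(total)) {
    if (total[i] == 0) {
      warning("sample '", sample_ids(table)[i],
              "' has no crop items; labelled mixed", call. = FALSE)
      labels[i] <- "mixed"
      next
    }
    share <- grp_counts[i, ] / total[i]
    hit <- names(share)[share >= threshold]
    if (length(hit)) {
      labels[i] <- hit[1L]
    } else {
      labels[i] <- "mixed"
      for (un in names(unions)) {
        members <- intersect(unions[[un]], names(crop_groups))
        if (length(members) < 2L) next
        if (sum(share[members]) >= threshold) {
          labels[i] <- un
          break
        }
      }
    }
  }
  data.frame(sample = sample_ids(table), label = labels,
             crop_items = as.numeric(total), stringsAsFactors = FALSE)
}

#' Write classification results to CSV
#'
#' Writes one row per sample (class, per-group posterior probabilities,
#' discriminant scores) to `path`, and the classification table (counts and
#' percentages per class) to a companion file `<path minus .csv>_table.csv`.
#'
#' @param result a `classification_result` from [jones_classify()] or
#'   [charles_classify()].
#' @param path output CSV path.
#' @return Invisibly, the paths written (main file first).
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "classification_result"))
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE)
  table_path <- sub("\\.csv$", "", path)
  table_path <- paste0(table_path, "_table.csv")
  utils::write.csv(classification_table(result), table_path,
                   row.names = FALSE)
  invisible(c(path, table_path))
}
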