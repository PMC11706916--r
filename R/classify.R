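#' Construct an ethnographic reference set
#'
#' Bundles an attribute matrix of ethnographic samples with their
#' crop-processing group labels 1-4 (1 winnowing by-product, 2 coarse sieve
#' by-product, 3 fine sieve by-product, 4 fine sieve product).
#'
#' @param scores an `attribute_matrix` (samples x 6).
#' @param groups integer (or coercible) group label per row, values 1-4; all
#'   four groups must be present with >= 2 samples each.
#' @param provenance free-text note on where the reference data come from.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(scores, groups,
                          provenance = "unspecified reference data") {
  scores <- attribute_matrix(scores)
  groups <- as.integer(as.character(groups))
  if (length(groups) != nrow(scores))
    stop("one group label per reference sample required", call. = FALSE)
  if (!all(groups %in% 1:4))
    stop("reference group labels must be 1, 2, 3 or 4", call. = FALSE)
  sizes <- table(factor(groups, levels = 1:4))
  if (any(sizes < 2L))
    stop("all four groups need >= 2 reference samples; short: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  structure(list(scores = scores, groups = groups, provenance = provenance),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d samples in 4 groups (%s)\n",
              nrow(x$scores),
              paste(table(factor(x$groups, levels = 1:4)), collapse = "/")))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

new_classification_result <- function(sample_ids, class, post, scores,
                                      model, method,
                                      ref_scores, ref_groups) {
  structure(
    list(sample_ids = sample_ids, class = class, posterior = post,
         scores = scores, model = model, method = method,
         ref_scores = ref_scores, ref_groups = ref_groups),
    class = "classification_result"
  )
}

#' Classify archaeological samples against the four-group ethnographic model
#'
#' The reference-only procedure: a discriminant model is fitted on the
#' ethnographic reference set alone (4 groups, hence 3 discriminant
#' functions on the 6 attribute scores) and the archaeological samples are
#' projected, given posterior probabilities for each of the four
#' crop-processing groups, and assigned to the most probable group.
#'
#' @param reference a [reference_set()].
#' @param arch `attribute_matrix` of archaeological samples.
#' @param priors prior specification passed to [fit_lda()].
#' @return A `classification_result` with per-sample class, posteriors and
#'   discriminant scores, the fitted model, and the reference coordinates
#'   needed for plotting.
#' @export
jones_classify <- function(reference, arch, priors = "proportional") {
  stopifnot(inherits(reference, "reference_set"))
  arch <- attribute_matrix(arch)
  model <- fit_lda(reference$scores, reference$groups, priors = priors)
  post <- posterior(model, arch)
  new_classification_result(
    sample_ids = rownames(arch),
    class = as.integer(predict_class(model, arch)),
    post = post,
    scores = project(model, arch),
    model = model, method = "jones",
    ref_scores = project(model, reference$scores),
    ref_groups = reference$groups
  )
}

#' Classify with the archaeological samples included as a fifth group
#'
#' The taphonomy-screening variant: the archaeological samples join the
#' model at the discrimination stage as group 5 ("archaeological"), giving a
#' five-group model with four discriminant functions. The same samples are
#' then re-entered and classified among the five groups. Archaeological
#' samples that still resemble a crop-processing stage more than their own
#' group fall out of group 5; a high group-5 share suggests an origin the
#' ethnographic stages do not explain (for instance dung burning).
#'
#' @inheritParams jones_classify
#' @param arch `attribute_matrix` with >= 2 archaeological samples (they
#'   form a training group).
#' @return A `classification_result` (5 posterior columns, 4 score columns).
#' @export
charles_classify <- function(reference, arch, priors = "proportional") {
  stopifnot(inherits(reference, "reference_set"))
  arch <- attribute_matrix(arch)
  if (nrow(arch) < 2L)
    stop("the archaeological set must have >= 2 samples to form a group",
         call. = FALSE)
  X <- rbind(unclass(reference$scores), unclass(arch))
  groups <- c(reference$groups, rep(5L, nrow(arch)))
  model <- fit_lda(X, groups, priors = priors)
  post <- posterior(model, arch)
  new_classification_result(
    sample_ids = rownames(arch),
    class = as.integer(predict_class(model, arch)),
    post = post,
    scores = project(model, arch),
    model = model, method = "charles",
    ref_scores = project(model, reference$scores),
    ref_groups = reference$groups
  )
}

#' Classification table: counts and percentages per class
#'
#' One row per class of the underlying model, including classes with zero
#' samples; percentages are of the number of classified samples.
#'
#' @param result a `classification_result`.
#' @return data frame with columns `class`, `label`, `n`, `percent`.
#' @export
classification_table <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  classes <- as.integer(result$model$group_labels)
  counts <- as.integer(table(factor(result$class, levels = classes)))
  n <- length(result$class)
  data.frame(
    class = classes,
    label = unname(GROUP_LABELS[as.character(classes)]),
    n = counts,
    percent = if (n > 0) 100 * counts / n else rep(0, length(classes)),
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.classification_result <- function(x, ...) {
  k <- ncol(x$posterior)
  df <- data.frame(sample = x$sample_ids, class = x$class,
                   stringsAsFactors = FALSE)
  post <- as.data.frame(x$posterior)
  colnames(post) <- paste0("prob.", x$model$group_labels)
  sc <- as.data.frame(x$scores)
  colnames(sc) <- colnames(x$scores)
  rownames(df) <- NULL
  cbind(df, post, sc, row.names = NULL)
}

#' @export
print.classification_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s-method classification of %d sample(s)\n",
              x$method, length(x$sample_ids)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L)) & colnames(df) != "class"
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  cat("\nclassification table:\n")
  tab <- classification_table(x)
  tab$percent <- round(tab$percent, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Re-run a classification with selected taxa removed
#'
#' Implements the iterative sensitivity workflow: suspect taxa (hay-meadow
#' species, dung-flora species, ...) are removed from the raw counts, the
#' cleaning steps are re-applied — unclassified taxa dropped and the
#' minimum-seed filter recomputed, so sample membership may change — the
#' attribute transform is recomputed, and the chosen classification is run
#' on both the original and the reduced data. Per-sample class changes are
#' reported.
#'
#' @param table raw [count_table()] (weeds with codes; other rows are
#'   dropped during cleaning).
#' @param taxa_to_remove character vector of taxon ids to remove; names not
#'   present in the table give a warning, not an error.
#' @param reference a [reference_set()].
#' @param min_seeds minimum classifiable weed seeds per sample (the filter
#'   is recomputed after removal).
#' @param method `"jones"` or `"charles"`.
#' @param priors prior specification passed to [fit_lda()].
#' @return list with elements `before` and `after` (both
#'   `classification_result`) and `changes`, a data frame of the samples
#'   whose class changed or that dropped out of the filtered set.
#' @export
rerun_without_taxa <- function(table, taxa_to_remove, reference,
                               min_seeds = 10, method = c("jones", "charles"),
                               priors = "proportional") {
  stopifnot(inherits(table, "count_table"))
  method <- match.arg(method)
  absent <- setdiff(taxa_to_remove, taxon_ids(table))
  if (length(absent))
    warning("taxa not present in the table: ",
            paste(absent, collapse = ", "), call. = FALSE)

  run <- function(tab) {
    tab <- drop_unclassified(tab)
    tab <- filter_min_items(tab, min_seeds, basis = "classifiable_weed_seeds")
    am <- attribute_transform(tab)
    if (method == "jones") jones_classify(reference, am, priors = priors)
    else charles_classify(reference, am, priors = priors)
  }
  before <- run(table)
  keep <- !(taxon_ids(table) %in% taxa_to_remove)
  after <- run(subset_count_table(table, i = which(keep)))

  common <- intersect(before$sample_ids, after$sample_ids)
  b <- before$class[match(common, before$sample_ids)]
  a <- after$class[match(common, after$sample_ids)]
  changed <- data.frame(sample = common, class_before = b, class_after = a,
                        stringsAsFactors = FALSE)[b != a, , drop = FALSE]
  lost <- setdiff(before$sample_ids, after$sample_ids)
  if (length(lost))
    changed <- rbind(changed, data.frame(
      sample = lost,
      class_before = before$class[match(lost, before$sample_ids)],
      class_after = NA_integer_, stringsAsFactors = FALSE))
  rownames(changed) <- NULL
  list(before = before, after = after, changes = changed)
}
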