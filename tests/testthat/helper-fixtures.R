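# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

# minimal coded weed table: taxa x samples
toy_weed_table <- function(counts, codes) {
  count_table(counts, "weed", codes)
}

# write a CSV in the supplementary layout (taxa rows, Codes column, then
# sample columns) and return its path
write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# random coded weed table for property-style loops
random_weed_table <- function(n_taxa = 8, n_samples = 4, seed = 1,
                              max_count = 30) {
  set.seed(seed)
  codes <- sample(ATTRIBUTE_CODES, n_taxa, replace = TRUE)
  counts <- matrix(rpois(n_taxa * n_samples, max_count / 2) + 1L,
                   n_taxa, n_samples,
                   dimnames = list(paste0("t", seq_len(n_taxa)),
                                   paste0("s", seq_len(n_samples))))
  toy_weed_table(counts, codes)
}

# independent brute-force oracle for the attribute transform: loops
# taxon-by-taxon, computes sqrt(percentage) and accumulates by code
oracle_attribute_transform <- function(table) {
  out <- matrix(0, ncol(table$counts), length(ATTRIBUTE_CODES),
                dimnames = list(colnames(table$counts), ATTRIBUTE_CODES))
  for (s in seq_len(ncol(table$counts))) {
    N <- sum(table$counts[, s])
    for (i in seq_len(nrow(table$counts))) {
      pct <- 100 * table$counts[i, s] / N
      code <- table$attribute_code[i]
      out[s, code] <- out[s, code] + sqrt(pct)
    }
  }
  out
}

# independent full-dimensional shared-covariance Gaussian posterior oracle
oracle_gaussian_posterior <- function(model, X) {
  X <- as.matrix(unclass(X))
  Sinv <- solve(model$pooled_cov)
  G <- length(model$group_labels)
  logd <- sapply(seq_len(G), function(k) {
    d <- sweep(X, 2L, model$means[k, ])
    -0.5 * rowSums((d %*% Sinv) * d) + log(model$priors[k])
  })
  logd <- matrix(logd, nrow = nrow(X))
  un <- exp(logd - apply(logd, 1L, max))
  un / rowSums(un)
}

# small well-separated 3-group data in 2-D for lda unit tests
toy_lda_data <- function(seed = 1, n = 12) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  X <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(rnorm(2 * n, sd = 0.5), n, 2), 2L, centers[g, ], "+")
  }))
  colnames(X) <- c("v1", "v2")
  list(X = X, groups = rep(1:3, each = n))
}
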