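ref <- synthetic_reference_set(n_per_group = 12, seed = 31)

test_that("a sample at a group centroid is classified into that group", {
  centroid <- attribute_matrix(
    matrix(colMeans(ref$scores[ref$groups == 2, , drop = FALSE]), 1,
           dimnames = list("at_g2", ATTRIBUTE_CODES)))
  res <- jones_classify(ref, centroid)
  expect_identical(res$class, 2L)
  expect_identical(unname(which.max(res$posterior[1, ])), 2L)
})

test_that("jones_classify is equivariant under arch row permutation", {
  arch <- attribute_transform(
    generate_archaeological(n = 12, seed = 32)$table)
  res <- jones_classify(ref, arch)
  perm <- c(7, 1, 12, 3, 9, 2, 11, 4, 10, 5, 8, 6)
  res_p <- jones_classify(ref, arch[perm, , drop = FALSE])
  expect_identical(res_p$sample_ids, res$sample_ids[perm])
  expect_identical(res_p$class, res$class[perm])
  expect_equal(unname(res_p$posterior), unname(res$posterior[perm, ]),
               tolerance = 1e-12)
})

test_that("charles_classify has five-group mechanics", {
  arch <- attribute_transform(
    generate_archaeological(n = 10, seed = 33)$table)
  res <- charles_classify(ref, arch)
  expect_identical(res$method, "charles")
  expect_identical(ncol(res$posterior), 5L)
  expect_identical(ncol(res$scores), 4L)   # m = min(5 - 1, 6)
  expect_equal(unname(rowSums(res$posterior)), rep(1, 10),
               tolerance = 1e-12)
  expect_identical(res$class,
                   as.integer(colnames(res$posterior)[
                     apply(res$posterior, 1, which.max)]))
  expect_error(charles_classify(ref, arch[1, , drop = FALSE]), ">= 2")
})

test_that("classification_table covers zero-count classes and sums to 100", {
  arch4 <- attribute_matrix(
    ref$scores[ref$groups == 4, , drop = FALSE][1:10, ])
  res <- jones_classify(ref, arch4)
  tab <- classification_table(res)
  expect_identical(tab$class, 1:4)
  expect_identical(tab$n[tab$class == 4], 10L)
  expect_equal(tab$percent[tab$class == 4], 100)
  expect_identical(sum(tab$n), 10L)

  for (seed in 34:36) {
    arch <- attribute_transform(
      generate_archaeological(n = 9, seed = seed,
                              contamination = 0.4)$table)
    tj <- classification_table(jones_classify(ref, arch))
    tc <- classification_table(charles_classify(ref, arch))
    expect_equal(sum(tj$percent), 100, tolerance = 0.1)
    expect_equal(sum(tc$percent), 100, tolerance = 0.1)
    expect_identical(nrow(tc), 5L)
  }
})

test_that("the transform feeding both methods is method-agnostic", {
  arch_tab <- generate_archaeological(n = 8, seed = 37)$table
  am1 <- attribute_transform(arch_tab)
  am2 <- attribute_transform(arch_tab)
  expect_identical(unclass(am1), unclass(am2))
  # same matrix enters jones and charles untouched
  rj <- jones_classify(ref, am1)
  rc <- charles_classify(ref, am1)
  expect_identical(rj$sample_ids, rc$sample_ids)
})

test_that("rerun_without_taxa recomputes filters and reports changes", {
  gen <- generate_archaeological(n = 10, seed = 38)
  tab <- gen$table

  # removing taxa absent from every sample changes nothing
  tab0 <- tab
  tab0$counts <- rbind(tab0$counts,
                       ghost = rep(0, ncol(tab0$counts)))
  tab0$item_category <- c(tab0$item_category, "weed")
  tab0$attribute_code <- c(tab0$attribute_code, "BHH")
  rr <- suppressMessages(
    rerun_without_taxa(tab0, "ghost", ref, min_seeds = 10))
  expect_identical(nrow(rr$changes), 0L)
  expect_identical(rr$before$class, rr$after$class)

  # absent names warn but do not error
  expect_warning(
    suppressMessages(rerun_without_taxa(tab, "no_such_taxon", ref)),
    "not present")

  # removing a dominant code's taxa both reclassifies and can drop samples
  rr2 <- suppressMessages(
    rerun_without_taxa(tab, c("SFL_t1", "SFL_t2", "SHL_t1", "SHL_t2"),
                       ref, min_seeds = 10))
  expect_true(all(rr2$after$sample_ids %in% rr2$before$sample_ids))
  lost <- setdiff(rr2$before$sample_ids, rr2$after$sample_ids)
  if (length(lost))
    expect_true(all(is.na(
      rr2$changes$class_after[rr2$changes$sample %in% lost])))
})
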