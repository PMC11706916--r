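# totals rows in the published three-column layout, entered by hand
table2_rows <- triplot_table(data.frame(
  sample = c("461", "462", "466", "467"),
  grain = c(23173, 239, 2060, 1327),
  rachis = c(2300, 5, 437, 153),
  weeds = c(9760, 67, 3567, 2228)
))

test_that("proportions are percentages of the sample total", {
  tt <- triplot_table(data.frame(sample = "a", grain = 50, rachis = 25,
                                 weeds = 25))
  pr <- triplot_proportions(tt)
  expect_equal(c(pr$grain, pr$rachis, pr$weeds), c(50, 25, 25))

  # worked arithmetic: 239/311, 5/311, 67/311
  pr2 <- triplot_proportions(table2_rows)
  i <- match("462", pr2$sample)
  expect_equal(round(c(pr2$grain[i], pr2$rachis[i], pr2$weeds[i]), 2),
               c(76.85, 1.61, 21.54))
  expect_equal(pr2$grain + pr2$rachis + pr2$weeds, rep(100, 4),
               tolerance = 1e-9)

  # scale invariance
  tt2 <- triplot_table(data.frame(sample = "a", grain = 2, rachis = 1,
                                  weeds = 1))
  expect_equal(triplot_proportions(tt2)$grain, pr$grain)

  zero <- triplot_table(data.frame(sample = c("ok", "void"),
                                   grain = c(1, 0), rachis = c(1, 0),
                                   weeds = c(1, 0)))
  expect_error(triplot_proportions(zero), "void")
})

test_that("ternary coordinates place vertices and centroid correctly", {
  s3 <- sqrt(3) / 2
  corners <- data.frame(grain = c(100, 0, 0), rachis = c(0, 100, 0),
                        weeds = c(0, 0, 100))
  xy <- ternary_coordinates(corners)
  expect_equal(unname(as.matrix(xy)),
               rbind(c(0.5, s3), c(0, 0), c(1, 0)), tolerance = 1e-12)
  centroid <- ternary_coordinates(
    data.frame(grain = 100 / 3, rachis = 100 / 3, weeds = 100 / 3))
  expect_equal(as.numeric(centroid), c(0.5, s3 / 3), tolerance = 1e-9)
})

test_that("planar coordinates invert back to proportions (1e-12)", {
  set.seed(41)
  raw <- matrix(rexp(60), 20, 3)
  pr <- data.frame(100 * raw / rowSums(raw))
  colnames(pr) <- c("grain", "rachis", "weeds")
  back <- cropclass:::ternary_invert(ternary_coordinates(pr))
  expect_equal(back, pr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all plotted points fall inside the triangle", {
  pr <- triplot_proportions(table2_rows)
  xy <- ternary_coordinates(pr)
  s3 <- sqrt(3) / 2
  expect_true(all(xy$y >= -1e-12 & xy$y <= s3 + 1e-12))
  expect_true(all(xy$y <= sqrt(3) * xy$x + 1e-12))        # left edge
  expect_true(all(xy$y <= sqrt(3) * (1 - xy$x) + 1e-12))  # right edge
})

test_that("make_triplot honours highlights and warns as specified", {
  eth <- synthetic_triplot_reference(n_per_group = 5, seed = 42)
  refp <- triplot_proportions(eth$table)
  arch <- triplot_proportions(table2_rows)

  pdf(NULL)
  on.exit(dev.off())
  out <- make_triplot(arch, refp, reference_groups = eth$groups)
  expect_identical(out$highlighted, character(0))
  expect_identical(nrow(out$archaeological), nrow(arch))
  expect_identical(nrow(out$reference), nrow(refp))

  out2 <- make_triplot(arch, refp, highlight = "462")
  expect_identical(out2$highlighted, "462")

  expect_warning(make_triplot(arch, refp, highlight = "478"),
                 "478")

  small <- triplot_proportions(triplot_table(
    data.frame(sample = "tiny", grain = 5, rachis = 2, weeds = 3)))
  expect_warning(make_triplot(small, refp), "below 30")
})
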