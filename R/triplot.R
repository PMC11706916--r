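#' Grain : rachis : weeds percentages
#'
#' Converts per-sample totals of grain, rachis nodes and weed seeds into
#' percentages of the sample total, the three-component composition plotted
#' on the ternary diagram. Samples with a zero total are an error; apply the
#' minimum-items filter first.
#'
#' @param table a [triplot_table()].
#' @return A `ternary_points` data frame: `sample`, `grain`, `rachis`,
#'   `weeds` (percentages summing to 100), with the raw totals kept in the
#'   `"totals"` attribute.
#' @export
triplot_proportions <- function(table) {
  stopifnot(inherits(table, "triplot_table"))
  tot <- table$grain + table$rachis + table$weeds
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(table$sample[tot == 0], collapse = ", "),
         "; filter them out first", call. = FALSE)
  out <- data.frame(
    sample = table$sample,
    grain = 100 * table$grain / tot,
    rachis = 100 * table$rachis / tot,
    weeds = 100 * table$weeds / tot,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ternary_points", "data.frame")
  attr(out, "totals") <- tot
  out
}

#' Ternary (barycentric) to planar coordinates
#'
#' Maps grain/rachis/weeds percentages into the unit-side triangle with
#' grain at the apex (0.5, sqrt(3)/2), rachis at the lower-left (0, 0) and
#' weeds at the lower-right (1, 0).
#'
#' @param proportions a `ternary_points` data frame, or any data frame /
#'   matrix with columns `grain`, `rachis`, `weeds` in percent.
#' @return data frame with columns `x`, `y` (and `sample` if present).
#' @export
ternary_coordinates <- function(proportions) {
  pr <- as.data.frame(proportions)
  g <- pr$grain / 100
  w <- pr$weeds / 100
  out <- data.frame(x = w + g / 2, y = g * sqrt(3) / 2)
  if (!is.null(pr$sample)) out <- cbind(sample = pr$sample, out)
  out
}

# inverse of ternary_coordinates, used for round-trip checks
ternary_invert <- function(xy) {
  g <- xy$y * 2 / sqrt(3)
  w <- xy$x - g / 2
  data.frame(grain = 100 * g, rachis = 100 * (1 - g - w), weeds = 100 * w)
}

draw_triangle <- function(main) {
  s3 <- sqrt(3) / 2
  graphics::plot(NA, xlim = c(-0.1, 1.1), ylim = c(-0.12, s3 + 0.1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, s3))
  graphics::text(0.5, s3 + 0.06, "grain")
  graphics::text(-0.05, -0.06, "rachis")
  graphics::text(1.05, -0.06, "weeds")
}

#' Side-by-side ternary plot of ethnographic and archaeological proportions
#'
#' Draws two panels: the ethnographic reference proportions on the left
#' (symbol-coded by processing group) and the archaeological samples on the
#' right. Selected archaeological samples can be highlighted and labelled.
#' The default is monochrome. Samples whose raw totals fall below
#' `min_items_warn` trigger a warning (filtering is the caller's job).
#'
#' @param arch `ternary_points` for the archaeological samples.
#' @param reference `ternary_points` for the ethnographic samples.
#' @param reference_groups group label 1-4 per reference row (controls the
#'   plotting symbol).
#' @param highlight character vector of archaeological sample ids to label
#'   and emphasise; absent ids give a warning.
#' @param col,ref_col point colours for the two panels.
#' @param pch plotting symbol for archaeological points.
#' @param main_arch,main_ref panel titles.
#' @param min_items_warn totals below this trigger a warning (default 30).
#' @return Invisibly, a list with the planar coordinates of both panels.
#' @export
make_triplot <- function(arch, reference, reference_groups = NULL,
                         highlight = character(), col = "black",
                         ref_col = "black", pch = 1,
                         main_arch = "archaeological samples",
                         main_ref = "ethnographic samples",
                         min_items_warn = 30) {
  stopifnot(inherits(arch, "ternary_points"),
            inherits(reference, "ternary_points"))
  tot <- attr(arch, "totals")
  if (!is.null(tot) && any(tot < min_items_warn))
    warning("sample(s) below ", min_items_warn, " items: ",
            paste(arch$sample[tot < min_items_warn], collapse = ", "),
            call. = FALSE)
  missing_hl <- setdiff(highlight, arch$sample)
  if (length(missing_hl))
    warning("highlight id(s) not present: ",
            paste(missing_hl, collapse = ", "), call. = FALSE)

  ref_xy <- ternary_coordinates(reference)
  arch_xy <- ternary_coordinates(arch)
  old <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))

  draw_triangle(main_ref)
  ref_pch <- if (is.null(reference_groups)) rep(1L, nrow(reference))
             else c(1L, 2L, 3L, 4L)[as.integer(reference_groups)]
  graphics::points(ref_xy$x, ref_xy$y, pch = ref_pch, col = ref_col)

  draw_triangle(main_arch)
  graphics::points(arch_xy$x, arch_xy$y, pch = pch, col = col)
  hl <- intersect(highlight, arch$sample)
  if (length(hl)) {
    i <- match(hl, arch$sample)
    graphics::points(arch_xy$x[i], arch_xy$y[i], pch = 19, col = col)
    graphics::text(arch_xy$x[i], arch_xy$y[i], labels = hl, pos = 3)
  }
  invisible(list(reference = ref_xy, archaeological = arch_xy,
                 highlighted = hl))
}
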