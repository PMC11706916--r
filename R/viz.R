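#' 2D plot of discriminant scores
#'
#' Plots the ethnographic groups (symbol-coded 1-4) and the archaeological
#' samples on a chosen pair of discriminant functions. The coordinates are
#' taken verbatim from the classification result — for the five-group method
#' the reference coordinates were computed in the five-group model, never
#' reused from a four-group run — so no re-fitting happens inside plotting.
#'
#' @param result a `classification_result`.
#' @param axes integer pair of discriminant functions to display (default
#'   `c(1, 2)`); both must be distinct and at most the model's m.
#' @param labels sample ids to annotate with text; absent ids warn.
#' @param col colour for archaeological points (recycled per sample).
#' @param gcol colour for ethnographic points.
#' @param site legend label for the archaeological series.
#' @param pch plotting symbol for archaeological points.
#' @param main plot title.
#' @return Invisibly, a list with the plotted coordinates.
#' @export
plot_scores_2d <- function(result, axes = c(1, 2), labels = character(),
                           col = "black", gcol = "black",
                           site = "archaeological", pch = 17, main = NULL) {
  stopifnot(inherits(result, "classification_result"))
  m <- result$model$m
  check_axes(axes, 2L, m)
  if (is.null(main))
    main <- sprintf("%s-method discriminant scores", result$method)
  a1 <- axes[1L]; a2 <- axes[2L]
  rx <- result$ref_scores[, a1]; ry <- result$ref_scores[, a2]
  ax <- result$scores[, a1]; ay <- result$scores[, a2]
  xlim <- range(c(rx, ax)); ylim <- range(c(ry, ay))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = paste0("LD", a1), ylab = paste0("LD", a2),
                 main = main)
  graphics::points(rx, ry, pch = as.integer(result$ref_groups), col = gcol)
  graphics::points(ax, ay, pch = pch, col = col)
  missing_lab <- setdiff(labels, result$sample_ids)
  if (length(missing_lab))
    warning("label id(s) not present: ",
            paste(missing_lab, collapse = ", "), call. = FALSE)
  lab <- intersect(labels, result$sample_ids)
  if (length(lab)) {
    i <- match(lab, result$sample_ids)
    graphics::text(ax[i], ay[i], labels = lab, pos = 3)
  }
  graphics::legend("topright",
                   legend = c(unname(GROUP_LABELS[as.character(1:4)]), site),
                   pch = c(1:4, if (is.numeric(pch)) pch[1L] else 17),
                   col = c(rep(gcol[1L], 4L), col[1L]), cex = 0.7, bty = "n")
  invisible(list(reference = cbind(x = rx, y = ry),
                 archaeological = cbind(x = ax, y = ay), labelled = lab))
}

check_axes <- function(axes, k, m) {
  if (length(axes) != k || anyDuplicated(axes) ||
      any(axes < 1) || any(axes > m))
    stop("axes must be ", k, " distinct discriminant functions in 1..", m,
         if (m < k) "; this result has too few score columns for this plot"
         else "", call. = FALSE)
  invisible(axes)
}

#' Static 3D scatter of discriminant scores
#'
#' Renders three chosen discriminant functions as a 3D scatter under an
#' explicit camera (`theta`/`phi`, as in [graphics::persp()]); no automatic
#' viewpoint is chosen. Interactive rotation is outside the scope of an
#' offline build — render several camera angles instead.
#'
#' @inheritParams plot_scores_2d
#' @param axes integer triple of discriminant functions (default
#'   `c(1, 2, 3)`); requires a model with at least 3 functions, otherwise an
#'   error suggests the 2D plot.
#' @param theta,phi camera azimuth and colatitude in degrees (required
#'   explicitly for reproducible static export; defaults provided).
#' @return Invisibly, a list with the projected 2D coordinates of both
#'   series.
#' @export
plot_scores_3d <- function(result, axes = c(1, 2, 3), theta = 35, phi = 20,
                           labels = character(), col = "black",
                           gcol = "black", site = "archaeological",
                           pch = 17, main = NULL) {
  stopifnot(inherits(result, "classification_result"))
  m <- result$model$m
  if (m < 3L)
    stop("this result has only ", m, " discriminant function(s); ",
         "use plot_scores_2d()", call. = FALSE)
  check_axes(axes, 3L, m)
  if (is.null(main))
    main <- sprintf("%s-method discriminant scores (3D)", result$method)
  R <- result$ref_scores[, axes, drop = FALSE]
  A <- result$scores[, axes, drop = FALSE]
  all3 <- rbind(R, A)
  lims <- apply(all3, 2L, range)
  pad <- function(r) r + c(-0.05, 0.05) * diff(r)
  pm <- graphics::persp(x = pad(lims[, 1L]), y = pad(lims[, 2L]),
                        z = matrix(pad(lims[, 3L]), 2, 2),
                        xlim = pad(lims[, 1L]), ylim = pad(lims[, 2L]),
                        zlim = pad(lims[, 3L]),
                        theta = theta, phi = phi, border = NA, col = NA,
                        box = TRUE, axes = TRUE,
                        xlab = paste0("LD", axes[1L]),
                        ylab = paste0("LD", axes[2L]),
                        zlab = paste0("LD", axes[3L]), main = main)
  rp <- grDevices::trans3d(R[, 1L], R[, 2L], R[, 3L], pm)
  ap <- grDevices::trans3d(A[, 1L], A[, 2L], A[, 3L], pm)
  graphics::points(rp, pch = as.integer(result$ref_groups), col = gcol)
  graphics::points(ap, pch = pch, col = col)
  lab <- intersect(labels, result$sample_ids)
  if (length(setdiff(labels, result$sample_ids)))
    warning("label id(s) not present: ",
            paste(setdiff(labels, result$sample_ids), collapse = ", "),
            call. = FALSE)
  if (length(lab)) {
    i <- match(lab, result$sample_ids)
    graphics::text(ap$x[i], ap$y[i], labels = lab, pos = 3)
  }
  graphics::legend("topright",
                   legend = c(unname(GROUP_LABELS[as.character(1:4)]), site),
                   pch = c(1:4, if (is.numeric(pch)) pch[1L] else 17),
                   col = c(rep(gcol[1L], 4L), col[1L]), cex = 0.7, bty = "n")
  invisible(list(reference = rp, archaeological = ap, labelled = lab))
}
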