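#' Plot an arc diagram
#'
#' Draws each arc of [arcDiagram()] as a semicircle over the sequence axis;
#' line width scales with the expanded c-gram length. A convenience render —
#' the tabular export is the contract.
#'
#' @param result a [CompressionResult-class] (or an arc data.frame).
#' @param col arc colour.
#' @param ... passed to [graphics::plot()].
#' @return the arc data.frame, invisibly.
#' @export
plotArcDiagram <- function(result, col = "steelblue", ...) {
  arcs <- if (is(result, "CompressionResult")) arcDiagram(result) else result
  L <- if (is(result, "CompressionResult")) result@l else
    max(arcs$start2, 1L)
  graphics::plot(NA, xlim = c(1, max(L, 2)), ylim = c(0, max(L / 2, 1)),
                 xlab = "sequence position", ylab = "", yaxt = "n",
                 bty = "n", ...)
  if (nrow(arcs)) {
    th <- seq(0, pi, length.out = 64L)
    for (i in seq_len(nrow(arcs))) {
      a <- arcs$start1[i]
      b <- arcs$start2[i]
      r <- (b - a) / 2
      graphics::lines(a + r + r * cos(th), r * sin(th), col = col,
                      lwd = 0.5 + arcs$width[i] / 2)
    }
  }
  invisible(arcs)
}

#' Plot compressibility-versus-length curves
#'
#' @param curves a data.frame from [compressibilityCurve()], or a named list
#'   of them (one line each).
#' @param col line colours.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the input.
#' @export
plotCompressibilityCurve <- function(curves, col = NULL, ...) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (is.null(col)) col <- seq_along(curves)
  lens <- sort(unique(unlist(lapply(curves, `[[`, "length"))))
  ym <- max(unlist(lapply(curves, function(d) d$mean + d$sd)), 0.01)
  graphics::plot(NA, xlim = range(lens), ylim = c(0, min(1, ym * 1.05)),
                 xlab = "sequence length", ylab = "compressibility", ...)
  for (i in seq_along(curves)) {
    d <- curves[[i]]
    graphics::lines(d$length, d$mean, col = col[i], type = "b", pch = 16)
    has_sd <- d$sd > 0
    if (any(has_sd))
      graphics::arrows(d$length[has_sd], pmax(0, d$mean - d$sd)[has_sd],
                       d$length[has_sd], (d$mean + d$sd)[has_sd],
                       angle = 90, code = 3, length = 0.03, col = col[i])
  }
  if (!is.null(names(curves)))
    graphics::legend("topleft", legend = names(curves), col = col, lty = 1,
                     bty = "n")
  invisible(curves)
}
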