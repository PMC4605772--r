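# Base-graphics plot methods for the main result objects.

#' Plot a time-resolved information profile
#' @param x an \code{info_profile}.
#' @param normalized plot the normalized value (default) or raw bits.
#' @param ... passed to \code{plot}.
#' @export
plot.info_profile <- function(x, normalized = TRUE, ...) {
  y <- if (normalized) x$normalized else x$bits
  graphics::plot(x$time, y, type = "l", lwd = 2,
                 xlab = "time (s)",
                 ylab = if (normalized) "normalized MI" else "bits",
                 main = paste(attr(x, "measure"), "profile:",
                              paste(attr(x, "variables"), collapse = "+")),
                 ...)
  invisible(x)
}

#' Plot a specific-information surface
#' @param x an \code{info_surface}.
#' @param ... passed to \code{image}.
#' @export
plot.info_surface <- function(x, ...) {
  graphics::image(x$time, x$s_mids, x$bits, xlab = "time (s)",
                  ylab = "stimulus", main = paste(
                    "specific information:",
                    paste(x$variables, collapse = "+")), ...)
  invisible(x)
}

#' Plot a closed-loop trajectory over its gradient field
#' @param x a \code{trajectory}.
#' @param ... passed to \code{plot}.
#' @export
plot.trajectory <- function(x, ...) {
  field <- attr(x, "field")
  graphics::plot(x$x, x$y, type = "l", asp = 1, xlab = "x (cm)",
                 ylab = "y (cm)", main = "closed-loop klinotaxis run", ...)
  if (!is.null(field)) {
    graphics::points(field$peak[1], field$peak[2], pch = 19, col = "red")
    for (r in field$length_scale * c(0.25, 0.5, 0.75))
      graphics::symbols(field$peak[1], field$peak[2], circles = r,
                        inches = FALSE, add = TRUE, fg = "grey")
  }
  graphics::points(x$x[1], x$y[1], pch = 1)
  invisible(x)
}

#' Plot SMB gating curves
#' @param x a \code{gating_curves} object.
#' @param which \code{"fixed_delay"} or \code{"delay_averaged"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.gating_curves <- function(x, which = c("fixed_delay",
                                            "delay_averaged"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  graphics::matplot(x$phases, m, type = "l", lty = c(2, 2, 1, 1), lwd = 2,
                    col = c("blue", "red", "blue", "red"),
                    xlab = "onset phase (rad)", ylab = "normalized MI",
                    main = paste("SMB information gating,",
                                 gsub("_", " ", which)), ...)
  graphics::legend("topright", colnames(m), lty = c(2, 2, 1, 1),
                   col = c("blue", "red", "blue", "red"), lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot the empirical distribution of perceived concentration changes
#' @param x a \code{cdot_distribution}.
#' @param ... passed to \code{plot}.
#' @export
plot.cdot_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$p, type = "h", lwd = 3,
                 xlab = "perceived concentration change (per s)",
                 ylab = "probability", ...)
  invisible(x)
}

#' Diagnostic plot of a cell's synaptic transfer function
#'
#' Shows \eqn{\sigma(V + \theta)} for one cell over a net-input range, a
#' direct visualization of the saturation mechanism behind information
#' asymmetry and gating.
#'
#' @param params a \code{circuit_params}.
#' @param cell cell name (e.g. \code{"AIYR"}).
#' @param input_range net input range to display.
#' @param ... passed to \code{curve}.
#' @export
plot_transfer_function <- function(params, cell,
                                   input_range = c(-15, 15), ...) {
  theta <- params[[paste0("theta_", cell)]]
  f <- function(v) synaptic_output(v, theta)
  graphics::curve(f, input_range[1], input_range[2], lwd = 2,
                  xlab = "membrane potential", ylab = "synaptic output",
                  main = sprintf("%s transfer function (theta = %.2f)",
                                 cell, theta), ...)
  invisible(params)
}
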