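# Profile plots: cumulative percent of dose collected versus time, the
# primary readout of the dissolution cell. Base graphics, in the style of
# the flow-through-cell literature; CSV remains the primary artifact.

#' Plot a simulated permeation profile
#'
#' Cumulative percent of the dose collected versus time.
#'
#' @param x a `permeation_sim`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.permeation_sim <- function(x, ...) {
  args <- list(x = x$times, y = x$pct_collected, type = "l",
               xlab = "time (min)", ylab = "% of dose collected",
               ylim = c(0, 100),
               main = sprintf("%s, %s, %s", x$drug$name, x$run$dose_form,
                              sub("_", "-", x$run$stirring)))
  user <- list(...)
  args[names(user)] <- user
  do.call(graphics::plot, args)
  invisible(x)
}

#' Plot a sensitivity sweep
#'
#' Overlays the permeation profiles of every sweep value.
#'
#' @param x a `sweep_result`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, ...) {
  times <- x$results[[1L]]$times
  mat <- sapply(x$results, function(r) r$pct_collected)
  graphics::matplot(times, mat, type = "l", lty = 1,
                    col = seq_along(x$values),
                    xlab = "time (min)", ylab = "% of dose collected",
                    main = sprintf("Sweep over %s", x$parameter), ...)
  graphics::legend("bottomright", legend = signif(x$values, 4),
                   col = seq_along(x$values), lty = 1,
                   title = x$parameter, bty = "n")
  invisible(x)
}
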