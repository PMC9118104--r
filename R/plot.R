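# Diagnostic plots: positional variance diagram, staging histogram, and
# per-event mixture fits.

#' Plot a positional variance diagram
#'
#' Heatmap of the event-by-position probability matrix, rows ordered by the
#' maximum-likelihood sequence (earliest event on top) so a confident fit
#' shows a dark diagonal.
#'
#' @param pv Z x Z positional-variance matrix (rows = events).
#' @param ml_sequence Optional permutation used to order the rows.
#' @param main Plot title.
#' @export
plot_pvd <- function(pv, ml_sequence = NULL, main = "Positional variance") {
  if (!is.null(ml_sequence)) pv <- pv[ml_sequence, , drop = FALSE]
  z <- nrow(pv)
  pal <- grDevices::colorRampPalette(c("white", "darkred"))(64)
  graphics::image(seq_len(z), seq_len(z), t(pv[z:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "Position in sequence", ylab = "", main = main)
  graphics::axis(1, at = seq_len(z))
  graphics::axis(2, at = seq_len(z), labels = rev(rownames(pv)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(pv)
}

#' Plot a staging histogram
#'
#' Per-group proportions of subjects at each model stage, the standard
#' summary of how cases spread across disease stages while controls cluster
#' at stage 0.
#'
#' @param staging An `ebm_staging` data frame.
#' @param main Plot title.
#' @export
plot_staging_histogram <- function(staging, main = "Model staging") {
  h <- staging_histogram(staging)
  graphics::barplot(h, beside = TRUE, legend.text = rownames(h),
                    xlab = "Stage", ylab = "Proportion of group", main = main,
                    col = c("darkorange", "steelblue")[seq_len(nrow(h))])
  invisible(h)
}

#' Plot a fitted KDE mixture for one event
#'
#' Histogram of the pooled adjusted values with the fitted normal and
#' abnormal component densities (weighted by mixing fraction) and the
#' monotone posterior probability of abnormality.
#'
#' @param fit A `kde_mixture`.
#' @param control_values,case_values The data the fit was built from.
#' @param main Plot title.
#' @export
plot_mixture_fit <- function(fit, control_values, case_values,
                             main = "KDE mixture fit") {
  x <- c(control_values, case_values)
  g <- fit$posterior_grid
  f_n <- kde_eval(fit$normal$locs, fit$normal$w, fit$normal$h, g$x)
  f_a <- kde_eval(fit$abnormal$locs, fit$abnormal$w, fit$abnormal$h, g$x)
  graphics::hist(x, breaks = 30, freq = FALSE, col = "grey90",
                 border = "grey70", main = main, xlab = "Adjusted volume")
  graphics::lines(g$x, (1 - fit$theta) * f_n, col = "steelblue", lwd = 2)
  graphics::lines(g$x, fit$theta * f_a, col = "darkred", lwd = 2)
  sc <- max(graphics::hist(x, breaks = 30, plot = FALSE)$density)
  graphics::lines(g$x, g$posterior * sc, col = "black", lty = 2)
  invisible(fit)
}
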