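# Base-graphics diagnostics.

#' @export
plot.sc_matrix <- function(x, ...) {
  v <- x$values
  nd <- nrow(v)
  graphics::image(seq_len(nd), seq_len(nd), t(v[nd:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "surround", ylab = "center",
                  main = paste0(x$cell_id,
                                if (x$aligned) " (aligned)" else ""), ...)
  graphics::axis(1, seq_len(nd), colnames(v), cex.axis = 0.7)
  graphics::axis(2, seq_len(nd), rev(rownames(v)), cex.axis = 0.7, las = 1)
  invisible(x)
}

#' @export
plot.sc_popcurves <- function(x, ...) {
  rels <- unique(x$relationship)
  cols <- c(center_alone = "black", `0` = "darkgreen", `45` = "olivedrab",
            `90` = "orange", `135` = "salmon", `180` = "red")
  graphics::plot(NA, xlim = range(x$rel_dir), ylim = range(x$mean),
                 xlab = "center direction rel. preferred (deg)",
                 ylab = "mean dF/F0", ...)
  col_of <- function(r) {
    cc <- unname(cols[r])
    if (is.na(cc)) "grey40" else cc
  }
  for (r in rels) {
    d <- x[x$relationship == r, ]
    graphics::lines(d$rel_dir, d$mean, col = col_of(r), lwd = 2)
  }
  graphics::legend("topright", legend = rels, lwd = 2, cex = 0.7,
                   col = vapply(rels, col_of, character(1)))
  invisible(x)
}

#' @export
plot.sc_modfit <- function(x, ...) {
  graphics::plot(x$center, x$cs, pch = 19,
                 xlab = "center alone (dF/F0)",
                 ylab = "center with surround (dF/F0)", ...)
  graphics::abline(x$intercept, x$slope, col = "red", lwd = 2)
  graphics::abline(0, 1, col = "blue", lty = 2)
  invisible(x)
}
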