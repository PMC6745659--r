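# Print/summary/plot methods for simulation results.

#' @export
print.jg_replicate <- function(x, ...) {
  yrs <- sum(!is.na(x$trajectory[, "density"]))
  cat("Johnsongrass replicate:", yrs, "simulated years\n")
  if (!is.na(x$failure_year))
    cat("  weed control failed in year", x$failure_year, "\n")
  else cat("  weed control held over the horizon\n")
  if (x$accase_resistant)
    cat("  evolved ACCase resistance, first in year", x$accase_res_year, "\n")
  if (x$glyph_resistant)
    cat("  quantitative (glyphosate) resistant fraction above threshold,",
        "first in year", x$glyph_res_year, "\n")
  invisible(x)
}

#' @export
plot.jg_replicate <- function(x, ...) {
  tr <- x$trajectory
  yrs <- seq_len(nrow(tr))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(yrs, tr[, "density"], type = "b", pch = 16,
                 xlab = "year", ylab = "plants / m2",
                 main = "standing density at census", ...)
  if (!is.na(x$failure_year))
    graphics::abline(v = x$failure_year, lty = 2, col = "red")
  graphics::plot(yrs, tr[, "frac_sg"], type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "year", ylab = "resistant fraction",
                 main = "resistant fraction of standing plants")
  graphics::lines(yrs, tr[, "frac_qt"], type = "b", pch = 1, col = "blue")
  graphics::legend("topleft", c("single gene (RR/RS)", "Pz >= dose"),
                   pch = c(16, 1), col = c("black", "blue"), bty = "n")
  invisible(x)
}

#' @export
print.jg_ensemble <- function(x, ...) {
  s <- x$summary
  cat("Johnsongrass ensemble",
      if (!is.null(x$scenario_id)) paste0("(scenario ", x$scenario_id, ")"),
      "-", s$n_replicates, "replicates\n")
  cat(sprintf("  ACCase-R probability:      %5.1f %%\n",
              100 * s$accase_r_probability))
  cat(sprintf("  glyphosate-R probability:  %5.1f %%\n",
              100 * s$glyph_r_probability))
  cat(sprintf("  control failure:           %5.1f %%",
              100 * s$failure_probability))
  if (!is.na(s$mean_failure_year))
    cat(sprintf(", mean failure year %.1f", s$mean_failure_year))
  cat("\n")
  if (!is.na(s$seedbank_rhizome_ratio))
    cat(sprintf("  seedbank : tertiary-rhizome density ratio: %.2f\n",
                s$seedbank_rhizome_ratio))
  invisible(x)
}

#' @export
summary.jg_ensemble <- function(object, ...) object$summary

#' @export
plot.jg_ensemble <- function(x, ...) {
  if (!is.null(x$trajectories)) {
    yrs <- seq_len(nrow(x$trajectories[[1L]]))
    dens <- vapply(x$trajectories, function(tr) tr[, "density"],
                   numeric(length(yrs)))
    graphics::matplot(yrs, dens, type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey30", 0.25),
                      xlab = "year", ylab = "plants / m2",
                      main = "density trajectories", ...)
    graphics::abline(h = x$config$density_threshold, lty = 2, col = "red")
  } else {
    fy <- x$replicates$failure_year
    if (all(is.na(fy))) {
      graphics::plot.new()
      graphics::title("no replicate reached the failure threshold")
    } else {
      graphics::hist(fy[!is.na(fy)], breaks = seq(0.5, 30.5, 1),
                     xlab = "failure year", main = "year of control failure",
                     col = "grey80", ...)
    }
  }
  invisible(x)
}

#' @export
print.jg_sensitivity <- function(x, ...) {
  cat("One-at-a-time sensitivity analysis (",
      attr(x, "n_replicates"), " replicates per ensemble)\n", sep = "")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
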