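#' @export
plot.epx_sim <- function(x, which = c("abundance", "richness", "saturation"),
                         ...) {
  which <- match.arg(which)
  s <- x$summary
  y <- switch(which,
              abundance = s$abundance / x$area_ha,
              richness = s$richness,
              saturation = s$saturation)
  ylab <- switch(which,
                 abundance = "abundance (individuals / ha)",
                 richness = "species richness",
                 saturation = "saturation (%)")
  graphics::plot(s$year, y, type = "l", xlab = "year", ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.epx_experiment <- function(x, which = c("saturation", "abundance",
                                             "richness"), ...) {
  which <- match.arg(which)
  a <- x$aggregate
  if (is.null(a)) stopf("no completed runs to plot")
  col <- switch(which, saturation = "saturation_mean",
                abundance = "abundance_ha_mean", richness = "richness_mean")
  scen <- unique(a$scenario)
  graphics::plot(range(a$year), range(a[[col]]), type = "n", xlab = "year",
                 ylab = which, ...)
  for (i in seq_along(scen)) {
    d <- a[a$scenario == scen[i], ]
    graphics::lines(d$year, d[[col]], col = i)
  }
  graphics::legend("topright", legend = scen, col = seq_along(scen),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
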