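#' Save / load a model checkpoint
#'
#' A checkpoint stores the configuration, all weight banks, the adaptive
#' state (`rho`, `ybar`, `S`, `s_max`, gap-junction kernel), the RNG stream
#' states and the iteration counter, so a run can be resumed or analyzed
#' later bit-for-bit.
#'
#' @param model An [astro_model()].
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `astro_model`.
#' @export
save_checkpoint <- function(model, path) {
  chk <- list(config = model$config, W = model$W,
              rho = model$rho, ybar = model$ybar, S = model$S,
              y = model$y, gs = model$gs, s_max = model$s_max,
              gj_kernel = model$gj_kernel,
              stream_states = lapply(model$streams, function(s) s$state),
              iteration = model$iteration,
              degenerate_redraws = model$degenerate_redraws)
  saveRDS(chk, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  chk <- readRDS(path)
  m <- astro_model(chk$config)
  for (f in c("W", "rho", "ybar", "S", "y", "gs", "s_max", "gj_kernel",
              "iteration", "degenerate_redraws"))
    assign(f, chk[[f]], envir = m)
  for (nm in names(chk$stream_states))
    m$streams[[nm]]$state <- chk$stream_states[[nm]]
  m
}

# serialized image of everything plasticity may touch; used to verify that
# probing leaves the model untouched
model_state_image <- function(model) {
  serialize(list(model$W, model$rho, model$ybar, model$s_max,
                 model$iteration,
                 lapply(model$streams, function(s) s$state)),
            NULL, version = 2)
}

#' Write a sweep summary to CSV
#'
#' @param sweep Data frame from [run_sweep()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}

#' Render an orientation map as an HSV image
#'
#' Hue encodes the preferred orientation, value the selectivity (scaled to
#' its maximum). Optionally overlays detected pinwheel centres.
#'
#' @param map An `orientation_map`.
#' @param file Optional PNG path; `NULL` draws to the current device.
#' @param pinwheels Optional `pinwheel_set` to overlay.
#' @param px Image size per axis in pixels (PNG only).
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_orientation_map <- function(map, file = NULL, pinwheels = NULL,
                                 px = 480) {
  sel <- map$selectivity
  v <- if (max(sel) > 0) sel / max(sel) else sel
  col <- grDevices::hsv(h = as.vector(map$preference) / pi, s = 1,
                        v = as.vector(v))
  n1 <- nrow(map$preference); n2 <- ncol(map$preference)
  img <- matrix(col, n1, n2)
  if (!is.null(file)) grDevices::png(file, px, px)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0.5, n2 + 0.5), ylim = c(0.5, n1 + 0.5),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s map, iteration %s", map$layer,
                                map$iteration))
  graphics::rasterImage(img, 0.5, 0.5, n2 + 0.5, n1 + 0.5,
                        interpolate = FALSE)
  if (!is.null(pinwheels) && pinwheels$count > 0)
    graphics::points(pinwheels$centers[, 2], n1 + 1 - pinwheels$centers[, 1],
                     pch = ifelse(pinwheels$charges > 0, 3, 4),
                     col = "white", cex = 0.8)
  invisible(file)
}

#' Plot a radial power spectrum and its fitted peak
#'
#' @param fit A `spectrum_fit`.
#' @return `NULL`, invisibly.
#' @export
plot_spectrum_fit <- function(fit) {
  graphics::plot(fit$k, fit$P, type = "b", pch = 16, cex = 0.6,
                 xlab = "k (cycles per map)", ylab = "P(k)",
                 main = sprintf("zeta = %.2f, Lambda = %.2f mm",
                                fit$zeta, fit$lambda_mm))
  if (fit$quality == "fit") {
    kk <- seq(min(fit$k), max(fit$k), length.out = 200)
    cf <- fit$coef
    graphics::lines(kk, cf["a0"] * exp(-(kk - cf["a1"])^2 / (2 * cf["a2"]^2)) +
                      cf["a3"] + cf["a4"] * kk + cf["a5"] * kk^2, col = 2)
  }
  graphics::abline(v = fit$zeta, lty = 2)
  invisible(NULL)
}
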