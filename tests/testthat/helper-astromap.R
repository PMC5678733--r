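# small desk-scale configurations used across tests

tiny_config <- function(density = 12, ...) {
  model_config(density = density, rad_A = 0.27, rad_I = 0.22,
               settling_steps = 4, lgn_settle_steps = 2, seed = 7, ...)
}

small_config <- function(...) {
  model_config(density = 24, seed = 11, ...)
}

# centred full-contrast training stimulus on a model's retina
centre_stimulus <- function(m, orientation = pi / 6, amplitude = 1) {
  cfg <- m$config
  structure(list(center = rep(m$retina$origin + m$retina$extent / 2, 2),
                 orientation = orientation,
                 sigma_major = cfg$sigma_major,
                 sigma_minor = cfg$sigma_minor,
                 amplitude = amplitude),
            class = "training_stimulus")
}

# brute-force disc pooling (independent oracle for astrocyte activation)
pool_disc_oracle <- function(field, radius_px) {
  nr <- nrow(field); nc <- ncol(field)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    s <- 0
    for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
      if ((ii - i)^2 + (jj - j)^2 <= radius_px^2) s <- s + field[ii, jj]
    }
    out[i, j] <- s
  }
  out
}
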