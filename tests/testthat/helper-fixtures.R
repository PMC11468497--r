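# Small shared fixtures built in code at test time.

straight_path <- function(L = 20, w = 400) {
  centerline_path(c(0, L), c(0, 0), w)
}

default_section <- function() channel_section(400, 300)

# brute-force per-pixel classification oracle (independent of the
# vectorized path in classify_pixels)
brute_force_counts <- function(img, roi_, calib) {
  n_mixed <- n_unmixed <- 0L
  inbox <- function(px, b) {
    px[1] >= b[1] && px[1] <= b[2] && px[2] >= b[3] && px[2] <= b[4] &&
      px[3] >= b[5] && px[3] <= b[6]
  }
  for (r in roi_$rows) for (cc in roi_$cols) {
    px <- img[r, cc, 1:3]
    if (inbox(px, calib$mixed)) n_mixed <- n_mixed + 1L
    else if (inbox(px, calib$blue) || inbox(px, calib$yellow))
      n_unmixed <- n_unmixed + 1L
  }
  list(n_mixed = n_mixed, n_unmixed = n_unmixed)
}

# brute-force 1D diffusion of a step profile between no-flux walls:
# independent finite-difference oracle for the eigenmode series
fd_step_diffusion_mi <- function(t_end, W_m, D, n = 400) {
  h <- W_m / n
  y <- rep(c(0, 1), each = n / 2)
  dt <- 0.2 * h^2 / D
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  for (k in seq_len(nt)) {
    yp <- c(y[1], y, y[n])          # zero-flux ghosts
    y <- y + D * dt / h^2 * (yp[1:n] - 2 * y + yp[3:(n + 2)])
  }
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  1 - psd(y) / 0.5
}
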