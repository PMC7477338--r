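# Brute-force oracles and small fixtures shared across tests.  Every
# oracle is an independent re-derivation: a dense-grid scan or a direct
# transcription of the defining formula, never a call into the code path
# it checks.

# direct transcription of the difference-of-Gaussians formula
dog_direct <- function(f, re, we, ri, wi) {
  re * exp(-(f^2) / (2 * we^2)) - ri * exp(-(f^2) / (2 * wi^2))
}

# dense-grid characteristics at 1e-3 Hz resolution over [0.05, 32] Hz:
# argmax plus the nearest half-maximum crossings below/above it
bf_characteristics <- function(re, we, ri, wi, lo = 0.05, hi = 32) {
  f <- seq(lo, hi, by = 1e-3)
  v <- dog_direct(f, re, we, ri, wi)
  i <- which.max(v)
  if (v[i] <= 0) return(list(f_opt = NA, f_low_half = NA, f_high_half = NA))
  half <- v[i] / 2
  below <- which(f < f[i] & v < half)
  above <- which(f > f[i] & v < half)
  list(
    f_opt = f[i],
    f_low_half = if (length(below)) f[max(below)] else NA_real_,
    f_high_half = if (length(above)) f[min(above)] else NA_real_
  )
}

# dense-grid scan for the contrast where a Naka-Rushton curve reaches a
# fraction q of its 100%-contrast value (1e-3 % resolution)
bf_quartile_contrast <- function(r_max, sigma, n, q, hi = 1000) {
  cc <- seq(1e-3, hi, by = 1e-3)
  v <- r_max * cc^n / (sigma^n + cc^n)
  target <- q * r_max * 100^n / (sigma^n + 100^n)
  if (target <= 0) return(NA_real_)
  i <- which(v >= target)
  if (!length(i)) return(NA_real_)
  cc[min(i)]
}

# a noiseless condition-response tibble generated directly from the
# static normalization surface formula
make_static_surface <- function(params,
                                tf = c(0.5, 1, 2, 4, 8, 16),
                                contrasts = c(10, 30, 50, 70, 90)) {
  grid <- expand.grid(tf_hz = tf, contrast_pct = contrasts)
  tt <- dog_direct(grid$tf_hz, params$t_gain_e %||% 1, params$t_width_e,
                   params$t_gain_i, params$t_width_i)
  cn <- grid$contrast_pct^params$n
  grid$mean_rate <- params$r_max * cn / (params$sigma^params$n / tt + cn)
  grid$sem <- 0
  out <- tibble::as_tibble(grid)
  class(out) <- c("population_surface", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compact protocol used by smoke tests (full factorial, fewer cells)
quick_protocol <- function() {
  stimulus_protocol(directions = c(0, 90), repeats = 3)
}
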