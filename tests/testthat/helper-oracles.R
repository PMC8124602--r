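# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity with naive loops rather than
# calling into the code paths they verify.

# summed per-target MSE, explicit double loop
naive_total_loss <- function(estimates, measured) {
  total <- 0
  for (v in seq_len(ncol(measured))) {
    acc <- 0
    for (m in seq_len(nrow(measured))) acc <- acc + (measured[m, v] - estimates[m, v])^2
    total <- total + acc / nrow(measured)
  }
  total
}

naive_rmse <- function(y, yhat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - yhat[i])^2
  sqrt(acc / length(y))
}

naive_mae <- function(y, yhat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs(y[i] - yhat[i])
  acc / length(y)
}

naive_mre <- function(y, yhat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs(y[i] - yhat[i]) / y[i]
  acc / length(y) * 100
}

naive_r_squared <- function(y, yhat) {
  ss_res <- 0; ss_tot <- 0; mu <- sum(y) / length(y)
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - mu)^2
  }
  1 - ss_res / ss_tot
}

# bilinear resampler with half-pixel centre alignment, plain double loop
naive_resize <- function(x, oh, ow) {
  ih <- nrow(x); iw <- ncol(x)
  y <- matrix(0, oh, ow)
  for (r in seq_len(oh)) {
    for (c in seq_len(ow)) {
      sr <- (r - 0.5) * ih / oh - 0.5
      sc <- (c - 0.5) * iw / ow - 0.5
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0; fc <- sc - c0
      cl <- function(v, n) min(max(v, 0), n - 1) + 1
      y[r, c] <- (1 - fr) * ((1 - fc) * x[cl(r0, ih), cl(c0, iw)] +
                               fc * x[cl(r0, ih), cl(c0 + 1, iw)]) +
        fr * ((1 - fc) * x[cl(r0 + 1, ih), cl(c0, iw)] +
                fc * x[cl(r0 + 1, ih), cl(c0 + 1, iw)])
    }
  }
  y
}

# trigger scan: enumerate qualifying windows, then apply the cooldown rule
brute_force_events <- function(w, window = 4, max_spread = 0.2,
                               rng = c(16.5, 117), refractory = window) {
  qualifying <- integer()
  if (length(w) >= window) {
    for (i in window:length(w)) {
      win <- w[(i - window + 1):i]
      if (all(win >= rng[1] & win <= rng[2]) && (max(win) - min(win)) < max_spread)
        qualifying <- c(qualifying, i)
    }
  }
  events <- integer()
  last <- -Inf
  for (i in qualifying) {
    if (i - last >= refractory) {
      events <- c(events, i)
      last <- i
    }
  }
  events
}

# loft volume by fine numeric integration of the section-area profile
# (independent of the exact per-segment Simpson closed form)
numeric_volume_cm3 <- function(phen, as_imaged = FALSE, n = 20000) {
  prof <- pigdepth:::body_profile(phen, as_imaged = as_imaged)
  s <- seq(min(prof$s), max(prof$s), length.out = n)
  w <- approx(prof$s, prof$w, s)$y
  a <- approx(prof$s, prof$a, s)$y
  area <- (pi / 2) * w * a
  sum((area[-1] + area[-n]) / 2 * diff(s))
}

# integral of the rendered height field, cm^3
rendered_volume_cm3 <- function(img, config) {
  sum(config$camera_distance_mm - as.numeric(img)) * config$mm_per_pixel^2 / 1000
}

# small scene config used across tests
tiny_scene <- function(..., size = 64) {
  scene_config(image_height_px = size, image_width_px = size, ...)
}
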