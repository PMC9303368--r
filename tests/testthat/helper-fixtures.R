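# Small fixtures built in code, shared across test files.

make_locs <- function(x, y, frame, photons = 400, width = 300,
                      background = 1) {
  data.frame(x = x, y = y, frame = frame,
             photons = rep_len(photons, length(x)),
             width = rep_len(width, length(x)),
             background = rep_len(background, length(x)))
}

# PALM frames of the default 10-frame shutter cycle, in order
palm_frames_default <- function(n) {
  f <- seq_len(ceiling(n / 8) * 10 + 10)
  f[frame_role(f) == "palm"][seq_len(n)]
}

# Brownian trace with localization noise, on a supplied frame vector
brownian_trace <- function(frames, D, dt = 0.05, noise_um = 0,
                           x0 = 0, y0 = 0) {
  gaps <- c(0, diff(frames)) * dt
  x <- x0 + cumsum(c(0, stats::rnorm(length(frames) - 1, 0,
                                     sqrt(2 * D * gaps[-1]))))
  y <- y0 + cumsum(c(0, stats::rnorm(length(frames) - 1, 0,
                                     sqrt(2 * D * gaps[-1]))))
  make_locs(x + stats::rnorm(length(x), 0, noise_um),
            y + stats::rnorm(length(y), 0, noise_um), frames)
}
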