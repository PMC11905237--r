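# Shared fixtures for the suite. The packaged beam model is loaded once.

.model_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.model_cache$m)) .model_cache$m <- unity_beam_model()
  .model_cache$m
}

# variant of the packaged model with selected profile parameters replaced
model_with_profiles <- function(asymmetry_shift = NULL, horn_slope = NULL) {
  m <- test_model()
  p <- m$profiles
  if (!is.null(asymmetry_shift)) {
    p$asymmetry_shift <- rep(asymmetry_shift, length(p$sides))
  }
  if (!is.null(horn_slope)) p$horn_slope <- rep(horn_slope, length(p$sides))
  m$profiles <- p
  m
}

# printed PDD nodes of the packaged model's commissioning comparison:
# depth mm -> (side mm -> table value)
printed_pdd_nodes <- function() {
  data.frame(
    side = rep(c(20, 30, 50, 100, 220), times = 3),
    depth = rep(c(50, 100, 130), each = 5),
    value = c(0.830, 0.839, 0.857, 0.880, 0.885,
              0.634, 0.649, 0.674, 0.708, 0.724,
              0.528, 0.538, 0.563, 0.602, 0.629)
  )
}

# the published DLG optimization grid: candidate, primary mean diff %,
# adaptive mean diff % (12 primary, 10 adaptive plans)
published_dlg_trials <- function() {
  grid <- rbind(
    c(0.00, 1.62, 1.55),
    c(0.01, 1.43, 1.61),
    c(0.02, 1.49, 1.70),
    c(0.10, 1.56, 2.22),
    c(0.15, 1.73, 2.65),
    c(0.20, 2.08, 3.29),
    c(1.00, 9.81, 9.76)
  )
  lapply(seq_len(nrow(grid)), function(i) {
    dlg_trial(grid[i, 1], grid[i, 2], grid[i, 3],
              n_primary = 12, n_adaptive = 10)
  })
}

# smooth random 1-D dose profile for gamma tests: FFF-like plateau with
# penumbra, plus low-frequency noise
random_profile <- function(seed, n = 200, half_width = 60, noise = 0.02) {
  set.seed(seed)
  x <- seq(-100, 100, length.out = n)
  prof <- 0.5 * ((2 * pnorm((half_width - x) / 4 * sqrt(2)) - 1) +
                   (2 * pnorm((x + half_width) / 4 * sqrt(2)) - 1))
  wig <- sin(x / 17 + runif(1, 0, 2 * pi)) * noise +
    sin(x / 41 + runif(1, 0, 2 * pi)) * noise
  data.frame(position_mm = x, dose = pmax(prof * (1 + wig), 0.001))
}
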