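# Fixtures are generated once per test run and cached; everything is built in
# code (no binary fixtures on disk).
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = fixture_env)) assign(name, fn(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# A reduced phantom (smaller FOV, 2 high-b averages -> 36 frames) for unit
# tests; the acceptance suite uses the full protocol scale.
small_phantom_params <- function(...) {
  phantom_params(
    shape = c(64L, 48L), center = c(32.5, 24.5),
    n_averages_high = 2L, motion_period_frames = 7.3, ...
  )
}

ph_small_clean <- function() {
  fixture("ph_small_clean", function() {
    make_phantom(small_phantom_params(snr = Inf, motion_amplitude_px = 0))
  })
}

ph_small_motion <- function() {
  fixture("ph_small_motion", function() {
    make_phantom(small_phantom_params(snr = 20, motion_amplitude_px = 4, seed = 1))
  })
}

ph_protocol_clean <- function() {
  fixture("ph_protocol_clean", function() {
    make_phantom(phantom_params(snr = Inf, motion_amplitude_px = 0))
  })
}

# uniform translation field helper
uniform_field <- function(shape, dr = 0, dc = 0) {
  list(dr = matrix(dr, shape[1], shape[2]), dc = matrix(dc, shape[1], shape[2]))
}

# random 3D rotation matrix from a fixed seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

tensor6_from_matrix <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}
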