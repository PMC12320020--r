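# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small slab + 3x3 pad used by forward/inverse unit tests
small_system <- function() fixture("small_system", function() {
  ph <- slab_phantom(c(40, 40, 24), voxel_mm = 2)
  g <- checkerboard_grid(9.75, 3, 3, origin = c(10, 10, 0))
  ch <- enumerate_channels(g, 40, wavelengths = 830)
  A <- slab_sensitivity(g, ch, ph, 830)
  op <- inverse_operator(A)
  list(phantom = ph, grid = g, channels = ch, A = A, op = op)
})

# default noisy synthetic session (auditory protocol)
default_session <- function() fixture("default_session", function() {
  make_session(session_spec(), seed = 3)
})

# noiseless session for exact-recovery tests
clean_session <- function() fixture("clean_session", function() {
  make_session(session_spec(noise = NULL, superficial_amp = 0,
                            cardiac_amp = 0), seed = 1)
})

# reconstructed HbO/HbR series (1 Hz) for the default noisy session
recon_hemo <- function(ses) {
  ops <- lapply(ses$A, inverse_operator)
  xs <- lapply(names(ops), function(w) {
    y <- final_filter_downsample(temporal_filter(ses$y[[w]]))
    reconstruct(ops[[w]], y)
  })
  names(xs) <- names(ops)
  spectroscopy(xs[["685"]], xs[["830"]])
}

expect_setequal_num <- function(a, b, tol = 1e-9) {
  expect_equal(sort(a), sort(b), tolerance = tol)
}
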