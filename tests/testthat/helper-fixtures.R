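# shared fixtures, built once per test session and cached
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) {
    assign(key, builder(), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# configuration-I dataset used by several processing tests
fixture_dataset <- function(n = 120, seed = 42) {
  cached(sprintf("ds_%d_%d", n, seed), function() {
    simulate_dataset(default_system(), protocol_spec(seed = seed), n)
  })
}

# paper-fitted Bell parameter sets for the three transition classes
intact_params <- function() bell_params(k_off = 7.3e-7, delta_x = 0.13)
shielded_params <- function() bell_params(k_off = 4.7e-4, delta_x = 0.19)
xmod_params <- function() bell_params(k_off = 2.6e-6, delta_x = 0.15)

# independent FRC oracle: direct transcription of the two-regime response,
# kept separate from the package implementation
oracle_frc_ratio <- function(force, b = 0.11, gamma = 41, kBT = 4.114) {
  g <- gamma * pi / 180
  lp <- b * cos(g / 2) / abs(log(cos(g)))
  fstar <- kBT * lp / b^2
  vapply(force, function(f) {
    if (f > fstar) {
      1 - kBT / (2 * f * b)
    } else {
      fr <- f * lp / kBT
      stats::uniroot(function(u) 4 * u^3 + 4 * (fr - 0.75) * u^2 - 1,
                     c(1e-12, 1), tol = 1e-12)$root |> (\(u) 1 - u)()
    }
  }, numeric(1))
}
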