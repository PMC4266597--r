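test_that("with no kinetics the trace is a smooth monotone pull", {
  sys <- system_spec(
    domains = list(domain_spec("inert", 30, 2, kinetics = NULL)),
    complex_intact = NULL, complex_shielded = NULL
  )
  prot <- protocol_spec(max_extension = 150, force_noise_sd = 0,
                        sampling_rate = 5000, seed = 1)
  tr <- simulate_trace(sys, prot)
  expect_equal(nrow(tr$events), 0)
  expect_identical(tr$history, "none")
  expect_true(all(diff(tr$curve$force) >= -1e-9))
  # the grid ends within one time step of the target separation
  expect_lt(abs(max(tr$curve$time) * prot$pulling_speed - 150),
            prot$pulling_speed * prot$time_step + 1e-9)
})

test_that("identical seeds give identical curves and event logs", {
  sys <- default_system()
  tr1 <- simulate_trace(sys, protocol_spec(seed = 11))
  tr2 <- simulate_trace(sys, protocol_spec(seed = 11))
  expect_identical(tr1$curve$force, tr2$curve$force)
  expect_identical(tr1$events, tr2$events)
  ds1 <- simulate_dataset(sys, protocol_spec(seed = 5, sampling_rate = 4000),
                          5)
  ds2 <- simulate_dataset(sys, protocol_spec(seed = 5, sampling_rate = 4000),
                          5)
  expect_identical(ds1$ground_truth, ds2$ground_truth)
})

test_that("the event log matches the recorded curve", {
  tr <- simulate_trace(default_system(), protocol_spec(seed = 23))
  ev <- tr$events
  expect_gt(nrow(ev), 0)
  expect_true(all(diff(ev$time) > 0))
  expect_identical(ev$kind[nrow(ev)], "complex_rupture")
  expect_equal(sum(ev$kind == "complex_rupture"), 1)
  # event force equals the curve force at the event index (pre-drop)
  expect_identical(ev$force, tr$curve$force[ev$index])
  expect_true(all(ev$loading_rate > 0))
  # force drops across each event index
  drops <- tr$curve$force[ev$index + 1] - tr$curve$force[ev$index]
  drops <- drops[!is.na(drops)]
  expect_true(all(drops < -20))
})

test_that("the trace satisfies the series force balance", {
  sys <- default_system()
  prot <- protocol_spec(seed = 31, force_noise_sd = 0)
  tr <- simulate_trace(sys, prot)
  cv <- tr$curve
  # reconstruct the unfolded contour and rigid spacer at each sample
  l_prot <- rep(0, length(cv$time))
  rigid0 <- sum(vapply(sys$domains, function(d) d$folded_length, numeric(1)))
  rigid <- rep(rigid0, length(cv$time))
  for (i in seq_len(nrow(tr$events))) {
    e <- tr$events[i, ]
    if (!startsWith(e$kind, "domain_unfold:")) next
    nm <- sub("domain_unfold:", "", e$kind)
    d <- Filter(function(x) x$name == nm, sys$domains)[[1]]
    after <- seq_along(cv$time) > e$index
    l_prot[after] <- l_prot[after] + d$delta_Lc + d$folded_length
    rigid[after] <- rigid[after] - d$folded_length
  }
  pick <- seq(50, length(cv$time) - 10, by = 200)
  pick <- pick[cv$force[pick] > 20]
  x_model <- vapply(pick, function(i) {
    forcespec:::model_extension(cv$force[i], 1, sys$polymer) * l_prot[i] +
      sys$peg_contour * sys$n_linkers *
        forcespec:::wlc_extension_ratio(cv$force[i], sys$peg_persistence,
                                        sys$polymer$kBT) +
      rigid[i]
  }, numeric(1))
  expect_lt(max(abs(x_model - cv$extension[pick])), 0.05)
  # cantilever deflection accounts for the remaining separation
  z <- cv$time * prot$pulling_speed
  expect_equal(cv$extension, z - cv$force / sys$cantilever_stiffness,
               tolerance = 1e-9)
})

test_that("dataset generation counts, junk mixing, and container round trip", {
  ds <- simulate_dataset(default_system(),
                         protocol_spec(seed = 2, sampling_rate = 4000), 10)
  expect_length(ds$curves, 10)
  expect_setequal(unique(ds$ground_truth$trace_id),
                  vapply(ds$curves, function(cv) cv$curve_id, ""))
  dir <- tempfile()
  write_curve_dataset(ds, dir)
  back <- read_curves(dir)
  expect_length(back, 10)
  expect_equal(back[[1]]$force, ds$curves[[1]]$force, tolerance = 1e-6)
  expect_equal(back[[7]]$extension, ds$curves[[7]]$extension,
               tolerance = 1e-6)
  expect_identical(back[[3]]$configuration, "I")
  unlink(dir, recursive = TRUE)
})

test_that("the shielded branch frequency follows the programmed probability", {
  prot <- protocol_spec(seed = 77, sampling_rate = 2000, force_noise_sd = 0)
  ds <- simulate_dataset(default_system(), prot, 600)
  per_trace <- ds$ground_truth[!duplicated(ds$ground_truth$trace_id), ]
  frac <- mean(per_trace$history == "shielded")
  expect_lt(abs(frac - 0.375), 0.05)
  # shielded traces carry an X-module unfolding before rupture
  sh <- ds$ground_truth[ds$ground_truth$history == "shielded", ]
  xm <- tapply(sh$kind, sh$trace_id,
               function(k) any(k == "domain_unfold:XMod") &&
                 k[length(k)] == "complex_rupture")
  expect_true(all(xm))
})

test_that("single-bond KMC rupture forces match the analytic distribution", {
  p <- intact_params()
  sys <- single_bond_system(p)
  prot <- protocol_spec(pulling_speed = 200, sampling_rate = 50000,
                        force_noise_sd = 0, max_extension = 200,
                        post_rupture_time = 0, seed = 13)
  ds <- simulate_dataset(sys, prot, 2000)
  rf <- ds$ground_truth$force[ds$ground_truth$kind == "complex_rupture"]
  expect_length(rf, 2000)
  r <- sys$cantilever_stiffness * prot$pulling_speed
  ks <- suppressWarnings(
    stats::ks.test(rf, function(q) rupture_force_cdf(q, r, p)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("simulated modal rupture force agrees with the Bell-Evans prediction", {
  prot <- protocol_spec(seed = 19, sampling_rate = 10000)
  ds <- simulate_dataset(default_system(shield_branch_probability = 0),
                         prot, 400)
  gt <- ds$ground_truth[ds$ground_truth$kind == "complex_rupture", ]
  g <- fit_gaussian_mode(gt$force)
  r_star <- 10^fit_gaussian_mode(log10(gt$loading_rate))$mode
  pred <- most_probable_force(r_star, intact_params())
  expect_lt(abs(g$mode - pred) / pred, 0.05)
})
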