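# build a synthetic sawtooth curve with known peak positions
make_sawtooth <- function(n_teeth = 3, peak = 150, drop = 100, n = 200,
                          noise = 0, seed = 1) {
  set.seed(seed)
  f <- numeric(0)
  for (k in seq_len(n_teeth)) {
    f <- c(f, seq(peak - drop, peak, length.out = n))
  }
  f <- c(f, seq(peak - drop, 40, length.out = n)) + rnorm(length(f) + n, 0,
                                                          noise)
  t <- seq_along(f) * 1e-4
  force_curve(t, extension = t * 1000, force = f)
}

test_that("sawtooth events are detected and pure noise is not", {
  cv <- make_sawtooth(noise = 2)
  ev <- detect_unfolding_events(cv, min_drop = 50)
  expect_equal(nrow(ev), 3)
  expect_true(ev$is_final[3])
  expect_true(all(abs(ev$force - 150) < 10))
  set.seed(4)
  null <- force_curve(seq(1e-4, 0.1, 1e-4), seq(0.1, 100, length.out = 1000),
                      rnorm(1000, 30, 5))
  expect_equal(nrow(detect_unfolding_events(null, min_drop = 50)), 0)
})

test_that("detected events match the simulator ground truth", {
  ds <- fixture_dataset(200)
  gt <- ds$ground_truth
  hits <- 0; total <- 0
  for (cv in ds$curves) {
    ev <- detect_unfolding_events(cv)
    g <- gt[gt$trace_id == cv$curve_id & gt$kind != "none", ]
    total <- total + nrow(g)
    if (!nrow(ev)) next
    hits <- hits + sum(vapply(g$index,
                              function(i) any(abs(ev$index - i) <= 2),
                              logical(1)))
  }
  expect_gte(hits / total, 0.98)
})

test_that("loading-rate extraction recovers exact and simulated slopes", {
  t <- seq(0, 0.2, by = 1e-3)
  cv <- force_curve(t, t * 1000, 1000 * t)
  expect_equal(extract_loading_rate(cv, length(t)), 1000, tolerance = 1e-9)
  expect_error(extract_loading_rate(cv, 4), "5 samples")
  ds <- fixture_dataset(200)
  gt <- ds$ground_truth
  rel <- c()
  for (cv in ds$curves) {
    ev <- detect_unfolding_events(cv)
    fin <- which(ev$is_final)
    g <- gt[gt$trace_id == cv$curve_id & gt$kind == "complex_rupture", ]
    if (!length(fin) || !nrow(g)) next
    if (abs(ev$index[fin] - g$index[1]) > 2) next
    prev <- if (fin > 1) ev$index[fin - 1] + 1 else 1
    lr <- tryCatch(extract_loading_rate(cv, ev$index[fin],
                                        prev_index = prev),
                   error = function(e) NA)
    rel <- c(rel, abs(lr / g$loading_rate[1] - 1))
  }
  expect_lt(median(rel, na.rm = TRUE), 0.10)
})

test_that("contour-length transform inverts model-generated curves", {
  pp <- polymer_params()
  # noiseless single-state chain at L0 = 120 nm
  f <- seq(95, 155, length.out = 500)
  x <- forcespec:::model_extension(f, 120, pp)
  cv <- force_curve(seq_along(f) * 1e-4, x, f)
  h <- transform_to_contour_length(cv, pp)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  expect_lt(abs(mids[which.max(h$counts)] - 120), 1)
  expect_equal(sum(h$counts), 500)
  # two-state curve: increment 89 nm appears as the peak separation
  f2 <- c(f, f)
  x2 <- c(x, forcespec:::model_extension(f, 209, pp))
  cv2 <- force_curve(seq_along(f2) * 1e-4, x2, f2)
  h2 <- transform_to_contour_length(cv2, pp)
  mi <- measure_increments(h2, min_distance = 20, smooth = 1)
  expect_equal(length(mi$peaks), 2)
  expect_lt(abs(mi$increments - 89), 2)
  # all samples below the threshold: empty histogram with a warning
  low <- force_curve(c(1, 2, 3), c(1, 2, 3), c(10, 12, 14))
  expect_warning(h0 <- transform_to_contour_length(low, pp), "no samples")
  expect_equal(sum(h0$counts), 0)
})

test_that("master histogram assembly aligns shifted copies", {
  pp <- polymer_params()
  ds <- fixture_dataset(200)
  h1 <- transform_to_contour_length(ds$curves[[1]], pp)
  single <- assemble_master_histogram(list(h1))
  expect_identical(single$counts, h1$counts)
  expect_identical(attr(single, "offsets"), 0)
  # the same histogram pre-shifted by +5 nm is pulled back
  h_shift <- contour_hist(h1$bin_edges + 5, h1$counts, source_ids = "s")
  two <- assemble_master_histogram(list(h1, h_shift))
  expect_equal(attr(two, "offsets")[2], -5)
  expect_equal(max(two$counts), 2 * max(h1$counts))
  # incompatible binning is an error
  bad <- contour_hist(seq(0, 10, by = 2), rep(1, 5))
  expect_error(assemble_master_histogram(list(h1, bad)), "bin widths")
})

test_that("master histogram assembly is insensitive to curve order", {
  pp <- polymer_params()
  ds <- fixture_dataset(200)
  hs <- lapply(ds$curves[1:60], transform_to_contour_length, params = pp)
  m1 <- assemble_master_histogram(hs)
  set.seed(8)
  m2 <- assemble_master_histogram(sample(hs))
  p1 <- measure_increments(m1)$peaks
  p2 <- measure_increments(m2)$peaks
  expect_equal(length(p1), length(p2))
  expect_lt(max(abs(p1 - p2)), 1 + 1e-9)
})

test_that("increment measurement reads peak-to-peak distances", {
  counts <- rep(0, 120)
  counts[11] <- 40; counts[100] <- 60   # bins centered at 10.5 and 99.5
  counts <- counts + rep(c(1, 0), 60)
  h <- contour_hist(0:120, counts)
  mi <- measure_increments(h, smooth = 1, prominence = 10)
  expect_equal(mi$increments, 89)
  single <- contour_hist(0:120, c(rep(0, 50), 30, rep(0, 69)))
  expect_warning(mi1 <- measure_increments(single, smooth = 1), "fewer")
  expect_length(mi1$increments, 0)
  expect_error(measure_increments(contour_hist(0:3, rep(0, 3))), "empty")
})

test_that("fingerprint classification follows the template rules", {
  cls <- classify_fingerprint(c(90, 55))
  expect_identical(cls$label, "specific")
  expect_identical(cls$history, "intact")
  cls2 <- classify_fingerprint(c(90, 55, 34))
  expect_identical(cls2$label, "specific")
  expect_identical(cls2$history, "shielded")
  expect_identical(classify_fingerprint(numeric(0))$label, "unclassified")
  expect_identical(classify_fingerprint(numeric(0))$history, "unassigned")
  # the three-peaked xylanase matches through consecutive sub-increments
  cls3 <- classify_fingerprint(c(30, 30, 29, 56))
  expect_identical(cls3$label, "specific")
  m <- cls3$matches
  expect_equal(m$measured[m$name == "Xyn"], 89)
  expect_equal(m$from[m$name == "Xyn"], 1)
  expect_equal(m$to[m$name == "Xyn"], 3)
  # single-step templates may not swallow several increments
  cls4 <- classify_fingerprint(c(30, 26, 90))
  m4 <- cls4$matches
  expect_true(is.na(m4$measured[m4$name == "CBM"]))
})

test_that("simulated shielded traces are tagged shielded from their increments", {
  ds <- fixture_dataset(200)
  gt <- ds$ground_truth
  sh_ids <- unique(gt$trace_id[gt$history == "shielded"])
  tagged <- vapply(sh_ids, function(id) {
    cv <- ds$curves[[match(id, vapply(ds$curves, function(c) c$curve_id,
                                      ""))]]
    ev <- detect_unfolding_events(cv)
    inc <- measure_curve_increments(cv, ev)
    classify_fingerprint(inc)$history == "shielded"
  }, logical(1))
  expect_gte(mean(tagged), 0.95)
})

test_that("junk traces are rarely classified as specific", {
  prot <- protocol_spec(seed = 55, sampling_rate = 2000)
  ds <- simulate_dataset(default_system(), prot, 60, junk_fraction = 0.999)
  labels <- vapply(ds$curves, function(cv) {
    ev <- detect_unfolding_events(cv)
    inc <- measure_curve_increments(cv, ev)
    classify_fingerprint(inc)$label
  }, "")
  expect_lt(mean(labels == "specific"), 0.05)
})
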