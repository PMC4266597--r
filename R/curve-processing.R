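#' A constant-speed force-extension trace
#'
#' @param time time, s, strictly increasing.
#' @param extension tip-surface separation (deflection-corrected), nm.
#' @param force force, pN.
#' @param pulling_speed nm/s.
#' @param curve_id identifier.
#' @param configuration pulling configuration: `"I"`, `"II"`, or
#'   `"unknown"`.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(time, extension, force, pulling_speed = NA_real_,
                        curve_id = "curve",
                        configuration = c("I", "II", "unknown")) {
  configuration <- match.arg(configuration)
  n <- length(time)
  if (n < 2 || length(extension) != n || length(force) != n) {
    stop("force_curve(): arrays must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("force_curve(): time must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, extension = extension, force = force,
                 pulling_speed = pulling_speed, curve_id = curve_id,
                 configuration = configuration),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force curve '%s' (config %s): %d samples, %.3g s, peak force %.0f pN\n",
    x$curve_id, x$configuration, length(x$time), max(x$time),
    max(x$force)))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, ...) {
  graphics::plot(x$extension, x$force, type = "l",
                 xlab = "extension (nm)", ylab = "force (pN)",
                 main = x$curve_id, ...)
  invisible(x)
}

#' Detect unfolding/rupture events in a sawtooth trace
#'
#' Finds local force maxima that are followed by a drop of at least
#' `min_drop` pN within `min_separation` nm of extension and whose peak
#' force is at least `min_force` pN. Peaks closer than `min_separation`
#' (in extension) to a stronger accepted peak are suppressed. The last
#' event is flagged as the final rupture.
#'
#' @param curve a [force_curve()].
#' @param min_drop minimum force drop after the peak, pN. Default 30.
#' @param min_force minimum peak force, pN. Default 50 (events below this
#'   are in the PEG/noise region).
#' @param min_separation drop search window and suppression radius, nm.
#'   Default 5.
#' @param smooth odd running-median window for detection (peaks are
#'   re-localized on the raw trace). Default 5.
#' @return `data.frame` with columns `index`, `time`, `force`,
#'   `loading_rate` (`NA` until assigned), `is_final`; zero rows when no
#'   event qualifies.
#' @export
detect_unfolding_events <- function(curve, min_drop = 30, min_force = 50,
                                    min_separation = 5, smooth = 5) {
  f <- curve$force
  n <- length(f)
  fs <- if (smooth > 1 && n > smooth) as.numeric(stats::runmed(f, smooth)) else f
  # zero = "+" so that plateaus introduced by the running median still
  # terminate in a detectable peak
  pk <- pracma::findpeaks(fs, minpeakheight = min_force, zero = "+")
  if (is.null(pk)) {
    return(empty_events())
  }
  idx <- pk[, 2]
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    jmax <- i
    while (jmax < n &&
           curve$extension[jmax] - curve$extension[i] < min_separation) {
      jmax <- jmax + 1
    }
    if (jmax > i && fs[i] - min(fs[(i + 1):jmax]) >= min_drop) {
      keep[k] <- TRUE
    }
  }
  idx <- idx[keep]
  if (!length(idx)) return(empty_events())
  # non-maximum suppression within min_separation of extension
  ord <- order(fs[idx], decreasing = TRUE)
  accepted <- integer(0)
  for (i in idx[ord]) {
    if (!any(abs(curve$extension[accepted] - curve$extension[i]) <
             min_separation)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  # re-localize on the raw trace: the unfolding force drop is far sharper
  # than the noise, so the event index is the sample preceding the
  # steepest raw drop near the smoothed peak
  accepted <- vapply(accepted, function(i) {
    jmax <- i
    while (jmax < n &&
           curve$extension[jmax] - curve$extension[i] < min_separation) {
      jmax <- jmax + 1
    }
    w <- max(1, i - 3):max(min(n - 1, jmax - 1), max(1, i - 3))
    w[which.min(f[w + 1] - f[w])]
  }, integer(1))
  accepted <- sort(unique(accepted))
  ev <- data.frame(index = accepted,
                   time = curve$time[accepted],
                   force = f[accepted],
                   loading_rate = NA_real_,
                   is_final = FALSE)
  ev$is_final[nrow(ev)] <- TRUE
  ev
}

empty_events <- function() {
  data.frame(index = integer(0), time = numeric(0), force = numeric(0),
             loading_rate = numeric(0), is_final = logical(0))
}

#' Loading rate at a rupture peak
#'
#' Slope of a least-squares line fitted to force vs time over the window
#' immediately preceding the peak: by default the samples spanning the
#' final `window_fraction` of the force rise from the preceding valley to
#' the peak.
#'
#' @param curve a [force_curve()].
#' @param peak_index sample index of the peak.
#' @param window_fraction fraction of the force rise used. Default 0.2
#'   (larger windows increasingly under-estimate the tangent slope at the
#'   peak because the loading rate grows along the rise).
#' @param prev_index search floor for the preceding valley (e.g. the index
#'   of the previous event). Default 1.
#' @return loading rate, pN/s.
#' @export
extract_loading_rate <- function(curve, peak_index, window_fraction = 0.2,
                                 prev_index = 1) {
  stopifnot(peak_index >= 1, peak_index <= length(curve$force),
            window_fraction > 0, window_fraction <= 1)
  f <- curve$force
  lo <- max(1, prev_index)
  if (peak_index - lo < 5) {
    stop("extract_loading_rate(): fewer than 5 samples before peak",
         call. = FALSE)
  }
  seg <- lo:peak_index
  valley <- seg[which.min(stats::runmed(f[seg], min(5, length(seg) -
                                                      (length(seg) + 1) %% 2)))]
  fp <- f[peak_index]
  rise <- fp - f[valley]
  thr <- fp - window_fraction * rise
  w <- which(f >= thr & seq_along(f) >= valley & seq_along(f) <= peak_index)
  w <- w[w >= valley]
  if (length(w) < 5) w <- max(valley, peak_index - 4):peak_index
  if (length(w) < 5) {
    stop("extract_loading_rate(): fewer than 5 samples in window",
         call. = FALSE)
  }
  t <- curve$time[w]
  if (stats::var(t) == 0) {
    stop("extract_loading_rate(): degenerate time window", call. = FALSE)
  }
  unname(stats::coef(stats::lm(f[w] ~ t))[2])
}

#' Contour-length histogram container
#'
#' @param bin_edges strictly increasing, uniform-width bin edges, nm.
#' @param counts per-bin counts (length `length(bin_edges) - 1`).
#' @param offset alignment shift applied, nm.
#' @param source_ids contributing curve ids.
#' @return object of class `contour_hist`.
#' @export
contour_hist <- function(bin_edges, counts, offset = 0,
                         source_ids = character(0)) {
  stopifnot(length(bin_edges) == length(counts) + 1)
  w <- diff(bin_edges)
  if (length(w) && (any(w <= 0) || diff(range(w)) > 1e-8 * w[1])) {
    stop("contour_hist(): bin edges must be uniform and increasing",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("contour_hist(): negative counts",
                            call. = FALSE)
  structure(list(bin_edges = bin_edges, counts = counts, offset = offset,
                 source_ids = source_ids),
            class = "contour_hist")
}

#' @export
print.contour_hist <- function(x, ...) {
  cat(sprintf(
    "Contour-length histogram: %d bins of %.3g nm, %d counts, %d curve(s)\n",
    length(x$counts), if (length(x$counts)) diff(x$bin_edges[1:2]) else NA,
    sum(x$counts), max(1L, length(x$source_ids))))
  invisible(x)
}

#' @export
plot.contour_hist <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mids, x$counts, type = "h",
                 xlab = "contour length (nm)", ylab = "counts", ...)
  invisible(x)
}

#' Transform a force curve into contour-length space
#'
#' Maps every sample with force above the threshold (and non-negative
#' extension, excluding the cantilever-contact region) to its apparent
#' contour length under the QM-FRC model and bins the result.
#'
#' @param curve a [force_curve()].
#' @param params a [polymer_params()] (QM-FRC).
#' @param force_threshold transformation threshold, pN. Default 90: below
#'   this the trace is dominated by PEG elasticity and noise.
#' @param force_max upper force limit, pN. Default 160. Restricting all
#'   segments to a common force window -- spanning the force range that
#'   every inter-event segment traverses, just below the fingerprint
#'   unfolding forces -- makes the untransformed PEG-linker and
#'   folded-domain contribution to the apparent contour length the same
#'   for every segment, so that peak-to-peak spacings are unbiased
#'   estimates of the unfolding increments; segments sampled over
#'   disparate force ranges otherwise shift against each other by several
#'   nm. Set to `Inf` to transform broadly.
#' @param bin_width histogram bin width, nm. Default 1.
#' @return a [contour_hist()] (empty, with a warning, when no sample
#'   qualifies).
#' @export
transform_to_contour_length <- function(curve, params = polymer_params(),
                                        force_threshold = 90,
                                        force_max = 160,
                                        bin_width = 1) {
  ok <- curve$force > force_threshold & curve$force <= force_max &
    curve$extension >= 0
  l <- apparent_contour_length(curve$force[ok], curve$extension[ok],
                               params, force_threshold)
  l <- l[is.finite(l)]
  if (!length(l)) {
    warning(sprintf("curve '%s': no samples above %g pN", curve$curve_id,
                    force_threshold), call. = FALSE)
    return(contour_hist(c(0, bin_width), 0L, source_ids = curve$curve_id))
  }
  edges <- seq(0, (floor(max(l) / bin_width) + 1) * bin_width,
               by = bin_width)
  counts <- graphics::hist(l, breaks = edges, plot = FALSE)$counts
  contour_hist(edges, counts, source_ids = curve$curve_id)
}

# place a contour_hist onto a global bin grid given common width
embed_counts <- function(h, edges) {
  counts <- numeric(length(edges) - 1)
  if (!length(h$counts)) return(counts)
  w <- diff(edges[1:2])
  k <- round((h$bin_edges[1] - edges[1]) / w)
  counts[seq_along(h$counts) + k] <- h$counts
  counts
}

#' Assemble a master barrier-position histogram by cross-correlation
#'
#' Iteratively aligns per-curve contour-length histograms to the running
#' master: each histogram is shifted by the integer-bin offset (within
#' `+/- max_shift` nm) that maximizes the cross-correlation of the counts
#' with the master, then summed in. Offsets compensate the tether-length
#' variability between curves.
#'
#' @param histograms list of [contour_hist()] with a common bin width.
#' @param max_shift alignment search radius, nm. Default 10.
#' @return a [contour_hist()] with the summed counts; per-histogram offsets
#'   in attribute `offsets`.
#' @export
assemble_master_histogram <- function(histograms, max_shift = 10) {
  stopifnot(length(histograms) >= 1)
  if (length(histograms) == 1) {
    out <- histograms[[1]]
    attr(out, "offsets") <- 0
    return(out)
  }
  ws <- vapply(histograms, function(h) diff(h$bin_edges[1:2]), numeric(1))
  if (diff(range(ws)) > 1e-8) {
    stop("assemble_master_histogram(): incompatible bin widths",
         call. = FALSE)
  }
  w <- ws[1]
  lo <- min(vapply(histograms, function(h) h$bin_edges[1], numeric(1)))
  hi <- max(vapply(histograms, function(h) max(h$bin_edges), numeric(1)))
  pad <- ceiling(max_shift / w) * w
  edges <- seq(lo - pad, hi + pad, by = w)
  master <- embed_counts(histograms[[1]], edges)
  offsets <- numeric(length(histograms))
  s_max <- round(max_shift / w)
  if (length(histograms) > 1) {
    for (i in 2:length(histograms)) {
      h <- embed_counts(histograms[[i]], edges)
      best <- 0; best_score <- -Inf
      for (s in -s_max:s_max) {
        hs <- shift_vec(h, s)
        score <- sum(master * hs)
        if (score > best_score) { best_score <- score; best <- s }
      }
      offsets[i] <- best * w
      master <- master + shift_vec(h, best)
    }
  }
  out <- contour_hist(edges, master,
                      source_ids = unlist(lapply(histograms,
                                                 function(h) h$source_ids)))
  attr(out, "offsets") <- offsets
  out
}

shift_vec <- function(x, s) {
  n <- length(x)
  out <- numeric(n)
  if (s >= 0) out[(1 + s):n] <- x[1:(n - s)] else
    out[1:(n + s)] <- x[(1 - s):n]
  out
}

# prominence of each local maximum (classic definition: height above the
# highest saddle separating it from higher terrain)
peak_prominence <- function(counts, idx) {
  n <- length(counts)
  vapply(idx, function(i) {
    h <- counts[i]
    scan <- function(js) {
      lowest <- h
      for (j in js) {
        if (counts[j] > h) return(lowest)   # reached higher terrain
        if (counts[j] < lowest) lowest <- counts[j]
      }
      lowest                                # edge reached: min to the edge
    }
    lb <- if (i > 1) scan((i - 1):1) else h
    rb <- if (i < n) scan((i + 1):n) else h
    h - max(lb, rb)
  }, numeric(1))
}

#' Measure contour-length increments from a master histogram
#'
#' Detects peaks (barrier positions) by prominence and returns successive
#' peak-to-peak spacings, the raw contour-length increments of the
#' unfolding pathway.
#'
#' @param master a [contour_hist()].
#' @param prominence minimum peak prominence in counts; default 5% of the
#'   maximum bin count.
#' @param min_distance minimum peak spacing, nm. Default 10.
#' @param smooth odd running-median window (bins) applied before peak
#'   detection. Default 3.
#' @return list with `peaks` (bin-center positions, nm) and `increments`
#'   (successive differences, nm; empty with a warning when fewer than two
#'   peaks are found).
#' @export
measure_increments <- function(master, prominence = NULL,
                               min_distance = 10, smooth = 3) {
  counts <- master$counts
  if (!length(counts) || sum(counts) == 0) {
    stop("measure_increments(): empty histogram", call. = FALSE)
  }
  w <- diff(master$bin_edges[1:2])
  cs <- if (smooth > 1 && length(counts) > smooth) {
    as.numeric(stats::runmed(counts, smooth))
  } else counts
  if (is.null(prominence)) prominence <- 0.05 * max(cs)
  pk <- pracma::findpeaks(cs, zero = "+",
                          minpeakdistance = max(1, round(min_distance / w)))
  if (is.null(pk)) pk <- matrix(numeric(0), ncol = 4)
  idx <- pk[, 2]
  if (length(idx)) {
    prom <- peak_prominence(cs, idx)
    idx <- sort(idx[prom >= prominence])
  }
  mids <- (master$bin_edges[-1] +
             master$bin_edges[-length(master$bin_edges)]) / 2
  peaks <- mids[idx]
  if (length(peaks) < 2) {
    warning("fewer than two peaks: no increments measurable", call. = FALSE)
    return(list(peaks = peaks, increments = numeric(0)))
  }
  list(peaks = peaks, increments = diff(peaks))
}

#' Per-curve increments from detected events
#'
#' Apparent contour length is piecewise constant between unfolding events;
#' this measures the per-segment level (median apparent contour length of
#' the samples above the force threshold) and returns the level steps
#' between successive segments, i.e. the per-curve contour-length
#' increments.
#'
#' @param curve a [force_curve()].
#' @param events event table from [detect_unfolding_events()].
#' @param params a [polymer_params()].
#' @param force_threshold pN. Default 90.
#' @param force_max common upper force window, pN (see
#'   [transform_to_contour_length()]). Default 160.
#' @param fallback_floor,fallback_max widened force window, pN, used for a
#'   segment with too few samples inside the common window (e.g. a segment
#'   ending in an unfolding event below the common window at slow pulling
#'   speed, or the short segment between X-module unfolding and the
#'   immediately following rupture). The wider window costs a few nm of
#'   accuracy, acceptable at the classification tolerance. Defaults 30
#'   and 500.
#' @return numeric vector of increments (length `nrow(events) - 1` at
#'   most; segments with no usable samples are dropped).
#' @export
measure_curve_increments <- function(curve, events,
                                     params = polymer_params(),
                                     force_threshold = 90,
                                     force_max = 160,
                                     fallback_floor = 30,
                                     fallback_max = 500) {
  if (nrow(events) < 2) return(numeric(0))
  bounds <- c(0, events$index)
  levels <- rep(NA_real_, length(bounds) - 1)
  for (s in seq_len(length(bounds) - 1)) {
    i <- (bounds[s] + 1):bounds[s + 1]
    ok <- curve$force[i] > force_threshold & curve$force[i] <= force_max &
      curve$extension[i] >= 0
    floor_used <- force_threshold
    if (sum(ok) < 3) {
      ok <- curve$force[i] > fallback_floor &
        curve$force[i] <= fallback_max & curve$extension[i] >= 0
      floor_used <- fallback_floor
    }
    if (sum(ok) >= 2) {
      l <- apparent_contour_length(curve$force[i][ok],
                                   curve$extension[i][ok],
                                   params, floor_used)
      levels[s] <- stats::median(l, na.rm = TRUE)
    }
  }
  diff(levels[!is.na(levels)])
}

#' Match measured increments to fingerprint templates
#'
#' Matches template increments to the measured increments in construct
#' order: templates are taken in the order they appear in the table (the
#' order the domains unfold along the pathway), and each is matched to the
#' earliest contiguous run of unmatched increments whose sum lies within
#' the tolerance -- multi-step fingerprints (like the three-peaked
#' xylanase) spread their total increment over up to `steps` consecutive
#' sub-increments; single-step domains match one increment only. Among
#' runs starting at the same position the closest sum wins.
#'
#' @param increments measured increments, nm (ordered along the pathway).
#' @param templates an [increment_table()].
#' @param tolerance matching tolerance, nm. Default 8.
#' @return `data.frame`: `name`, `expected`, `measured` (`NA` when
#'   unmatched), `from`, `to` (increment run indices).
#' @export
match_increments <- function(increments, templates = increment_table(),
                             tolerance = 8) {
  stopifnot(tolerance > 0)
  tab <- templates$entries
  used <- rep(FALSE, length(increments))
  out <- data.frame(name = tab$name, expected = tab$increment,
                    measured = NA_real_, from = NA_integer_,
                    to = NA_integer_)
  steps <- if (is.null(tab$steps)) rep(1L, nrow(tab)) else tab$steps
  for (k in seq_len(nrow(tab))) {
    target <- tab$increment[k]
    best <- NULL
    n <- length(increments)
    for (i in seq_len(n)) {
      if (used[i]) next
      s <- 0
      best_err <- tolerance
      for (j in i:min(n, i + steps[k] - 1)) {
        if (used[j]) break
        s <- s + increments[j]
        if (s > target + tolerance) break
        err <- abs(s - target)
        if (err < best_err - 1e-12) {
          best_err <- err
          best <- c(i, j, s)
        }
      }
      if (!is.null(best)) break   # earliest feasible start wins
    }
    if (!is.null(best)) {
      out$measured[k] <- best[3]
      out$from[k] <- best[1]
      out$to[k] <- best[2]
      used[best[1]:best[2]] <- TRUE
    }
  }
  out
}

#' Classify a curve's unfolding fingerprint and bond history
#'
#' A curve is `"specific"` when all required fingerprint templates match
#' its measured increments (configuration I requires Xyn and CBM);
#' otherwise `"unclassified"`. The bond history of the final rupture is
#' `"shielded"` when the X-module template matched (its unfolding preceded
#' the final rupture), `"intact"` for a specific curve without it, and
#' `"unassigned"` otherwise.
#'
#' @param increments measured increments, nm.
#' @param templates an [increment_table()].
#' @param tolerance matching tolerance, nm. Default 8.
#' @param required template names that must match for specificity.
#' @param xmod_name name of the shielding domain template.
#' @return list with `label`, `history`, and the `matches` table.
#' @examples
#' classify_fingerprint(c(90, 55))   # specific, intact
#' @export
classify_fingerprint <- function(increments,
                                 templates = increment_table(),
                                 tolerance = 8,
                                 required = c("Xyn", "CBM"),
                                 xmod_name = "XMod") {
  m <- match_increments(increments, templates, tolerance)
  specific <- all(required %in% m$name[!is.na(m$measured)])
  label <- if (specific) "specific" else "unclassified"
  history <- if (!specific) "unassigned" else
    if (xmod_name %in% m$name[!is.na(m$measured)]) "shielded" else "intact"
  list(label = label, history = history, matches = m)
}

#' Domain-level increments from a master histogram
#'
#' Combines [measure_increments()] and [match_increments()]: measures the
#' peak-to-peak spacings of the master histogram and reports, per
#' fingerprint template, the matched (possibly multi-step) increment.
#'
#' @inheritParams measure_increments
#' @param templates an [increment_table()].
#' @param tolerance matching tolerance, nm.
#' @return the [match_increments()] table with an attribute `peaks`.
#' @export
domain_increments <- function(master, templates = increment_table(),
                              tolerance = 8, prominence = NULL,
                              min_distance = 10) {
  mi <- measure_increments(master, prominence = prominence,
                           min_distance = min_distance)
  out <- match_increments(mi$increments, templates, tolerance)
  attr(out, "peaks") <- mi$peaks
  out
}
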