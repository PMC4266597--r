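#' Mechanical specification of one unfoldable domain
#'
#' @param name domain name (sub-steps of a multi-step fingerprint can share
#'   a stem, e.g. `"Xyn_1"`).
#' @param delta_Lc contour-length increment released on unfolding, nm, `> 0`.
#' @param folded_length folded N-C distance, nm (carried as a rigid spacer
#'   while folded).
#' @param kinetics a [bell_params()] for the unfolding transition, or `NULL`
#'   for a domain that never unfolds.
#' @param refoldable whether the domain refolds between traces (dataset
#'   level; refolding never occurs within a single trace at these speeds).
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(name, delta_Lc, folded_length = 0,
                        kinetics = NULL, refoldable = TRUE) {
  stopifnot(delta_Lc > 0, folded_length >= 0)
  if (!is.null(kinetics)) stopifnot(inherits(kinetics, "bell_params"))
  structure(list(name = name, delta_Lc = delta_Lc,
                 folded_length = folded_length, kinetics = kinetics,
                 refoldable = refoldable),
            class = "domain_spec")
}

#' Mechanical ground truth of the simulated pulling configuration
#'
#' Describes the series mechanical circuit of a constant-speed AFM pulling
#' experiment: cantilever spring, PEG linkers (WLC), the polyprotein with
#' its unfoldable fingerprint domains (unfolded polypeptide follows the
#' QM-FRC), and the terminal receptor-ligand complex with two rupture
#' kinetics: `complex_intact` while the shielding X-module is folded and
#' `complex_shielded` after it unfolds.
#'
#' Whether a trace takes the X-module-unfolding ("shielded") path is
#' governed by an explicit `shield_branch_probability` by default; set
#' `emergent_competition = TRUE` to let X-module unfolding compete with
#' intact rupture through their Bell rates instead.
#'
#' @param domains list of [domain_spec()]s, ordered along the construct.
#' @param complex_intact,complex_shielded [bell_params()] for final rupture
#'   with the X-module folded / unfolded; either may be `NULL` to disable.
#' @param shield_branch_probability probability that a trace follows the
#'   X-module-unfolding branch, in `[0, 1]`.
#' @param xmod_name name of the shielding domain within `domains` (its
#'   unfolding switches the rupture kinetics).
#' @param peg_contour contour length per PEG linker, nm.
#' @param n_linkers number of PEG linkers in series (tip + surface).
#' @param peg_persistence PEG persistence length, nm.
#' @param cantilever_stiffness pN/nm, `> 0`.
#' @param polymer [polymer_params()] for unfolded polypeptide (QM-FRC).
#' @param emergent_competition see above.
#' @return object of class `system_spec`.
#' @seealso [default_system()], [single_bond_system()]
#' @export
system_spec <- function(domains = list(),
                        complex_intact = NULL,
                        complex_shielded = NULL,
                        shield_branch_probability = 0.375,
                        xmod_name = "XMod",
                        peg_contour = 32,
                        n_linkers = 2,
                        peg_persistence = 0.38,
                        cantilever_stiffness = 50,
                        polymer = polymer_params(),
                        emergent_competition = FALSE) {
  stopifnot(shield_branch_probability >= 0, shield_branch_probability <= 1,
            cantilever_stiffness > 0, peg_contour >= 0, n_linkers >= 0,
            peg_persistence > 0)
  stopifnot(all(vapply(domains, inherits, logical(1), "domain_spec")))
  structure(list(
    domains = domains,
    complex_intact = complex_intact,
    complex_shielded = complex_shielded,
    shield_branch_probability = shield_branch_probability,
    xmod_name = xmod_name,
    peg_contour = peg_contour,
    n_linkers = n_linkers,
    peg_persistence = peg_persistence,
    cantilever_stiffness = cantilever_stiffness,
    polymer = polymer,
    emergent_competition = emergent_competition
  ), class = "system_spec")
}

#' Default pulling configuration I system
#'
#' Xyn-XMod-Doc pulled against Coh-CBM: a three-step xylanase fingerprint
#' (sub-increments 30/30/29 nm summing to the ~89 nm Xyn increment), the
#' ~56 nm CBM fingerprint, the shielding X-module (~34 nm), and the
#' ultrastable complex with its two bond-history rupture kinetics
#' (`delta_x` 0.13 nm / `k_off` 7.3e-7 1/s intact; 0.19 nm / 4.7e-4 1/s
#' shielded). X-module unfolding precedes rupture in 37.5% of traces.
#'
#' @param shield_branch_probability see [system_spec()].
#' @param ... further arguments passed to [system_spec()].
#' @return a `system_spec`.
#' @export
default_system <- function(shield_branch_probability = 0.375, ...) {
  xyn_kin <- bell_params(k_off = 1e-3, delta_x = 0.50)
  cbm_kin <- bell_params(k_off = 2e-4, delta_x = 0.40)
  xmod_kin <- bell_params(k_off = 2.6e-6, delta_x = 0.15)
  domains <- list(
    domain_spec("Xyn_1", 30, 1.5, xyn_kin),
    domain_spec("Xyn_2", 30, 1.5, xyn_kin),
    domain_spec("Xyn_3", 29, 1.0, xyn_kin, refoldable = FALSE),
    domain_spec("CBM", 56, 5.0, cbm_kin),
    domain_spec("XMod", 34, 4.5, xmod_kin)
  )
  system_spec(
    domains = domains,
    complex_intact = bell_params(k_off = 7.3e-7, delta_x = 0.13),
    complex_shielded = bell_params(k_off = 4.7e-4, delta_x = 0.19),
    shield_branch_probability = shield_branch_probability,
    ...
  )
}

#' Minimal single-bond system
#'
#' A bare receptor-ligand bond loaded directly through the cantilever (no
#' linkers, no domains), so the force ramp is exactly linear with loading
#' rate `cantilever_stiffness * pulling_speed`. This is the configuration
#' in which the kinetic Monte Carlo core can be compared against the
#' analytic Bell-Evans rupture-force distribution.
#'
#' @param kinetics [bell_params()] of the bond.
#' @param cantilever_stiffness pN/nm.
#' @param ... passed to [system_spec()].
#' @return a `system_spec`.
#' @export
single_bond_system <- function(kinetics, cantilever_stiffness = 50, ...) {
  system_spec(domains = list(), complex_intact = kinetics,
              complex_shielded = NULL, shield_branch_probability = 0,
              peg_contour = 0, n_linkers = 0,
              cantilever_stiffness = cantilever_stiffness, ...)
}

#' Pulling protocol
#'
#' @param pulling_speed constant retraction speed, nm/s, `> 0`.
#' @param sampling_rate samples per second, 1/s.
#' @param force_noise_sd Gaussian noise added to the reported force, pN.
#' @param max_extension stop separation, nm.
#' @param time_step integration step, s; must be `<= 1/sampling_rate`
#'   (default equal to it, so every step is a recorded sample).
#' @param post_rupture_time baseline recorded after the final rupture, s
#'   (the instrument keeps sampling while the cantilever relaxes; this
#'   makes the final force drop visible to event detection). Default 0.01.
#' @param seed integer seed for the trace.
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(pulling_speed = 1600,
                          sampling_rate = 20000,
                          force_noise_sd = 5,
                          max_extension = 350,
                          time_step = 1 / sampling_rate,
                          post_rupture_time = 0.01,
                          seed = NULL) {
  stopifnot(pulling_speed > 0, sampling_rate > 0,
            time_step <= 1 / sampling_rate + 1e-15,
            force_noise_sd >= 0, max_extension > 0)
  stopifnot(post_rupture_time >= 0)
  structure(list(pulling_speed = pulling_speed,
                 sampling_rate = sampling_rate,
                 force_noise_sd = force_noise_sd,
                 max_extension = max_extension,
                 time_step = time_step,
                 post_rupture_time = post_rupture_time,
                 seed = seed),
            class = "protocol_spec")
}

# ---- series force balance -------------------------------------------------

# Interpolators for the polymer extension basis on a log-spaced force grid.
# The series extension at force F with n_prot nm of unfolded polypeptide and
# `rigid` nm of folded spacer is
#   x(F) = F/k_c + L_peg * wlc_r(F) + n_prot * frc_rf(F) + rigid
# where frc_rf includes the QM stretch factor. Built once per system.
chain_basis <- function(system, f_max = 2e4, n_grid = 700) {
  fg <- exp(seq(log(1e-3), log(f_max), length.out = n_grid))
  pol <- system$polymer
  frc <- frc_extension_ratio(fg, pol, warn_below_floor = FALSE) *
    backbone_stretch_factor(fg, pol)
  frc <- pmax(cummax(frc), 0)  # clamp unphysical negative low-force tail
  wlc <- wlc_extension_ratio(fg, system$peg_persistence, pol$kBT)
  list(
    fg = fg,
    frc_fun = stats::splinefun(log(fg), frc, method = "hyman"),
    wlc_fun = stats::splinefun(log(fg), wlc, method = "hyman"),
    f_max = f_max
  )
}

# Solve the force balance F/k_c + x_poly(F) = z for a vector of separations
# z (nm), given current contour state. Vectorized: table inversion followed
# by Newton refinement on the spline representation.
solve_force_balance <- function(z, basis, system, l_prot, rigid,
                                tol = 1e-6) {
  kc <- system$cantilever_stiffness
  l_peg <- system$peg_contour * system$n_linkers
  fg <- basis$fg
  xg <- fg / kc + l_peg * basis$wlc_fun(log(fg)) +
    l_prot * basis$frc_fun(log(fg)) + rigid
  f <- stats::approx(xg, fg, xout = z, rule = 2)$y
  for (iter in 1:6) {
    lf <- log(f)
    x <- f / kc + l_peg * basis$wlc_fun(lf) + l_prot * basis$frc_fun(lf) +
      rigid
    dx <- 1 / kc +
      (l_peg * basis$wlc_fun(lf, deriv = 1) +
         l_prot * basis$frc_fun(lf, deriv = 1)) / f
    step <- (x - z) / dx
    f <- pmin(pmax(f - step, 1e-4), basis$f_max)
    if (max(abs(step)) < tol) break
  }
  slack <- z <= rigid + 1e-9   # chain not yet taut: no solution, force 0
  resid <- f / kc + l_peg * basis$wlc_fun(log(f)) +
    l_prot * basis$frc_fun(log(f)) + rigid - z
  resid[slack] <- 0
  if (max(abs(resid)) > 100 * tol + 1e-3) {
    stop(sprintf(
      "force-balance solver did not converge (max residual %.3g nm at z=%.3g)",
      max(abs(resid)), z[which.max(abs(resid))]), call. = FALSE)
  }
  f[slack] <- 0
  f
}

# ---- kinetic Monte Carlo trace --------------------------------------------

#' Simulate one constant-speed pulling trace
#'
#' Kinetic Monte Carlo simulation of the series circuit
#' cantilever-PEG-polyprotein-complex. At each time step the total
#' tip-surface separation `v t` is partitioned between cantilever
#' deflection `F/k_c` and polymer extension by solving the series force
#' balance; each folded domain unfolds with probability
#' `1 - exp(-k(F) dt)` (trapezoidal step-integrated Bell hazard), growing
#' the unfolded contour by its `delta_Lc` and relaxing the force; the
#' complex ruptures by the same rule under the intact kinetics while the
#' X-module is folded and the shielded kinetics after it unfolds. Gaussian
#' noise is added to the reported force. The trace ends at rupture (or at
#' `max_extension` if rupture is disabled or never fires).
#'
#' @param system a [system_spec()].
#' @param protocol a [protocol_spec()].
#' @param curve_id identifier stored on the returned curve.
#' @return list with `curve` (a [force_curve()]) and `events` (an event log
#'   `data.frame`: `time`, `index`, `force` pN, `kind`
#'   (`"domain_unfold:<name>"` or `"complex_rupture"`), `loading_rate`
#'   pN/s), plus `history` (`"intact"`, `"shielded"`, or `"none"`).
#' @examples
#' tr <- simulate_trace(default_system(), protocol_spec(seed = 1))
#' tr$events
#' @export
simulate_trace <- function(system, protocol, curve_id = "trace") {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  v <- protocol$pulling_speed
  dt <- protocol$time_step
  t_end <- protocol$max_extension / v
  basis <- chain_basis(system)

  # branch decision: does this trace take the shielded path?
  has_xmod <- any(vapply(system$domains, function(d) d$name, "") ==
                    system$xmod_name)
  shielded_branch <- FALSE
  if (!system$emergent_competition && has_xmod &&
      !is.null(system$complex_shielded)) {
    shielded_branch <- stats::runif(1) < system$shield_branch_probability
  }

  folded <- system$domains
  l_prot <- 0
  rigid <- sum(vapply(folded, function(d) d$folded_length, numeric(1)))
  xmod_unfolded <- FALSE

  active_channels <- function() {
    ch <- list()
    for (i in seq_along(folded)) {
      d <- folded[[i]]
      if (is.null(d$kinetics)) next
      if (!system$emergent_competition && d$name == system$xmod_name &&
          !shielded_branch) next   # intact branch: X-module stays folded
      ch[[length(ch) + 1]] <- list(kind = "domain", i = i, kin = d$kinetics)
    }
    rup <- if (xmod_unfolded) system$complex_shielded else
      system$complex_intact
    if (!system$emergent_competition && shielded_branch && !xmod_unfolded) {
      rup <- NULL                  # rupture waits for X-module unfolding
    }
    if (!is.null(rup)) {
      ch[[length(ch) + 1]] <- list(kind = "rupture", i = NA, kin = rup)
    }
    ch
  }

  time <- force <- ext <- numeric(0)
  events <- list()
  t0 <- 0
  ruptured <- FALSE

  while (t0 < t_end - dt / 2 && !ruptured) {
    tj <- seq(t0 + dt, t_end, by = dt)
    if (!length(tj)) break
    zj <- v * tj
    fj <- solve_force_balance(zj, basis, system, l_prot, rigid)
    ch <- active_channels()
    if (length(ch)) {
      kt <- rep(0, length(fj))
      per <- lapply(ch, function(c) bell_rate(pmin(fj, 4000), c$kin,
                                              system$polymer$kBT))
      for (k in per) kt <- kt + k
      # trapezoidal step-integrated hazard
      kprev <- c(kt[1], kt[-length(kt)])
      haz <- cumsum(dt * (kt + kprev) / 2)
      e <- stats::rexp(1)
      j <- match(TRUE, haz >= e)
    } else {
      j <- NA_integer_
    }
    if (is.na(j)) {
      time <- c(time, tj); force <- c(force, fj)
      ext <- c(ext, zj - fj / system$cantilever_stiffness)
      t0 <- t_end
      break
    }
    # record samples up to and including the event step
    time <- c(time, tj[1:j]); force <- c(force, fj[1:j])
    ext <- c(ext, zj[1:j] - fj[1:j] / system$cantilever_stiffness)
    # pick the channel in proportion to its rate at the event force
    rates <- vapply(ch, function(c) bell_rate(min(fj[j], 4000), c$kin,
                                              system$polymer$kBT),
                    numeric(1))
    pick <- ch[[sample.int(length(ch), 1, prob = rates)]]
    lr <- if (j > 1) (fj[j] - fj[j - 1]) / dt else
      if (length(fj) > 1) (fj[2] - fj[1]) / dt else
        system$cantilever_stiffness * v
    idx <- length(time)
    if (pick$kind == "domain") {
      d <- folded[[pick$i]]
      events[[length(events) + 1]] <- data.frame(
        time = tj[j], index = idx, force = fj[j],
        kind = paste0("domain_unfold:", d$name), loading_rate = lr)
      l_prot <- l_prot + d$delta_Lc + d$folded_length
      rigid <- rigid - d$folded_length
      if (d$name == system$xmod_name) xmod_unfolded <- TRUE
      folded <- folded[-pick$i]
    } else {
      events[[length(events) + 1]] <- data.frame(
        time = tj[j], index = idx, force = fj[j],
        kind = "complex_rupture", loading_rate = lr)
      ruptured <- TRUE
    }
    t0 <- tj[j]
  }

  if (ruptured && protocol$post_rupture_time > 0) {
    tt <- seq(t0 + dt, t0 + protocol$post_rupture_time, by = dt)
    if (length(tt)) {
      time <- c(time, tt)
      force <- c(force, rep(0, length(tt)))
      ext <- c(ext, v * tt)
    }
  }
  if (protocol$force_noise_sd > 0) {
    force <- force + stats::rnorm(length(force), 0, protocol$force_noise_sd)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), index = integer(0), force = numeric(0),
               kind = character(0), loading_rate = numeric(0))
  # event log reports the force actually recorded on the curve
  if (nrow(ev)) ev$force <- force[ev$index]
  history <- if (!ruptured) "none" else if (xmod_unfolded) "shielded" else
    "intact"
  curve <- force_curve(time = time, extension = ext, force = force,
                       pulling_speed = v, curve_id = curve_id,
                       configuration = "I")
  list(curve = curve, events = ev, history = history)
}

# nonspecific adhesion trace: random WLC peeling events, no fingerprint
simulate_junk_trace <- function(system, protocol, curve_id = "junk") {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  v <- protocol$pulling_speed
  dt <- protocol$time_step
  n_seg <- sample(1:3, 1)
  contours <- sort(stats::runif(n_seg, 20, 150))
  f_det <- stats::runif(n_seg, 50, 400)
  time <- force <- ext <- numeric(0)
  t0 <- 0
  for (s in seq_len(n_seg)) {
    tj <- seq(t0 + dt, protocol$max_extension / v, by = dt)
    if (!length(tj)) break
    zj <- v * tj
    wp <- polymer_params("WLC",
                         persistence_length = system$peg_persistence,
                         kBT = system$polymer$kBT)
    # series WLC + cantilever solved pointwise on the detachment segment
    fj <- vapply(zj, function(z) {
      g <- function(f) f / system$cantilever_stiffness +
        contours[s] * wlc_extension_ratio(f, wp$persistence_length, wp$kBT) -
        z
      if (g(1e-9) > 0) return(0)
      stats::uniroot(g, c(1e-9, 5e4), tol = 1e-9)$root
    }, numeric(1))
    j <- match(TRUE, fj >= f_det[s])
    if (is.na(j)) j <- length(fj)
    time <- c(time, tj[1:j]); force <- c(force, fj[1:j])
    ext <- c(ext, zj[1:j] - fj[1:j] / system$cantilever_stiffness)
    t0 <- tj[j]
    if (s == n_seg || j == length(fj)) break
  }
  if (protocol$force_noise_sd > 0) {
    force <- force + stats::rnorm(length(force), 0, protocol$force_noise_sd)
  }
  list(curve = force_curve(time, ext, force, pulling_speed = v,
                           curve_id = curve_id, configuration = "unknown"),
       events = data.frame(time = numeric(0), index = integer(0),
                           force = numeric(0), kind = character(0),
                           loading_rate = numeric(0)),
       history = "junk")
}

#' Simulate a dataset of pulling traces
#'
#' Runs [simulate_trace()] `n_traces` times with per-trace seeds derived
#' deterministically from the master seed in `protocol`, optionally mixing
#' in a fraction of nonspecific-adhesion ("junk") traces with no
#' fingerprint, and optionally writing the plain-text curve container and
#' ground-truth table.
#'
#' @param system a [system_spec()].
#' @param protocol a [protocol_spec()]; its `seed` is the master seed.
#' @param n_traces number of traces, `>= 1`.
#' @param pulling_speeds optional vector of speeds cycled across traces
#'   (overrides `protocol$pulling_speed`).
#' @param junk_fraction fraction of junk traces, in `[0, 1)`. Default 0.
#' @param dir if non-`NULL`, write `curves.tsv`, `curve_metadata.tsv` and
#'   `ground_truth.csv` there (see [write_curve_dataset()]).
#' @return list with `curves` (list of [force_curve()]),
#'   `ground_truth` (`data.frame`: `trace_id`, `pulling_speed`, `history`,
#'   one row per event: `kind`, `time`, `index`, `force`, `loading_rate`).
#' @export
simulate_dataset <- function(system, protocol, n_traces,
                             pulling_speeds = NULL, junk_fraction = 0,
                             dir = NULL) {
  stopifnot(n_traces >= 1, junk_fraction >= 0, junk_fraction < 1)
  master <- if (is.null(protocol$seed)) 1L else protocol$seed
  set.seed(master)
  trace_seeds <- sample.int(.Machine$integer.max - 1L, n_traces)
  is_junk <- stats::runif(n_traces) < junk_fraction
  if (is.null(pulling_speeds)) pulling_speeds <- protocol$pulling_speed
  speeds <- rep_len(pulling_speeds, n_traces)
  # Xyn does not refold once lost (configuration II behaviour) -- dataset
  # level flag is carried by the refoldable field; configuration I systems
  # keep all domains, so nothing to drop here per trace.
  curves <- vector("list", n_traces)
  gt <- list()
  for (i in seq_len(n_traces)) {
    id <- sprintf("trace_%04d", i)
    pi <- protocol
    pi$seed <- trace_seeds[i]
    pi$pulling_speed <- speeds[i]
    tr <- if (is_junk[i]) simulate_junk_trace(system, pi, id) else
      simulate_trace(system, pi, id)
    curves[[i]] <- tr$curve
    if (nrow(tr$events)) {
      g <- tr$events
      g$trace_id <- id
      g$pulling_speed <- speeds[i]
      g$history <- tr$history
      gt[[length(gt) + 1]] <- g
    } else {
      gt[[length(gt) + 1]] <- data.frame(
        time = NA_real_, index = NA_integer_, force = NA_real_,
        kind = "none", loading_rate = NA_real_, trace_id = id,
        pulling_speed = speeds[i], history = tr$history)
    }
  }
  ground_truth <- do.call(rbind, gt)
  ground_truth <- ground_truth[, c("trace_id", "pulling_speed", "history",
                                   "kind", "time", "index", "force",
                                   "loading_rate")]
  out <- list(curves = curves, ground_truth = ground_truth,
              master_seed = master)
  if (!is.null(dir)) write_curve_dataset(out, dir)
  out
}
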