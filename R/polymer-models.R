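#' Polymer elasticity parameters
#'
#' Bundles the parameters of the two elasticity models used throughout the
#' package: the freely rotating chain with quantum-mechanical backbone
#' stretching corrections (QM-FRC), used for unfolded polypeptide, and the
#' worm-like chain (WLC, Marko-Siggia interpolation), used for PEG linkers.
#'
#' The FRC describes the polypeptide as rigid bonds of length `b` joined at
#' a fixed angle `gamma`. Its effective persistence length is
#' `l_p = b * cos(gamma/2) / |log(cos(gamma))|`, and its force-extension
#' response crosses over from a semiflexible (persistence-length dominated)
#' regime to a discrete bond-dominated regime at
#' `F* = kBT * l_p / b^2` (about 124 pN for the defaults). Above `F*` the
#' fractional extension is `1 - kBT / (2 F b)`, which is parameter-free once
#' `b` and `gamma` are fixed; no parameter of this model is ever fitted.
#'
#' The quantum-mechanical correction accounts for elastic lengthening of the
#' peptide backbone itself at high force: the stretched contour length is
#' `L(F) = L0 * stretch_factor(F)` with a quadratic parametrization
#' `stretch_factor(F) = 1 + c1 F + c2 F^2` of ab initio backbone elasticity
#' (about 0.6% elongation at 600 pN with the defaults).
#'
#' @param model `"QM_FRC"` or `"WLC"`.
#' @param b FRC bond length, nm. Default 0.11 nm.
#' @param gamma FRC fixed bond angle, degrees, in (0, 90). Default 41.
#' @param persistence_length WLC persistence length, nm. Default 0.38 nm
#'   (PEG).
#' @param qm_correction numeric vector of polynomial coefficients
#'   `(c1, c2, ...)` of the force-dependent backbone stretch factor
#'   `1 + c1 F + c2 F^2 + ...` (force in pN). Use `NULL` to disable the
#'   correction (factor identically 1).
#' @param kBT thermal energy, pN nm. Default 4.114 (T of about 298 K).
#' @param validity_floor force below which the FRC transform is considered
#'   noise-dominated, pN. Points below it are flagged. Default 10.
#'
#' @return An object of class `polymer_params`.
#' @examples
#' pp <- polymer_params()                   # QM-FRC defaults
#' frc_extension_ratio(200, pp)             # fractional extension at 200 pN
#' wp <- polymer_params("WLC", persistence_length = 0.38)
#' @export
polymer_params <- function(model = c("QM_FRC", "WLC"),
                           b = 0.11,
                           gamma = 41,
                           persistence_length = 0.38,
                           qm_correction = c(6.4e-6, 4.9e-9),
                           kBT = 4.114,
                           validity_floor = 10) {
  model <- match.arg(model)
  stopifnot(b > 0, gamma > 0, gamma < 90, persistence_length > 0, kBT > 0,
            validity_floor >= 0)
  if (!is.null(qm_correction)) {
    stopifnot(is.numeric(qm_correction), length(qm_correction) >= 1)
  }
  obj <- list(
    model = model,
    b = b,
    gamma = gamma,
    persistence_length = persistence_length,
    qm_correction = qm_correction,
    kBT = kBT,
    validity_floor = validity_floor
  )
  class(obj) <- "polymer_params"
  obj
}

#' @export
print.polymer_params <- function(x, ...) {
  cat("Polymer elasticity parameters (", x$model, ")\n", sep = "")
  if (x$model == "QM_FRC") {
    cat(sprintf("  bond length b        : %.3f nm\n", x$b))
    cat(sprintf("  bond angle gamma     : %.1f deg\n", x$gamma))
    cat(sprintf("  eff. persistence l_p : %.4f nm\n", frc_persistence(x)))
    cat(sprintf("  regime crossover F*  : %.1f pN\n", frc_crossover_force(x)))
    cat("  QM correction        : ",
        if (is.null(x$qm_correction)) "disabled"
        else paste(format(x$qm_correction), collapse = ", "), "\n", sep = "")
  } else {
    cat(sprintf("  persistence length   : %.3f nm\n", x$persistence_length))
  }
  cat(sprintf("  kBT                  : %.3f pN nm\n", x$kBT))
  invisible(x)
}

# effective persistence length of the fixed-angle chain, nm
frc_persistence <- function(params) {
  g <- params$gamma * pi / 180
  params$b * cos(g / 2) / abs(log(cos(g)))
}

# crossover force between the semiflexible and discrete-bond regimes, pN
frc_crossover_force <- function(params) {
  params$kBT * frc_persistence(params) / params$b^2
}

#' Backbone stretch factor of the QM-corrected chain
#'
#' Multiplicative elongation of the polypeptide contour length under force:
#' `L(F) = L0 * backbone_stretch_factor(F)`. Equal to 1 at zero force and
#' identically 1 when the correction is disabled.
#'
#' @param force force, pN (vectorized, must be `>= 0`).
#' @param params a [polymer_params()] object.
#' @return dimensionless factor `>= 1`, same length as `force`.
#' @export
backbone_stretch_factor <- function(force, params = polymer_params()) {
  if (any(force < 0)) {
    stop("backbone_stretch_factor(): force must be >= 0", call. = FALSE)
  }
  cf <- params$qm_correction
  if (is.null(cf)) {
    return(rep(1, length(force)))
  }
  fac <- rep(1, length(force))
  for (i in seq_along(cf)) fac <- fac + cf[i] * force^i
  fac
}

# Marko-Siggia interpolation: force (pN) of a WLC at fractional extension r
wlc_force <- function(ratio, persistence_length, kBT) {
  (kBT / persistence_length) *
    (1 / (4 * (1 - ratio)^2) - 0.25 + ratio)
}

# inverse Marko-Siggia: fractional extension at force (vectorized Newton on
# u = 1 - r via the cubic 4u^3 + 4(f - 3/4)u^2 - 1 = 0)
wlc_extension_ratio <- function(force, persistence_length, kBT) {
  f <- force * persistence_length / kBT
  vapply(f, function(fi) {
    if (fi <= 0) return(0)
    g <- function(u) 4 * u^3 + 4 * (fi - 0.75) * u^2 - 1
    u <- stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    1 - u
  }, numeric(1))
}

#' Fractional extension of the freely rotating chain
#'
#' Ratio `x/L` of end-to-end extension to (stretched) contour length at a
#' given force. Below the crossover force `F* = kBT l_p / b^2` the
#' semiflexible response (Marko-Siggia interpolation at the FRC effective
#' persistence length) is used; above it, the discrete-bond regime
#' `1 - kBT/(2 F b)`. When the QM correction is enabled the contour length
#' `L` in the ratio is the force-dependent stretched contour length.
#'
#' @param force force, pN, `> 0` (vectorized).
#' @param params a [polymer_params()] with `model = "QM_FRC"`.
#' @param warn_below_floor warn when any force is below
#'   `params$validity_floor` (noise-dominated region; the value is still
#'   computed). Default `TRUE`.
#' @return `x/L` in (0, 1), strictly increasing in force.
#' @export
frc_extension_ratio <- function(force, params = polymer_params(),
                                warn_below_floor = TRUE) {
  if (params$model != "QM_FRC") {
    stop("frc_extension_ratio() requires QM_FRC parameters", call. = FALSE)
  }
  if (any(force <= 0)) {
    stop("frc_extension_ratio(): force must be > 0", call. = FALSE)
  }
  if (warn_below_floor && any(force < params$validity_floor)) {
    warning(sprintf(
      "%d force value(s) below the %.0f pN validity floor; computed anyway",
      sum(force < params$validity_floor), params$validity_floor
    ), call. = FALSE)
  }
  lp <- frc_persistence(params)
  fstar <- frc_crossover_force(params)
  out <- numeric(length(force))
  hi <- force > fstar
  out[hi] <- 1 - params$kBT / (2 * force[hi] * params$b)
  if (any(!hi)) {
    out[!hi] <- wlc_extension_ratio(force[!hi], lp, params$kBT)
  }
  out
}

# fractional extension dispatched on model; used by the simulator
extension_ratio <- function(force, params) {
  if (params$model == "QM_FRC") {
    r <- frc_extension_ratio(pmax(force, 1e-12), params,
                             warn_below_floor = FALSE)
    r * backbone_stretch_factor(pmax(force, 0), params)
  } else {
    wlc_extension_ratio(force, params$persistence_length, params$kBT)
  }
}

# end-to-end extension (nm) of a chain of zero-force contour length L0
model_extension <- function(force, contour_length, params) {
  contour_length * extension_ratio(force, params)
}

#' Force at a given extension (numerical inverse of the elasticity model)
#'
#' Root-solves `model_extension(F) = extension` for `F`. For the WLC this
#' uses the Marko-Siggia closed form directly; for the QM-FRC it brackets
#' and bisects the monotone extension model.
#'
#' @param extension end-to-end extension, nm, `>= 0`.
#' @param contour_length zero-force contour length `L0`, nm, `> 0`.
#' @param params a [polymer_params()] object.
#' @param f_max upper bracket for the root search, pN. Default 5e4.
#' @return force, pN.
#' @export
force_at_extension <- function(extension, contour_length,
                               params = polymer_params(), f_max = 5e4) {
  stopifnot(contour_length > 0)
  if (length(extension) > 1) {
    return(vapply(extension, force_at_extension, numeric(1),
                  contour_length = contour_length, params = params,
                  f_max = f_max))
  }
  if (extension < 0) stop("extension must be >= 0", call. = FALSE)
  if (extension == 0) return(0)
  if (params$model == "WLC") {
    r <- extension / contour_length
    if (r >= 1) {
      stop(sprintf("extension %.3g nm exceeds WLC contour length %.3g nm",
                   extension, contour_length), call. = FALSE)
    }
    return(wlc_force(r, params$persistence_length, params$kBT))
  }
  x_hi <- model_extension(f_max, contour_length, params)
  if (extension >= x_hi) {
    stop(sprintf(
      "extension %.4g nm not attainable below %.3g pN (max %.4g nm)",
      extension, f_max, x_hi), call. = FALSE)
  }
  g <- function(f) model_extension(f, contour_length, params) - extension
  lo <- 1e-9
  if (g(lo) > 0) {
    stop("force_at_extension(): root not bracketable at lower bound",
         call. = FALSE)
  }
  stats::uniroot(g, c(lo, f_max), tol = 1e-12 * f_max)$root
}

#' Apparent contour length of a force-extension point
#'
#' The contour-length transformation: each sampled point `(F, x)` with force
#' above the threshold is mapped to the zero-force contour length
#' `L0 = x / (frc_ratio(F) * stretch_factor(F))` of the QM-FRC chain that
#' would show that extension at that force. Points at or below the threshold
#' are rejected (returned as `NA`, counted, not an error): at low force the
#' transformation amplifies noise and the model leaves its validity range.
#'
#' @param force force, pN (vectorized).
#' @param extension extension, nm (same length).
#' @param params a [polymer_params()] with `model = "QM_FRC"`.
#' @param force_threshold rejection threshold, pN. Defaults to
#'   `params$validity_floor`.
#' @return numeric vector of apparent contour lengths, nm; `NA` where
#'   rejected, with attribute `n_rejected`.
#' @export
apparent_contour_length <- function(force, extension,
                                    params = polymer_params(),
                                    force_threshold = params$validity_floor) {
  stopifnot(length(force) == length(extension))
  out <- rep(NA_real_, length(force))
  ok <- is.finite(force) & force > force_threshold
  if (any(ok)) {
    ratio <- frc_extension_ratio(force[ok], params, warn_below_floor = FALSE) *
      backbone_stretch_factor(force[ok], params)
    out[ok] <- extension[ok] / ratio
  }
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Fingerprint-domain increment table
#'
#' Expected unfolding contour-length increments of the fingerprint domains.
#' Each entry relates the residue count and folded N-C distance of a domain
#' to the contour length it releases on unfolding:
#' `increment = residues * residue_length - folded_length`, with
#' `residue_length = 0.365` nm per stretched amino acid.
#'
#' The default table carries entries whose increments reproduce the
#' canonical fingerprints of the xylanase (about 89 nm) and CBM (about 56
#' nm) marker domains plus the X-module; the residue counts and folded
#' lengths are synthetic placeholders consistent with those increments, not
#' measured values.
#'
#' @param entries `data.frame` with columns `name`, `residues`,
#'   `folded_length` (nm), and optionally `steps` (the number of
#'   sequential unfolding sub-steps the domain shows; the xylanase
#'   fingerprint is three-peaked, so its increment may be spread over up
#'   to three measured sub-increments. Default 1).
#' @param residue_length contour length per stretched amino acid, nm.
#'   Default 0.365.
#' @return object of class `increment_table`: the entries with an
#'   `increment` column.
#' @examples
#' increment_table()
#' @export
increment_table <- function(entries = NULL, residue_length = 0.365) {
  stopifnot(residue_length > 0)
  if (is.null(entries)) {
    entries <- data.frame(
      name = c("Xyn", "CBM", "XMod"),
      residues = c(255L, 167L, 105L),
      folded_length = c(4.0, 5.0, 4.5),
      steps = c(3L, 1L, 1L)
    )
  }
  stopifnot(all(c("name", "residues", "folded_length") %in% names(entries)))
  if (is.null(entries$steps)) entries$steps <- 1L
  entries$increment <- vapply(
    seq_len(nrow(entries)),
    function(i) expected_increment(entries$residues[i],
                                   entries$folded_length[i],
                                   residue_length),
    numeric(1)
  )
  structure(list(entries = entries, residue_length = residue_length),
            class = "increment_table")
}

#' @export
print.increment_table <- function(x, ...) {
  cat("Fingerprint increment table (", x$residue_length,
      " nm per stretched residue)\n", sep = "")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Expected contour-length increment of a domain
#'
#' `residues * residue_length - folded_length`: the contour length gained
#' when a folded domain of known size unfolds, accounting for the folded
#' N-C distance already part of the stretched path.
#'
#' @param residues number of residues released, `> 0`.
#' @param folded_length folded N-C distance, nm, `>= 0`.
#' @param residue_length nm per stretched amino acid. Default 0.365.
#' @return increment, nm (`> 0`, otherwise an error).
#' @examples
#' expected_increment(255, 4.0)   # xylanase fingerprint, ~89 nm
#' @export
expected_increment <- function(residues, folded_length,
                               residue_length = 0.365) {
  stopifnot(residues > 0, folded_length >= 0, residue_length > 0)
  inc <- residues * residue_length - folded_length
  if (inc <= 0) {
    stop(sprintf(
      "folded length %.3g nm exceeds stretched length %.3g nm",
      folded_length, residues * residue_length), call. = FALSE)
  }
  inc
}
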