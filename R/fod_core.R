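#' Fit the Gaussian hydrophobicity field to a position cloud
#'
#' The idealized ("theoretical") hydrophobicity density of a globular
#' protein is a 3D Gaussian encapsulating the whole structure. The capsule
#' is oriented along the principal axes of the centered position cloud;
#' within that frame, the center is the midpoint of the axis-aligned
#' bounding box and each sigma is 1/6 of the box span along its axis (the
#' three-sigma rule: the most distal positions sit three sigmas out).
#'
#' The 2D variant (\code{kind = "gauss2d"}) models a ribbon-like micelle:
#' the axis of largest span -- the fibril long axis -- is suppressed, so
#' the density depends only on the cross-sectional plane. This is the
#' limit of a 3D Gaussian whose long-axis sigma tends to infinity.
#'
#' @param positions Numeric matrix (n x 3) of effective-atom coordinates
#'   in Angstrom; n >= 2, not all coincident.
#' @param kind \code{"gauss3d"} (default) or \code{"gauss2d"}.
#' @param sigma_floor Sigma substituted (with a warning) for axes with
#'   zero span, so planar or collinear toys remain analyzable. Default 1 A.
#' @return Object of class \code{gaussian_field}: list with \code{center}
#'   (3-vector, model frame), \code{sigmas} (3-vector, field frame),
#'   \code{rotation} (3x3, rows = field axes; maps model frame to field
#'   frame), \code{kind}, and \code{suppressed_axis} (gauss2d only).
#' @export
fit_field <- function(positions, kind = c("gauss3d", "gauss2d"),
                      sigma_floor = 1.0) {
  kind <- match.arg(kind)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (nrow(positions) < 2L) stop("need at least 2 positions to fit a field")
  ctr0 <- colMeans(positions)
  centered <- sweep(positions, 2, ctr0)
  if (all(abs(centered) < 1e-12)) stop("all positions coincide")
  cv <- crossprod(centered) / (nrow(centered) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rot <- t(eg$vectors)            # rows: principal axes, descending variance
  # deterministic sign convention, then enforce right-handedness
  for (k in 1:2) if (rot[k, which.max(abs(rot[k, ]))] < 0) rot[k, ] <- -rot[k, ]
  rot[3, ] <- pracma_cross(rot[1, ], rot[2, ])
  rotated <- centered %*% t(rot)
  lo <- apply(rotated, 2, min)
  hi <- apply(rotated, 2, max)
  span <- hi - lo
  sigmas <- span / 6
  if (any(sigmas <= 0)) {
    warning("degenerate span along ", sum(sigmas <= 0),
            " axis/axes; sigma floored at ", sigma_floor, " A")
    sigmas[sigmas <= 0] <- sigma_floor
  }
  mid <- (lo + hi) / 2                      # bbox midpoint, field frame
  center <- ctr0 + drop(t(rot) %*% mid)     # back to model frame
  suppressed <- if (kind == "gauss2d") which.max(span) else NA_integer_
  structure(list(center = center, sigmas = sigmas, rotation = rot,
                 kind = kind, suppressed_axis = suppressed),
            class = "gaussian_field")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.gaussian_field <- function(x, ...) {
  cat("Gaussian hydrophobicity field (", x$kind, ")\n",
      "  center: ", paste(sprintf("%.2f", x$center), collapse = " "), " A\n",
      "  sigmas: ", paste(sprintf("%.2f", x$sigmas), collapse = " "), " A\n",
      sep = "")
  if (x$kind == "gauss2d")
    cat("  suppressed (long) axis:", x$suppressed_axis, "\n")
  invisible(x)
}

# shared profile constructor: normalize nonnegative raw values to sum 1
new_profile <- function(raw, keys, kind) {
  if (any(raw < 0)) stop("profile values must be nonnegative")
  s <- sum(raw)
  if (s <= 0) stop("profile sums to zero; ", kind, " undefined on this subset")
  structure(raw / s, names = keys, kind = kind)
}

res_keys <- function(res) paste0(res$chain, ":", res$resno)

#' Theoretical hydrophobicity profile (T)
#'
#' Evaluates the fitted Gaussian at each effective-atom position (in the
#' field frame, as a product of per-axis terms exp(-(u - u0)^2 / 2 sigma^2);
#' the 2D variant omits the suppressed long-axis term) and normalizes the
#' values to sum 1 over the scope.
#'
#' @param field A [fit_field()] result.
#' @param positions n x 3 matrix of effective-atom positions.
#' @param keys Optional residue keys for naming.
#' @return Numeric profile vector summing to 1 (kind \code{"T"}).
#' @export
theoretical_profile <- function(field, positions, keys = NULL) {
  stopifnot(inherits(field, "gaussian_field"))
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) stop("empty scope")
  u <- sweep(positions, 2, field$center) %*% t(field$rotation)
  terms <- exp(-sweep(u^2, 2, 2 * field$sigmas^2, `/`))
  if (field$kind == "gauss2d") terms[, field$suppressed_axis] <- 1
  new_profile(apply(terms, 1, prod), keys, "T")
}

#' Observed hydrophobicity profile (O)
#'
#' The observed hydrophobicity collected by residue j is the sum over all
#' residues i (including i = j, for which the weight is 1) of
#' \deqn{(h_i + h_j)\,w(r_{ij}),\qquad
#'   w(r) = 1 - \tfrac12\left(7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 - (r/c)^8\right)}
#' for \eqn{r \le c} and 0 beyond the cutoff \eqn{c} (default 9 Angstrom).
#' The raw values are normalized to sum 1.
#'
#' @param positions n x 3 matrix of effective-atom positions.
#' @param h Intrinsic hydrophobicities, aligned with \code{positions}.
#' @param cutoff Interaction cutoff c in Angstrom (default 9).
#' @param keys Optional residue keys.
#' @return Numeric profile vector summing to 1 (kind \code{"O"}).
#' @export
observed_profile <- function(positions, h, cutoff = 9.0, keys = NULL) {
  positions <- as.matrix(positions)
  if (length(h) != nrow(positions))
    stop("positions and hydrophobicities have mismatched lengths")
  if (cutoff <= 0) stop("cutoff must be positive")
  raw <- observed_raw(positions, h, cutoff)
  new_profile(raw, keys, "O")
}

# unnormalized interaction sums; vectorized over the full distance matrix
observed_raw <- function(positions, h, cutoff) {
  d <- as.matrix(stats::dist(positions))
  w <- interaction_weight(d, cutoff)
  hs <- outer(h, h, `+`)           # h_i + h_j
  colSums(hs * w)
}

#' Hydrophobic interaction weight
#'
#' The distance-dependent contact function of the observed distribution:
#' 1 at r = 0, exactly 0 at the cutoff, 0 beyond.
#'
#' @param r Distances (Angstrom), any shape.
#' @param cutoff Cutoff c in Angstrom.
#' @return Weights in \[0, 1\], same shape as \code{r}.
#' @export
interaction_weight <- function(r, cutoff = 9.0) {
  x2 <- (r / cutoff)^2
  w <- 1 - 0.5 * (7 * x2 - 9 * x2^2 + 5 * x2^3 - x2^4)
  w[r > cutoff] <- 0
  w
}

#' Intrinsic hydrophobicity profile (H)
#'
#' Per-residue scale values normalized to sum 1 over the subset.
#'
#' @param aa One-letter codes, or a precomputed numeric vector of
#'   intrinsic hydrophobicities.
#' @param scale Scale used when \code{aa} is character.
#' @param keys Optional residue keys.
#' @return Numeric profile vector summing to 1 (kind \code{"H"}).
#' @export
intrinsic_profile <- function(aa, scale = hydro_scale(), keys = NULL) {
  v <- if (is.character(aa)) scale_lookup(aa, scale) else as.numeric(aa)
  if (sum(v) <= 0)
    stop("all intrinsic hydrophobicities are zero; H undefined")
  new_profile(v, keys, "H")
}

#' Uniform reference profile (R)
#'
#' The "no core" reference: every residue carries 1/N.
#'
#' @param n Number of residues (>= 1).
#' @param keys Optional residue keys.
#' @return Numeric profile vector of n values 1/n (kind \code{"R"}).
#' @export
uniform_profile <- function(n, keys = NULL) {
  if (n < 1L) stop("n must be >= 1")
  new_profile(rep(1, n), keys, "R")
}

#' Kullback--Leibler divergence between hydrophobicity profiles
#'
#' \deqn{D_{KL}(p \| p_0) = \sum_i p_i \log_2(p_i / p_{0i})}
#' in bits (base-2 logarithm). Target zeros contribute 0; reference values
#' are floored at 1e-10 and renormalized so the divergence stays finite on
#' profiles with structural zeros.
#'
#' @param target,reference Profiles of equal length (nonnegative, each
#'   summing to 1).
#' @return Nonnegative divergence in bits.
#' @export
kl_divergence <- function(target, reference) {
  if (length(target) != length(reference))
    stop("profiles have different lengths")
  q <- pmax(as.numeric(reference), 1e-10)
  q <- q / sum(q)
  p <- as.numeric(target)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Relative distance (RD)
#'
#' \deqn{RD = \frac{D_{KL}(O\|T)}{D_{KL}(O\|T) + D_{KL}(O\|\mathrm{ref})}}
#' RD < 0.5 means the observed distribution is closer to the theoretical
#' Gaussian than to the reference: a prominent hydrophobic core is present
#' (T--O--R variant, reference R) or the structure is not dominated by
#' intrinsic residue properties (T--O--H variant, reference H).
#'
#' @param dkl_ot Divergence of O from T (nonnegative).
#' @param dkl_oref Divergence of O from the reference (nonnegative).
#' @return RD in \[0, 1\].
#' @export
relative_distance <- function(dkl_ot, dkl_oref) {
  if (dkl_ot < 0 || dkl_oref < 0) stop("divergences must be nonnegative")
  if (dkl_ot + dkl_oref == 0)
    stop("both divergences are zero; RD undefined")
  dkl_ot / (dkl_ot + dkl_oref)
}

#' Pearson correlations between the H, T and O profiles
#'
#' @param h,t,o Profiles of equal length (>= 3).
#' @return Named numeric vector \code{c(hvt, tvo, hvo)}. A pair involving
#'   a zero-variance profile yields \code{NA} with a warning.
#' @export
fod_correlations <- function(h, t, o) {
  n <- length(t)
  if (length(h) != n || length(o) != n) stop("profiles differ in length")
  if (n < 3L) stop("correlations need at least 3 residues")
  safe_cor <- function(a, b, lab) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero variance; ", lab, " correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  c(hvt = safe_cor(as.numeric(h), as.numeric(t), "HvT"),
    tvo = safe_cor(as.numeric(t), as.numeric(o), "TvO"),
    hvo = safe_cor(as.numeric(h), as.numeric(o), "HvO"))
}

#' Per-residue accordance categories
#'
#' Compares O with T residue by residue. Residues within tolerance of the
#' theoretical value are accordant: hydrophobic-core members if their T is
#' at or above the unit median (structure interior), hydrophilic surface
#' otherwise. Discordant residues either expose excess hydrophobicity at
#' the surface (O - T > tau) or internalize hydrophilic residues
#' (T - O > tau).
#'
#' @param t,o Profiles of equal length.
#' @param tau Accordance tolerance; defaults to the median |T - O| of the
#'   unit, an adaptive rule that scales with the unit's overall discordance.
#' @return Factor with levels \code{core_accordant}, \code{surface_accordant},
#'   \code{hydrophobic_exposed}, \code{hydrophilic_internalized}.
#' @export
classify_residues <- function(t, o, tau = NULL) {
  if (length(t) != length(o)) stop("profiles differ in length")
  t <- as.numeric(t); o <- as.numeric(o)
  if (is.null(tau)) tau <- stats::median(abs(t - o))
  if (tau < 0) stop("tau must be nonnegative")
  lab <- ifelse(o - t > tau, "hydrophobic_exposed",
         ifelse(t - o > tau, "hydrophilic_internalized",
         ifelse(t >= stats::median(t), "core_accordant",
                "surface_accordant")))
  factor(lab, levels = c("core_accordant", "surface_accordant",
                         "hydrophobic_exposed", "hydrophilic_internalized"))
}

#' Greedy elimination of discordant residues
#'
#' Identifies the fragments responsible for a discordant (RD >= 0.5)
#' status: repeatedly removes the residue with the largest |O - T| (ties
#' break toward the lower index), renormalizes T, O and the reference over
#' the survivors, and recomputes RD, until RD drops below the threshold or
#' only 3 residues remain (then flagged irreducible).
#'
#' @param t,o,r Profiles of equal length (reference r is typically the
#'   uniform profile).
#' @param threshold RD stopping threshold (default 0.5).
#' @param keys Optional residue keys; defaults to profile names or indices.
#' @return List: \code{removed} (keys in removal order), \code{rd_trace}
#'   (RD before any removal and after each), \code{survivors} (keys),
#'   \code{final_rd}, \code{irreducible} (logical).
#' @export
eliminate_discordant <- function(t, o, r, threshold = 0.5, keys = NULL) {
  n <- length(t)
  if (length(o) != n || length(r) != n) stop("profiles differ in length")
  keys <- keys %||% names(t) %||% as.character(seq_len(n))
  t <- as.numeric(t); o <- as.numeric(o); r <- as.numeric(r)
  alive <- rep(TRUE, n)
  rd_of <- function() {
    ts <- t[alive] / sum(t[alive])
    os <- o[alive] / sum(o[alive])
    rs <- r[alive] / sum(r[alive])
    relative_distance(kl_divergence(os, ts), kl_divergence(os, rs))
  }
  rd <- rd_of()
  trace <- rd
  removed <- character(0)
  while (rd >= threshold && sum(alive) > 3L) {
    idx_alive <- which(alive)
    gap <- abs(o[idx_alive] / sum(o[alive]) - t[idx_alive] / sum(t[alive]))
    drop_i <- idx_alive[which.max(gap)]    # which.max: first (lowest) index
    alive[drop_i] <- FALSE
    removed <- c(removed, keys[drop_i])
    rd <- rd_of()
    trace <- c(trace, rd)
  }
  list(removed = removed, rd_trace = trace,
       survivors = keys[alive], final_rd = rd,
       irreducible = rd >= threshold)
}

#' Hydrophobic-core residues
#'
#' The core is formed by residues with high values of both T and O
#' relative to the rest of the unit: both at or above the q-quantile.
#'
#' @param t,o Profiles of equal length.
#' @param q Quantile in (0, 1); default 0.75.
#' @param keys Optional residue keys.
#' @return Character vector of core residue keys.
#' @export
core_residues <- function(t, o, q = 0.75, keys = NULL) {
  if (length(t) != length(o)) stop("profiles differ in length")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  keys <- keys %||% names(t) %||% as.character(seq_along(t))
  t <- as.numeric(t); o <- as.numeric(o)
  sel <- t >= stats::quantile(t, q) & o >= stats::quantile(o, q)
  keys[sel]
}

#' Per-cross-section theoretical profiles of a fibril (diagnostic)
#'
#' Under the 2D (ribbon-like micelle) field, every cross-section of a
#' translationally repeated fibril carries the same hydrophobicity
#' distribution. This diagnostic renormalizes the 2D theoretical profile
#' within each cross-section (chain) so the claim can be inspected
#' directly; the headline FOD scores always normalize over the whole scope.
#'
#' @param field A gauss2d [fit_field()] result.
#' @param positions n x 3 positions.
#' @param groups Cross-section labels (typically the chain ids), length n.
#' @return List of per-group profiles, each summing to 1.
#' @export
cross_section_profiles <- function(field, positions, groups) {
  if (field$kind != "gauss2d")
    stop("cross-section profiles are defined for gauss2d fields")
  raw <- theoretical_profile(field, positions)
  lapply(split(as.numeric(raw), groups), function(v) v / sum(v))
}
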