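# Ground-truth structure generators. Synthetic structures use real
# amino-acid types binned into hydrophobic/neutral/polar classes by scale
# tertile, so the same scale machinery serves real and synthetic inputs.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic globular "spherical micelle" structure
#'
#' Residue positions are drawn quasi-uniformly inside a sphere (rejection
#' sampling). Residue types are assigned so that intrinsic hydrophobicity
#' decreases with distance from the centroid: with probability
#' \code{core_bias} a residue inside half the radius draws a hydrophobic
#' type and one outside draws a polar type; otherwise the type is drawn
#' uniformly. \code{core_bias = 1} is an idealized micelle with a fully
#' centralized hydrophobic core; \code{core_bias = 0} is a placement null.
#'
#' @param n_residues Number of residues (>= 10; default 200, a small
#'   single-domain globule).
#' @param radius Sphere radius in Angstrom; default \code{3.2 *
#'   n_residues^(1/3)}, matching typical protein packing density.
#' @param core_bias Core-placement strength in \[0, 1\].
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param scale Hydrophobicity scale (defines the type classes).
#' @return A [fod_structure] (single chain "A") with effective positions
#'   set.
#' @export
make_globule <- function(n_residues = 200, radius = NULL, core_bias = 1,
                         seed = 1, scale = hydro_scale()) {
  stopifnot(n_residues >= 10, core_bias >= 0, core_bias <= 1)
  radius <- radius %||% (3.2 * n_residues^(1 / 3))
  stopifnot(radius > 0)
  cls <- aa_classes(scale)
  with_seed(seed, {
    pos <- matrix(NA_real_, n_residues, 3)
    got <- 0L
    while (got < n_residues) {
      cand <- matrix(stats::runif(3 * 2 * (n_residues - got), -radius, radius),
                     ncol = 3)
      keep <- rowSums(cand^2) <= radius^2
      take <- min(sum(keep), n_residues - got)
      if (take > 0) {
        pos[got + seq_len(take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
        got <- got + take
      }
    }
    r <- sqrt(rowSums(pos^2))
    aa <- vapply(seq_len(n_residues), function(i) {
      if (stats::runif(1) < core_bias) {
        pool <- if (r[i] < radius / 2) cls$hydrophobic else cls$polar
      } else {
        pool <- unlist(cls)
      }
      sample(pool, 1L)
    }, character(1))
    res <- data.frame(chain = "A", resno = seq_len(n_residues), aa = aa,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      h = scale_lookup2(aa, scale),
                      stringsAsFactors = FALSE)
    fod_structure(res, name = sprintf("globule_n%d_b%.2f_s%d",
                                      n_residues, core_bias, seed))
  })
}

#' Generate a synthetic amyloid fibril with an axial hydrophobic band
#'
#' Builds one planar serpentine chain motif (two extended strands joined
#' by a turn, 3.5 Angstrom residue spacing) and stacks identical copies
#' along z at \code{rise_per_chain} (default 4.7 Angstrom, the cross-beta
#' stacking rise), producing a ribbon-like fibril. All chains share one
#' sequence, drawn so that residues within \code{band_width} of the fibril
#' axis are hydrophobic with probability \code{band_bias} (polar outside),
#' creating the axial hydrophobic band characteristic of a ribbon-like
#' micelle; with probability \code{1 - band_bias} the type is uniform.
#'
#' @param n_chains Number of stacked chains (>= 3; default 12, enough for
#'   the stacking axis to dominate the geometry).
#' @param chain_length Residues per chain (>= 8; default 24).
#' @param rise_per_chain Axial rise per chain in Angstrom (default 4.7).
#' @param band_width Half-width of the axial hydrophobic band in Angstrom
#'   (default 8).
#' @param band_bias Band-placement strength in \[0, 1\].
#' @param seed Integer seed.
#' @param scale Hydrophobicity scale.
#' @return A [fod_structure]; chains labeled A, B, C, ... form one
#'   protofibril group.
#' @export
make_fibril <- function(n_chains = 12, chain_length = 24,
                        rise_per_chain = 4.7, band_width = 8,
                        band_bias = 1, seed = 1, scale = hydro_scale()) {
  stopifnot(n_chains >= 3, chain_length >= 8, rise_per_chain > 0,
            band_width > 0, band_bias >= 0, band_bias <= 1)
  chain_ids <- c(LETTERS, letters)
  if (n_chains > length(chain_ids)) stop("at most 52 chains supported")
  cls <- aa_classes(scale)
  with_seed(seed, {
    m <- chain_length %/% 2L
    extra <- chain_length - 2L * m
    xs <- (seq_len(m) - (m + 1) / 2) * 3.5
    motif <- rbind(cbind(xs, -2.4, 0), cbind(rev(xs), 2.4, 0))
    if (extra) motif <- rbind(motif, c(max(xs) + 2.0, 0, 0))
    # thermal jitter, fixed once so every chain repeats the same motif;
    # nonzero thickness keeps a standalone chain's own capsule non-degenerate
    motif <- motif + matrix(stats::rnorm(3L * chain_length, 0, 0.3),
                            ncol = 3)
    # orthogonalize out-of-plane jitter against the in-plane coordinates so
    # the stacking axis stays an exact principal axis for any chain count
    X <- cbind(1, motif[, 1], motif[, 2])
    motif[, 3] <- motif[, 3] -
      X %*% solve(crossprod(X), crossprod(X, motif[, 3]))
    d_axis <- sqrt(rowSums(sweep(motif[, 1:2], 2,
                                 colMeans(motif[, 1:2]))^2))
    aa <- vapply(seq_len(chain_length), function(i) {
      if (stats::runif(1) < band_bias) {
        pool <- if (d_axis[i] <= band_width) cls$hydrophobic else cls$polar
      } else {
        pool <- unlist(cls)
      }
      sample(pool, 1L)
    }, character(1))
    h <- scale_lookup2(aa, scale)
    z0 <- (seq_len(n_chains) - (n_chains + 1) / 2) * rise_per_chain
    res <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
      data.frame(chain = chain_ids[k], resno = seq_len(chain_length),
                 aa = aa, x = motif[, 1], y = motif[, 2],
                 z = motif[, 3] + z0[k], h = h, stringsAsFactors = FALSE)
    }))
    fod_structure(res, protofibrils = list(chain_ids[seq_len(n_chains)]),
                  name = sprintf("fibril_c%d_l%d_b%.2f_s%d",
                                 n_chains, chain_length, band_bias, seed))
  })
}

#' Scramble hydrophobicity assignments (null model)
#'
#' Permutes residue types (and their intrinsic hydrophobicities) uniformly
#' at random across positions, leaving all coordinates untouched. The
#' scramble destroys the spatial organization of hydrophobicity while
#' preserving both geometry and composition, so any FOD score difference
#' from the original is attributable to hydrophobicity placement alone.
#'
#' @param model A [fod_structure].
#' @param seed Integer seed.
#' @return The model with permuted \code{aa}/\code{h} columns.
#' @export
scramble_hydrophobicity <- function(model, seed = 1) {
  stopifnot(inherits(model, "fod_structure"))
  if (length(unique(model$residues$aa)) < 2L) {
    warning("single residue type; scramble is a no-op")
    return(model)
  }
  with_seed(seed, {
    perm <- sample(nrow(model$residues))
    model$residues$aa <- model$residues$aa[perm]
    model$residues$h <- model$residues$h[perm]
    model$name <- paste0(model$name, "_scrambled_s", seed)
    model
  })
}

aa123_map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Write a structure as a single-model PDB file
#'
#' Each residue is written as one CA record at its effective position,
#' occupancy 1.00. When a per-residue value is supplied via
#' \code{bfactor} (e.g. \code{100 * O}), it fills the B-factor column so
#' standard viewers can color structures by observed hydrophobicity.
#'
#' @param model A [fod_structure] with positions set.
#' @param path Output path.
#' @param bfactor Optional numeric vector (one per residue) for the
#'   B-factor column; default 0.
#' @return The path, invisibly.
#' @export
write_pdb <- function(model, path, bfactor = NULL) {
  stopifnot(inherits(model, "fod_structure"))
  res <- model$residues
  if (anyNA(res$x)) stop("effective positions missing; cannot write PDB")
  b <- bfactor %||% rep(0, nrow(res))
  if (length(b) != nrow(res)) stop("bfactor length mismatch")
  res3 <- unname(aa123_map[res$aa])
  res3[is.na(res3)] <- "UNK"
  lines <- c(sprintf("REMARK   1 %s", model$name))
  serial <- 0L
  for (ch in unique(res$chain)) {
    rows <- which(res$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, res3[i], ch, res$resno[i],
        res$x[i], res$y[i], res$z[i], 1.0, b[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial, res3[rows[length(rows)]], ch,
                              res$resno[rows[length(rows)]]))
  }
  lines <- c(lines, "END")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
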