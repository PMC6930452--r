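#' Amino-acid intrinsic hydrophobicity scales
#'
#' The intrinsic hydrophobicity of a residue enters the observed
#' distribution O (as the interaction strength of each contact) and the
#' intrinsic reference distribution H. The packaged default is the
#' Kyte--Doolittle hydropathy scale rescaled linearly to \[0, 1\], so that
#' the most hydrophilic residue (Arg) carries 0 and the most hydrophobic
#' (Ile) carries 1. FOD conclusions are robust to the choice of scale;
#' any nonnegative per-residue scale can be substituted via
#' \code{load_scale()}.
#'
#' @param name Scale identifier. Currently only \code{"kd"}
#'   (Kyte--Doolittle, rescaled to \[0, 1\]).
#' @return Named numeric vector: one-letter amino-acid code to
#'   nonnegative hydrophobicity.
#' @examples
#' s <- hydro_scale()
#' s["I"]  # 1: most hydrophobic
#' s["R"]  # 0: most hydrophilic
#' @export
hydro_scale <- function(name = "kd") {
  name <- match.arg(name, "kd")
  path <- system.file("extdata", "scales", "kyte_doolittle.txt",
                      package = "oildrop", mustWork = TRUE)
  load_scale(path, normalize = TRUE)
}

#' Load a hydrophobicity scale from a two-column text file
#'
#' File format: whitespace-separated lines \code{<one-letter code> <value>};
#' lines starting with \code{#} are comments.
#'
#' @param path Path to the scale file.
#' @param normalize If \code{TRUE} (default) the values are rescaled
#'   linearly so the minimum maps to 0 and the maximum to 1. Raw scales
#'   with negative entries (e.g. hydropathy indices) must be normalized:
#'   intrinsic hydrophobicities are required to be nonnegative.
#' @return Named numeric vector keyed by one-letter code.
#' @export
load_scale <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("scale file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("aa", "value"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop("scale file is empty: ", path)
  if (anyDuplicated(tab$aa)) stop("duplicate amino-acid codes in scale: ", path)
  v <- stats::setNames(tab$value, toupper(tab$aa))
  if (normalize) {
    rng <- range(v)
    if (diff(rng) == 0) stop("constant scale cannot be normalized")
    v <- (v - rng[1]) / diff(rng)
  }
  if (any(v < 0)) stop("intrinsic hydrophobicities must be nonnegative; ",
                       "use normalize = TRUE for raw hydropathy scales")
  v
}

#' Look up intrinsic hydrophobicities for a sequence
#'
#' Codes absent from the scale (nonstandard residues) get 0 with a warning;
#' this keeps them in the geometry while excluding them from hydrophobic
#' weighting.
#'
#' @param aa Character vector of one-letter codes.
#' @param scale Named numeric vector as returned by [hydro_scale()].
#' @return Numeric vector of nonnegative hydrophobicities, same length.
#' @export
scale_lookup <- function(aa, scale = hydro_scale()) {
  v <- unname(scale[toupper(aa)])
  missing <- is.na(v)
  if (any(missing)) {
    warning("no scale entry for residue code(s) ",
            paste(unique(aa[missing]), collapse = ", "),
            "; assigned intrinsic hydrophobicity 0")
    v[missing] <- 0
  }
  v
}

# Residue types binned by scale tertile; used by the synthetic generators so
# that synthetic structures exercise the same scale machinery as real ones.
aa_classes <- function(scale = hydro_scale()) {
  ord <- names(sort(scale, decreasing = TRUE))
  n <- length(ord)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  list(hydrophobic = ord[seq_len(cut1)],
       neutral     = ord[seq(cut1 + 1L, cut2)],
       polar       = ord[seq(cut2 + 1L, n)])
}
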