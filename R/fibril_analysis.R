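#' Analyze one structural unit with the FOD model
#'
#' Resolves the selection, fits the Gaussian field on the field scope,
#' computes the theoretical (T) and observed (O) profiles over the field
#' scope, restricts them to the scored subset and renormalizes, builds the
#' intrinsic (H) and uniform (R) references on the subset, and derives the
#' two RD statistics, the three correlation coefficients, and per-residue
#' accordance categories. This is the per-row computation behind
#' chain/protofibril/superfibril comparison tables.
#'
#' @param model A [fod_structure] with effective positions.
#' @param spec A [selection_spec()] naming the analysis level.
#' @param kind Field kind: \code{"gauss3d"} (globular reference model) or
#'   \code{"gauss2d"} (ribbon-like micelle; fibril long axis suppressed).
#' @param scale Intrinsic hydrophobicity scale.
#' @param cutoff Hydrophobic interaction cutoff in Angstrom (default 9).
#' @param eliminate If \code{TRUE} and the unit is discordant
#'   (rd_tor >= 0.5), run [eliminate_discordant()] and attach the trace.
#' @param tau Accordance tolerance passed to [classify_residues()].
#' @return Object of class \code{fod_result}: \code{unit_label},
#'   \code{level}, \code{n_residues}, \code{scores} (rd_tor, rd_toh, hvt,
#'   tvo, hvo, dkl_ot, dkl_or, dkl_oh), \code{profiles} (per-residue
#'   data.frame with T, O, H, R and category), \code{field}, and
#'   optionally \code{removed}.
#' @export
analyze_unit <- function(model, spec, kind = c("gauss3d", "gauss2d"),
                         scale = hydro_scale(), cutoff = 9.0,
                         eliminate = FALSE, tau = NULL) {
  kind <- match.arg(kind)
  sel <- resolve_selection(model, spec)
  if (length(sel$subset) < 3L)
    stop("selection must score at least 3 residues")
  res <- model$residues
  scope_pos <- as.matrix(res[sel$field_scope, c("x", "y", "z")])
  sub_in_scope <- match(sel$subset, sel$field_scope)
  sub <- res[sel$subset, , drop = FALSE]
  keys <- res_keys(sub)

  field <- fit_field(scope_pos, kind)
  t_scope <- theoretical_profile(field, scope_pos)
  o_scope_raw <- observed_raw(scope_pos, res$h[sel$field_scope], cutoff)
  t_prof <- new_profile(as.numeric(t_scope)[sub_in_scope], keys, "T")
  o_prof <- new_profile(o_scope_raw[sub_in_scope], keys, "O")
  h_prof <- intrinsic_profile(sub$h, keys = keys)
  r_prof <- uniform_profile(nrow(sub), keys = keys)

  scores <- fod_scores(t_prof, o_prof, h_prof, r_prof)
  cats <- classify_residues(t_prof, o_prof, tau = tau)
  removed <- NULL
  if (eliminate && scores["rd_tor"] >= 0.5)
    removed <- eliminate_discordant(t_prof, o_prof, r_prof, keys = keys)

  profiles <- data.frame(chain = sub$chain, resno = sub$resno, aa = sub$aa,
                         T = as.numeric(t_prof), O = as.numeric(o_prof),
                         H = as.numeric(h_prof), R = as.numeric(r_prof),
                         category = cats, stringsAsFactors = FALSE)
  structure(list(unit_label = paste(model$name, spec$level, sep = " | "),
                 level = spec$level, n_residues = nrow(sub),
                 scores = scores, profiles = profiles, field = field,
                 removed = removed),
            class = "fod_result")
}

# all FOD summary statistics from the four aligned profiles
fod_scores <- function(t, o, h, r) {
  dkl_ot <- kl_divergence(o, t)
  dkl_or <- kl_divergence(o, r)
  dkl_oh <- kl_divergence(o, h)
  cors <- if (length(t) >= 3L) fod_correlations(h, t, o)
          else c(hvt = NA_real_, tvo = NA_real_, hvo = NA_real_)
  c(rd_tor = relative_distance(dkl_ot, dkl_or),
    rd_toh = relative_distance(dkl_ot, dkl_oh),
    cors,
    dkl_ot = dkl_ot, dkl_or = dkl_or, dkl_oh = dkl_oh)
}

#' @export
print.fod_result <- function(x, ...) {
  s <- x$scores
  cat("FOD analysis: ", x$unit_label, " (", x$field$kind, ", ",
      x$n_residues, " residues)\n", sep = "")
  cat(sprintf("  RD(T-O-R) = %.3f   RD(T-O-H) = %.3f   [%s]\n",
              s["rd_tor"], s["rd_toh"],
              if (s["rd_tor"] < 0.5) "hydrophobic core present"
              else "discordant with 3D Gaussian"))
  cat(sprintf("  HvT = %.3f   TvO = %.3f   HvO = %.3f\n",
              s["hvt"], s["tvo"], s["hvo"]))
  if (!is.null(x$removed))
    cat("  elimination: ", length(x$removed$removed), " residue(s) removed, ",
        sprintf("final RD = %.3f%s\n", x$removed$final_rd,
                if (x$removed$irreducible) " (irreducible)" else ""),
        sep = "")
  invisible(x)
}

#' Local FOD status of an inter-protofibril interface
#'
#' The Gaussian field and observed interactions are computed for the whole
#' complex; the profiles are then restricted to the interface residues and
#' renormalized. An interface whose local hydrophobicity follows the
#' complex-wide theoretical distribution (rd_tor < 0.5) is regarded as
#' stabilizing: its residues bury hydrophobicity consistently with a
#' shared core, which is what holds the protofibrils together.
#'
#' @param model A [fod_structure].
#' @param spec An \code{interface}-level [selection_spec()] (or a
#'   data.frame of \code{chain, resno} interface residues).
#' @param ... Passed to [analyze_unit()].
#' @return \code{fod_result} with additional element \code{stabilizing}
#'   (\code{TRUE} iff rd_tor < 0.5). Interfaces with fewer than 3 residues
#'   report RD but no correlations.
#' @export
analyze_interface <- function(model, spec, ...) {
  if (is.data.frame(spec)) spec <- selection_spec("interface", residues = spec)
  if (spec$level != "interface") stop("spec must have level 'interface'")
  sel <- resolve_selection(model, spec)
  if (length(sel$subset) < 3L) {
    # RD still defined; bypass the >= 3 residue gate used for correlations
    res <- model$residues
    scope_pos <- as.matrix(res[sel$field_scope, c("x", "y", "z")])
    sub_in_scope <- match(sel$subset, sel$field_scope)
    sub <- res[sel$subset, , drop = FALSE]
    keys <- res_keys(sub)
    field <- fit_field(scope_pos, "gauss3d")
    t_prof <- new_profile(
      as.numeric(theoretical_profile(field, scope_pos))[sub_in_scope],
      keys, "T")
    o_prof <- new_profile(
      observed_raw(scope_pos, res$h[sel$field_scope], 9.0)[sub_in_scope],
      keys, "O")
    h_prof <- intrinsic_profile(sub$h, keys = keys)
    r_prof <- uniform_profile(nrow(sub), keys = keys)
    out <- structure(list(unit_label = paste(model$name, "interface",
                                             sep = " | "),
                          level = "interface", n_residues = nrow(sub),
                          scores = fod_scores(t_prof, o_prof, h_prof, r_prof),
                          profiles = data.frame(
                            chain = sub$chain, resno = sub$resno, aa = sub$aa,
                            T = as.numeric(t_prof), O = as.numeric(o_prof),
                            H = as.numeric(h_prof), R = as.numeric(r_prof),
                            category = classify_residues(t_prof, o_prof),
                            stringsAsFactors = FALSE),
                          field = field, removed = NULL),
                     class = "fod_result")
  } else {
    out <- analyze_unit(model, spec, ...)
  }
  out$stabilizing <- unname(out$scores["rd_tor"] < 0.5)
  out
}

#' Comparative table across analysis units
#'
#' Assembles per-unit FOD scores into one table (sorted by unit label and
#' level) and, where a structure was analyzed both as a standalone chain
#' and as a chain in context, reports the RD deltas -- the change in
#' accordance a chain gains or loses from being embedded in the fibril.
#'
#' @param results List of \code{fod_result} objects.
#' @return data.frame with columns \code{unit, level, n, rd_tor, rd_toh,
#'   hvt, tvo, hvo}; per-structure chain-context deltas are attached as
#'   attribute \code{"deltas"}.
#' @export
comparative_table <- function(results) {
  if (length(results) == 0L) stop("no results to tabulate")
  rows <- lapply(results, function(r) {
    s <- r$scores
    data.frame(unit = r$unit_label, level = r$level, n = r$n_residues,
               rd_tor = unname(s["rd_tor"]), rd_toh = unname(s["rd_toh"]),
               hvt = unname(s["hvt"]), tvo = unname(s["tvo"]),
               hvo = unname(s["hvo"]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$structure <- sub(" \\| .*$", "", tab$unit)
  tab <- tab[order(tab$structure, tab$level), , drop = FALSE]
  rownames(tab) <- NULL

  deltas <- NULL
  for (st in unique(tab$structure)) {
    alone <- tab[tab$structure == st & tab$level == "chain_alone", ]
    ctx <- tab[tab$structure == st &
               tab$level %in% c("chain_in_protofibril",
                                "chain_in_superfibril"), ]
    if (nrow(alone) == 1L && nrow(ctx) >= 1L) {
      d <- data.frame(structure = st, context_level = ctx$level,
                      delta_rd_tor = ctx$rd_tor - alone$rd_tor,
                      stringsAsFactors = FALSE)
      deltas <- rbind(deltas, d)
    }
  }
  attr(tab, "deltas") <- deltas
  tab
}

#' Export per-residue profiles
#'
#' Writes the T/O/H/R profiles and accordance category of one analysis to
#' a tab-delimited file: the textual counterpart of an O-vs-T profile plot.
#'
#' @param result A \code{fod_result}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_profiles <- function(result, path) {
  stopifnot(inherits(result, "fod_result"))
  utils::write.table(result$profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
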