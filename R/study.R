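#' The amyloid validation set
#'
#' Definitions of the eight solid-state-NMR amyloid entries the FOD
#' multilevel analysis was developed on: amyloid name, PDB accession,
#' fibril composition (chains per protofibril x protofibrils per
#' superfibril), the amyloid-competent fragment where only part of the
#' chain fibrillizes, and the inter-protofibril interface residue numbers
#' (author numbering, applied to every chain of the complex).
#'
#' Structure files are not shipped; download the accessions yourself and
#' pass their directory to [reproduce_study()]. For 5O3T the interface is
#' asymmetric (residues 321 and 323 come from one protofibril, 313, 315
#' and 317 from its partner); the combined list is used here and can be
#' refined per chain via [selection_spec()].
#'
#' @return data.frame with one row per entry: \code{name, pdb_id,
#'   chain_length, n_chains_per_proto, n_protofibrils, fragment_start,
#'   fragment_end, interface} (comma-separated residue numbers).
#' @export
study_set <- function() {
  data.frame(
    name = c("Abeta(15-40) D23N", "Abeta(11-42)", "Abeta(1-40) E22D",
             "Abeta(11-42)", "TAU", "TAU", "TAU", "ASyn"),
    pdb_id = c("2MPZ", "2MXU", "2MVX", "5KK3", "5O3L", "5O3O", "5O3T",
               "2N0A"),
    chain_length = c(26L, 32L, 39L, 32L, 73L, 73L, 73L, 140L),
    n_chains_per_proto = c(9L, 12L, 5L, 9L, 5L, 5L, 5L, 10L),
    n_protofibrils = c(3L, 1L, 2L, 2L, 2L, 2L, 2L, 1L),
    fragment_start = c(NA, NA, NA, NA, NA, NA, NA, 30L),
    fragment_end = c(NA, NA, NA, NA, NA, NA, NA, 100L),
    interface = c("17,28,29,31,38,40",
                  "",
                  "3,4,13,28,29,30,37,38,39,40",
                  "11,13,15,17,34,35,36,37,38",
                  "331,332,333,334,335,336,338",
                  "331,332,333,334,335,336",
                  "321,323,313,315,317",
                  ""),
    stringsAsFactors = FALSE)
}

#' Run the multilevel FOD analysis on the amyloid validation set
#'
#' For every [study_set()] entry with a structure file present in
#' \code{dir} (\code{<pdb_id>.pdb} or \code{<pdb_id>.cif}, lowercase or
#' uppercase), loads the structure, groups its chains into protofibrils
#' by file order and the recorded composition, applies the
#' amyloid-competent fragment restriction where one is defined, and
#' computes FOD scores at chain-alone, chain-in-protofibril,
#' chain-in-superfibril (multi-protofibril entries), protofibril and
#' superfibril levels, plus the interface analysis where interface
#' residues are defined.
#'
#' @param dir Directory containing locally downloaded structure files.
#' @param entries Optional subset of PDB ids to analyze.
#' @param scale,cutoff Passed to [analyze_unit()].
#' @return List with \code{table} (comparative table across all units),
#'   \code{interface_table}, and \code{results}.
#' @export
reproduce_study <- function(dir, entries = NULL, scale = hydro_scale(),
                            cutoff = 9.0) {
  set <- study_set()
  if (!is.null(entries)) set <- set[set$pdb_id %in% entries, , drop = FALSE]
  files <- vapply(set$pdb_id, function(id) {
    cand <- file.path(dir, c(paste0(tolower(id), c(".pdb", ".cif")),
                             paste0(id, c(".pdb", ".cif"))))
    hit <- cand[file.exists(cand)]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  if (all(is.na(files)))
    stop("no structure files for ", paste(set$pdb_id, collapse = ", "),
         " found in '", dir, "'; download them first (not bundled)")
  results <- list(); iface <- list()
  for (i in which(!is.na(files))) {
    row <- set[i, ]
    model <- compute_effective_atoms(
      load_structure(files[i], scale = scale,
                     name = paste(row$name, row$pdb_id)))
    chains <- unique(model$residues$chain)
    npf <- row$n_protofibrils
    model$protofibrils <- split(chains,
                                ceiling(seq_along(chains) / row$n_chains_per_proto))
    frag <- if (!is.na(row$fragment_start))
      c(row$fragment_start, row$fragment_end)
    levels <- c("chain_alone", "chain_in_protofibril", "protofibril")
    if (npf > 1L) levels <- c(levels, "chain_in_superfibril", "superfibril")
    for (lv in levels) {
      results <- c(results, list(
        analyze_unit(model, selection_spec(lv, fragment = frag),
                     scale = scale, cutoff = cutoff)))
    }
    if (nzchar(row$interface)) {
      nums <- as.integer(strsplit(row$interface, ",")[[1]])
      resdf <- expand.grid(chain = chains, resno = nums,
                           stringsAsFactors = FALSE)
      have <- paste(model$residues$chain, model$residues$resno)
      resdf <- resdf[paste(resdf$chain, resdf$resno) %in% have, ]
      iface <- c(iface, list(
        analyze_interface(model,
                          selection_spec("interface", residues = resdf,
                                         fragment = frag),
                          scale = scale, cutoff = cutoff)))
    }
  }
  list(table = comparative_table(results),
       interface_table = if (length(iface)) comparative_table(iface),
       results = c(results, iface))
}
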