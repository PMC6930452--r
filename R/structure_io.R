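#' Structure container for FOD analysis
#'
#' A \code{fod_structure} holds an ordered table of residues, each reduced
#' (or reducible) to one effective atom, plus the chain partition and an
#' optional grouping of chains into protofibrils. It is the unit every
#' analysis level (chain, protofibril, superfibril, interface) operates on.
#'
#' @param residues data.frame with columns \code{chain} (character),
#'   \code{resno} (integer, author numbering), \code{aa} (one-letter code),
#'   \code{x,y,z} (effective-atom coordinates in Angstrom, may be \code{NA}
#'   until [compute_effective_atoms()] is called) and \code{h} (intrinsic
#'   hydrophobicity, nonnegative).
#' @param atoms Optional data.frame of the underlying heavy atoms
#'   (\code{chain, resno, x, y, z}), kept so effective positions can be
#'   (re)computed.
#' @param protofibrils Optional list of character vectors of chain ids,
#'   grouping chains into protofibrils. Groups must be disjoint. When
#'   \code{NULL}, all chains form a single protofibril.
#' @param name Label used in reports.
#' @return Object of class \code{fod_structure}.
#' @export
fod_structure <- function(residues, atoms = NULL, protofibrils = NULL,
                          name = "structure") {
  req <- c("chain", "resno", "aa", "x", "y", "z", "h")
  if (!is.data.frame(residues) || !all(req %in% names(residues)))
    stop("residues must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(residues) < 2L) stop("a structure needs at least 2 residues")
  if (any(residues$h < 0, na.rm = TRUE))
    stop("intrinsic hydrophobicities must be nonnegative")
  key <- paste(residues$chain, residues$resno)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno) residue keys: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  if (!is.null(protofibrils)) {
    all_ch <- unlist(protofibrils)
    if (anyDuplicated(all_ch))
      stop("protofibril groups must be disjoint")
    unknown <- setdiff(all_ch, residues$chain)
    if (length(unknown))
      stop("protofibril group names unknown chain(s): ",
           paste(unknown, collapse = ", "))
  } else {
    protofibrils <- list(unique(residues$chain))
  }
  rownames(residues) <- NULL
  structure(list(name = name, residues = residues, atoms = atoms,
                 protofibrils = protofibrils),
            class = "fod_structure")
}

#' @export
print.fod_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat("FOD structure '", x$name, "': ", nrow(x$residues), " residues, ",
      length(ch), " chain(s) [", paste(ch, collapse = " "), "], ",
      length(x$protofibrils), " protofibril group(s)\n", sep = "")
  invisible(x)
}

STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a protein structure from PDB or mmCIF
#'
#' Keeps polymer \code{ATOM} records of the first model only; waters,
#' heteroatoms and hydrogens are excluded and only the first alternate
#' location of each atom is kept. Residues are ordered by (chain, author
#' residue number). Effective-atom positions are not computed here; call
#' [compute_effective_atoms()] on the result.
#'
#' @param path Path to a structure file.
#' @param format \code{"pdb"}, \code{"cif"} or \code{"auto"} (default;
#'   decided by file extension, falling back to PDB).
#' @param scale Hydrophobicity scale used to annotate residues,
#'   see [hydro_scale()].
#' @param name Structure label; defaults to the file name.
#' @return A [fod_structure] whose residue coordinates are \code{NA} until
#'   effective atoms are computed.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"),
                           scale = hydro_scale(), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, multi = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  keep <- at$type == "ATOM" &
    !(at$resid %in% c("HOH", "WAT", "DOD")) &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    !(!is.na(at$elesy) & at$elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no standard polymer residues in '", path,
         "' (only HETATM/water records?)", call. = FALSE)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))

  rkey <- paste(at$chain, at$resno)
  first <- !duplicated(rkey)
  res <- data.frame(chain = at$chain[first],
                    resno = at$resno[first],
                    aa = aa1[first],
                    stringsAsFactors = FALSE)
  ord <- order(res$chain, res$resno)
  res <- res[ord, , drop = FALSE]
  nonstd <- !(res$aa %in% STANDARD_AA)
  if (any(nonstd)) {
    warning(sum(nonstd), " nonstandard residue(s) flagged 'X' with ",
            "intrinsic hydrophobicity 0")
    res$aa[nonstd] <- "X"
  }
  res$x <- NA_real_; res$y <- NA_real_; res$z <- NA_real_
  res$h <- scale_lookup2(res$aa, scale)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  fod_structure(res, atoms = atoms,
                name = name %||% basename(path))
}

# scale_lookup without the nonstandard-code warning spam (already warned once)
scale_lookup2 <- function(aa, scale) {
  v <- unname(scale[toupper(aa)])
  v[is.na(v)] <- 0
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce each residue to its effective atom
#'
#' The effective atom is the unweighted arithmetic mean of all heavy-atom
#' positions of the residue (hydrogens were already excluded at load time;
#' NMR entries would otherwise shift centroids relative to X-ray entries).
#' Residues with no atoms are dropped with a warning.
#'
#' @param model A [fod_structure] carrying an atom table (from
#'   [load_structure()]).
#' @return The model with \code{x,y,z} filled in for every residue.
#' @export
compute_effective_atoms <- function(model) {
  stopifnot(inherits(model, "fod_structure"))
  if (is.null(model$atoms))
    stop("model carries no atom table; effective atoms cannot be computed")
  at <- model$atoms
  akey <- paste(at$chain, at$resno)
  rkey <- paste(model$residues$chain, model$residues$resno)
  cx <- tapply(at$x, akey, mean)
  cy <- tapply(at$y, akey, mean)
  cz <- tapply(at$z, akey, mean)
  hit <- rkey %in% names(cx)
  if (!all(hit)) {
    warning(sum(!hit), " residue(s) without atoms dropped")
    model$residues <- model$residues[hit, , drop = FALSE]
    rkey <- rkey[hit]
  }
  model$residues$x <- as.numeric(cx[rkey])
  model$residues$y <- as.numeric(cy[rkey])
  model$residues$z <- as.numeric(cz[rkey])
  if (any(!is.finite(as.matrix(model$residues[, c("x", "y", "z")]))))
    stop("non-finite effective-atom coordinates")
  rownames(model$residues) <- NULL
  model
}

#' Define an analysis selection
#'
#' A selection names the structural level at which FOD status is evaluated
#' and, where relevant, which chains/residues participate. Two residue sets
#' result (see [resolve_selection()]): the \emph{subset} whose status is
#' scored, and the \emph{field scope} that defines the Gaussian field and
#' the observed interactions. A chain analyzed "in context" is scored
#' against the field of the whole fibril it belongs to.
#'
#' @param level One of \code{"chain_alone"}, \code{"chain_in_protofibril"},
#'   \code{"chain_in_superfibril"}, \code{"protofibril"},
#'   \code{"superfibril"}, \code{"interface"}.
#' @param chains Optional chain ids. For chain levels, the chain to score
#'   (when omitted at in-context levels, the centrally located chain along
#'   the fibril axis is used); for \code{protofibril}, the chains of the
#'   protofibril (when omitted, the model's first protofibril group).
#' @param residues Optional data.frame \code{(chain, resno)} of residue
#'   keys; required (nonempty) for \code{level = "interface"}.
#' @param fragment Optional length-2 integer vector \code{c(start, end)}
#'   restricting every set to author residue numbers in that interval
#'   (e.g. the amyloid-competent 30--100 fragment of alpha-synuclein).
#' @return Object of class \code{fod_selection}.
#' @export
selection_spec <- function(level, chains = NULL, residues = NULL,
                           fragment = NULL) {
  level <- match.arg(level, c("chain_alone", "chain_in_protofibril",
                              "chain_in_superfibril", "protofibril",
                              "superfibril", "interface"))
  if (level == "interface" && (is.null(residues) || nrow(residues) == 0L))
    stop("interface selection requires a nonempty residue list")
  if (!is.null(residues) &&
      !all(c("chain", "resno") %in% names(residues)))
    stop("residues must be a data.frame with columns chain, resno")
  if (!is.null(fragment)) {
    if (length(fragment) != 2L || fragment[1] > fragment[2])
      stop("fragment must be c(start, end) with start <= end")
  }
  structure(list(level = level, chains = chains, residues = residues,
                 fragment = fragment), class = "fod_selection")
}

#' Resolve a selection into scored and field-defining residue sets
#'
#' @param model A [fod_structure] with effective positions computed.
#' @param spec A [selection_spec()].
#' @return List with integer index vectors \code{subset} (residues whose
#'   status is evaluated) and \code{field_scope} (residues defining the
#'   Gaussian field and observed interactions); \code{subset} is always
#'   contained in \code{field_scope}.
#' @details The centrally located chain of a fibril is the median chain of
#'   the stacking order, obtained by sorting chain centroids along the
#'   first principal axis of the field scope (ties break toward the lower
#'   index). For even chain counts the lower middle is taken.
#' @export
resolve_selection <- function(model, spec) {
  stopifnot(inherits(model, "fod_structure"), inherits(spec, "fod_selection"))
  res <- model$residues
  if (anyNA(res$x))
    stop("effective positions missing; run compute_effective_atoms() first")
  in_frag <- if (is.null(spec$fragment)) rep(TRUE, nrow(res))
             else res$resno >= spec$fragment[1] & res$resno <= spec$fragment[2]
  if (!any(in_frag)) stop("fragment range selects no residues")
  if (!is.null(spec$chains)) {
    unknown <- setdiff(spec$chains, res$chain)
    if (length(unknown))
      stop("unknown chain(s): ", paste(unknown, collapse = ", "))
  }
  all_idx <- which(in_frag)

  pick_chain_idx <- function(chains) which(res$chain %in% chains & in_frag)

  out <- switch(spec$level,
    chain_alone = {
      ch <- spec$chains %||% unique(res$chain)[1]
      idx <- pick_chain_idx(ch)
      list(subset = idx, field_scope = idx)
    },
    chain_in_protofibril = {
      grp <- proto_group_for(model, spec$chains)
      scope <- pick_chain_idx(grp)
      ch <- spec$chains %||% central_chain(res[scope, ], grp)
      list(subset = pick_chain_idx(ch), field_scope = scope)
    },
    chain_in_superfibril = {
      scope <- all_idx
      ch <- spec$chains %||%
        central_chain(res[scope, ], unique(res$chain[scope]))
      list(subset = pick_chain_idx(ch), field_scope = scope)
    },
    protofibril = {
      grp <- if (!is.null(spec$chains)) spec$chains
             else proto_group_for(model, NULL)
      idx <- pick_chain_idx(grp)
      list(subset = idx, field_scope = idx)
    },
    superfibril = list(subset = all_idx, field_scope = all_idx),
    interface = {
      want <- paste(spec$residues$chain, spec$residues$resno)
      have <- paste(res$chain, res$resno)
      missing <- setdiff(want, have[in_frag])
      if (length(missing))
        stop("interface residues not in structure: ",
             paste(missing, collapse = "; "))
      list(subset = which(have %in% want & in_frag), field_scope = all_idx)
    })
  if (length(out$subset) == 0L) stop("selection resolves to no residues")
  out
}

# protofibril group containing the named chain(s), or the first group
proto_group_for <- function(model, chains) {
  if (is.null(chains)) return(model$protofibrils[[1]])
  hit <- vapply(model$protofibrils, function(g) any(chains %in% g), logical(1))
  if (!any(hit)) stop("chain(s) ", paste(chains, collapse = ", "),
                      " not in any protofibril group")
  model$protofibrils[[which(hit)[1]]]
}

# median chain of the stacking order along the first principal axis
central_chain <- function(res, chains) {
  if (length(chains) == 1L) return(chains)
  pos <- as.matrix(res[, c("x", "y", "z")])
  ctr <- sweep(pos, 2, colMeans(pos))
  ax <- eigen(crossprod(ctr) / (nrow(ctr) - 1), symmetric = TRUE)$vectors[, 1]
  proj <- vapply(chains, function(ch) {
    mean(ctr[res$chain == ch, , drop = FALSE] %*% ax)
  }, numeric(1))
  ord <- chains[order(proj, match(chains, chains))]
  ord[(length(ord) + 1L) %/% 2L]
}

#' Read a selection configuration file
#'
#' YAML with keys \code{level}, optional \code{chains} (list), optional
#' \code{interface} (list of \code{"chain:resno"} strings), optional
#' \code{fragment} (\code{[start, end]}).
#'
#' @param path YAML file path.
#' @return A [selection_spec()].
#' @export
read_selection <- function(path) {
  cfg <- yaml::read_yaml(path)
  residues <- NULL
  if (!is.null(cfg$interface)) {
    parts <- strsplit(as.character(cfg$interface), ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("interface entries must be 'chain:resno': ",
                       paste(cfg$interface[bad], collapse = ", "))
    residues <- data.frame(
      chain = vapply(parts, `[`, "", 1L),
      resno = as.integer(vapply(parts, `[`, "", 2L)),
      stringsAsFactors = FALSE)
  }
  selection_spec(level = cfg$level,
                 chains = if (!is.null(cfg$chains)) as.character(cfg$chains),
                 residues = residues,
                 fragment = if (!is.null(cfg$fragment))
                   as.integer(cfg$fragment))
}
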