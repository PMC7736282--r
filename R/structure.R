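#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records into a flat atom table.
#' Waters and other heteroatoms are excluded by default, as are hydrogens
#' and alternate locations other than blank/"A" -- the conventions used when
#' analysing crystal structures, which usually carry no hydrogens.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier(s) to keep.
#' @param include_hetatm Keep HETATM records (waters are still dropped unless
#'   `include_water = TRUE`).
#' @param include_water Keep water molecules (HOH/WAT).
#' @param include_hydrogens Keep hydrogen atoms.
#' @return An object of class `varsite_structure`: a data frame with one row
#'   per atom and columns `atom_name`, `element`, `res_name`, `res_no`,
#'   `chain`, `x`, `y`, `z` (coordinates in Angstrom) and `sidechain`
#'   (logical, `TRUE` for non-backbone heavy atoms of amino-acid residues).
#' @export
read_structure <- function(path, chain = NULL, include_hetatm = FALSE,
                           include_water = FALSE, include_hydrogens = FALSE) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!include_hetatm) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  }
  if (!include_water) {
    at <- at[!(at$resid %in% c("HOH", "WAT", "H2O")), , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("no ATOM records found in '", path, "'")
  }
  # altloc: keep blank or "A"
  at <- at[at$alt %in% c("", "A", NA), , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0L) {
      stop("no atoms found for chain(s) ", paste(chain, collapse = ", "))
    }
  }
  elem <- at$elesy
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem)) {
    elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
  }
  if (!include_hydrogens) {
    keep <- toupper(elem) != "H"
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  out <- data.frame(
    atom_name = at$elety,
    element = toupper(elem),
    res_name = at$resid,
    res_no = as.integer(at$resno),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("non-finite coordinates in '", path, "'")
  }
  out$sidechain <- is_sidechain_atom(out$atom_name, out$element)
  class(out) <- c("varsite_structure", "data.frame")
  attr(out, "source") <- path
  out
}

# Backbone heavy-atom names; everything else heavy in an amino acid is
# side chain (CB and beyond).
is_sidechain_atom <- function(atom_name, element) {
  backbone <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  !(atom_name %in% backbone) & toupper(element) != "H"
}

residue_key <- function(chain, res_no) paste0(chain, ":", res_no)

#' Residues with side-chain atoms near a focal selection
#'
#' Finds residues having at least one side-chain heavy atom within `cutoff`
#' Angstrom of any atom in the focal selection. The focal selection is either
#' every side-chain heavy atom of the focal residue (default) or one named
#' atom of it (e.g. `"NZ"`, the terminal amine of a lysine). Sequence
#' neighbours are not excluded. The focal residue itself never appears in the
#' result, and the result is monotone non-decreasing in `cutoff`.
#'
#' @param structure A `varsite_structure`.
#' @param res_no Residue number of the focal residue.
#' @param chain Chain of the focal residue (default first chain present).
#' @param cutoff Distance cutoff in Angstrom (>= 0).
#' @param focal_atom Either `"sidechain"` (all side-chain heavy atoms) or a
#'   single atom name such as `"NZ"`.
#' @return A data frame of class `varsite_neighbors` with columns `res_no`,
#'   `chain`, `res_name`, `min_distance` (Angstrom), ordered by distance.
#' @export
sidechain_neighbors <- function(structure, res_no, chain = NULL, cutoff = 4.0,
                                focal_atom = "sidechain") {
  stopifnot(inherits(structure, "varsite_structure"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0) {
    stop("cutoff must be a single non-negative number")
  }
  if (is.null(chain)) chain <- structure$chain[1L]
  focal <- structure[structure$res_no == res_no & structure$chain == chain, ,
                     drop = FALSE]
  if (nrow(focal) == 0L) {
    stop("focal residue ", res_no, " (chain ", chain, ") not found")
  }
  if (identical(focal_atom, "sidechain")) {
    focal <- focal[focal$sidechain, , drop = FALSE]
    if (nrow(focal) == 0L) {
      stop("focal residue ", res_no, " (", focal$res_name[1],
           ") has no side-chain heavy atoms")
    }
  } else {
    focal <- focal[focal$atom_name == focal_atom, , drop = FALSE]
    if (nrow(focal) == 0L) {
      stop("focal residue ", res_no, " has no atom named '", focal_atom, "'")
    }
  }
  cand <- structure[structure$sidechain &
                      !(structure$res_no == res_no & structure$chain == chain), ,
                    drop = FALSE]
  if (nrow(cand) == 0L) {
    return(empty_neighbors(res_no, chain, cutoff, focal_atom))
  }
  fm <- as.matrix(focal[, c("x", "y", "z")])
  cm <- as.matrix(cand[, c("x", "y", "z")])
  # min distance from each candidate atom to the focal selection
  d2 <- outer(rowSums(cm^2), rowSums(fm^2), "+") - 2 * cm %*% t(fm)
  dmin_atom <- sqrt(pmax(apply(d2, 1L, min), 0))
  key <- residue_key(cand$chain, cand$res_no)
  dmin <- tapply(dmin_atom, key, min)
  first <- !duplicated(key)
  info <- cand[first, c("res_no", "chain", "res_name")]
  info$min_distance <- as.numeric(dmin[residue_key(info$chain, info$res_no)])
  out <- info[info$min_distance <= cutoff, , drop = FALSE]
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  as_neighbors(out, res_no, chain, cutoff, focal_atom)
}

empty_neighbors <- function(res_no, chain, cutoff, focal_atom) {
  out <- data.frame(res_no = integer(), chain = character(),
                    res_name = character(), min_distance = numeric(),
                    stringsAsFactors = FALSE)
  as_neighbors(out, res_no, chain, cutoff, focal_atom)
}

as_neighbors <- function(out, res_no, chain, cutoff, focal_atom) {
  class(out) <- c("varsite_neighbors", "data.frame")
  attr(out, "focal_res") <- res_no
  attr(out, "focal_chain") <- chain
  attr(out, "cutoff") <- cutoff
  attr(out, "focal_atom") <- focal_atom
  out
}

#' Assign residues to shells around a catalytic focal residue
#'
#' Shell 1 contains residues with a side-chain heavy atom within
#' `first_cutoff` Angstrom of the focal residue's side chain. Shell 3
#' contains residues whose nearest side-chain heavy atom to the focal
#' reference atom (`"NZ"` for lysine) lies beyond `third_min` Angstrom.
#' Shell 2 is, by default, the distance band between the two criteria
#' (`second = "band"`); an alternative graph-expansion definition
#' (`second = "graph"`: side-chain contacts of shell-1 residues at
#' `first_cutoff`, excluding shell 1) is also available, and the variant used
#' is recorded in the result. Shells are disjoint (precedence 1 > 2 > 3) and
#' never include the focal residue.
#'
#' @param structure A `varsite_structure`.
#' @param res_no Focal residue number.
#' @param chain Focal chain (default first chain present).
#' @param first_cutoff Shell-1 cutoff in Angstrom (default 4).
#' @param third_min Minimum distance (Angstrom) from the reference atom for
#'   shell 3 (default 6).
#' @param reference_atom Atom of the focal residue used for the shell-2/3
#'   distance criterion; defaults to `"NZ"` for lysine and to the whole side
#'   chain otherwise.
#' @param second Shell-2 definition, `"band"` or `"graph"`.
#' @return A data frame of class `varsite_shells` with columns `res_no`,
#'   `chain`, `res_name`, `shell` (1, 2 or 3) and `min_distance` (Angstrom,
#'   to the reference selection).
#' @export
assign_shells <- function(structure, res_no, chain = NULL,
                          first_cutoff = 4.0, third_min = 6.0,
                          reference_atom = NULL,
                          second = c("band", "graph")) {
  stopifnot(inherits(structure, "varsite_structure"))
  second <- match.arg(second)
  if (is.null(chain)) chain <- structure$chain[1L]
  focal <- structure[structure$res_no == res_no & structure$chain == chain, ,
                     drop = FALSE]
  if (nrow(focal) == 0L) {
    stop("focal residue ", res_no, " (chain ", chain, ") not found")
  }
  if (is.null(reference_atom)) {
    reference_atom <- if (focal$res_name[1] == "LYS" &&
                          "NZ" %in% focal$atom_name) "NZ" else "sidechain"
  }
  shell1 <- sidechain_neighbors(structure, res_no, chain,
                                cutoff = first_cutoff,
                                focal_atom = "sidechain")
  # distances of every residue's nearest side-chain heavy atom to the
  # reference selection
  all_res <- sidechain_neighbors(structure, res_no, chain, cutoff = Inf,
                                 focal_atom = reference_atom)
  k1 <- residue_key(shell1$chain, shell1$res_no)
  kall <- residue_key(all_res$chain, all_res$res_no)
  if (second == "band") {
    # every non-shell-1 residue falls in the 2/3 distance band split
    shell <- ifelse(kall %in% k1, 1L,
                    ifelse(all_res$min_distance > third_min, 3L, 2L))
  } else {
    # graph expansion: shell 2 = side-chain contacts of shell-1 residues;
    # residues matching no criterion are left unassigned (NA)
    expand <- character()
    for (i in seq_len(nrow(shell1))) {
      nb <- sidechain_neighbors(structure, shell1$res_no[i], shell1$chain[i],
                                cutoff = first_cutoff,
                                focal_atom = "sidechain")
      expand <- union(expand, residue_key(nb$chain, nb$res_no))
    }
    expand <- setdiff(expand, c(k1, residue_key(chain, res_no)))
    shell <- rep(NA_integer_, nrow(all_res))
    shell[kall %in% k1] <- 1L
    shell[is.na(shell) & kall %in% expand] <- 2L
    shell[is.na(shell) & all_res$min_distance > third_min] <- 3L
  }
  out <- data.frame(res_no = all_res$res_no, chain = all_res$chain,
                    res_name = all_res$res_name, shell = shell,
                    min_distance = all_res$min_distance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$shell, out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("varsite_shells", "data.frame")
  attr(out, "focal_res") <- res_no
  attr(out, "focal_chain") <- chain
  attr(out, "first_cutoff") <- first_cutoff
  attr(out, "third_min") <- third_min
  attr(out, "reference_atom") <- reference_atom
  attr(out, "second") <- second
  out
}

#' @export
print.varsite_shells <- function(x, ...) {
  cat("Shell assignment around residue", attr(x, "focal_res"),
      "(chain", paste0(attr(x, "focal_chain"), ")"),
      "| shell-2 mode:", attr(x, "second"), "\n")
  for (s in 1:3) {
    m <- x[x$shell == s, , drop = FALSE]
    cat(sprintf("  shell %d (%d residues): %s\n", s, nrow(m),
                paste(paste0(m$res_name, m$res_no), collapse = ", ")))
  }
  invisible(x)
}

#' Write a shell assignment to CSV
#'
#' @param shells A `varsite_shells` object.
#' @param path Output CSV path.
#' @export
write_shells_csv <- function(shells, path) {
  stopifnot(inherits(shells, "varsite_shells"))
  df <- as.data.frame(shells)
  names(df)[names(df) == "min_distance"] <- "min_distance_A"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
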