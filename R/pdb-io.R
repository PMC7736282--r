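# Fixed-width PDB ATOM record (columns per the wwPDB format v3.3).
pdb_atom_line <- function(serial, name, res_name, chain, res_no,
                          x, y, z, element, occupancy = 1, b = 0) {
  name_field <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, res_name, chain, res_no, x, y, z,
          occupancy, b, element)
}

pdb_atom_block <- function(atoms, xyz_ang) {
  vapply(seq_len(nrow(atoms)), function(i) {
    pdb_atom_line(i, atoms$atom_name[i], atoms$res_name[i], atoms$chain[i],
                  atoms$res_no[i], xyz_ang[i, 1], xyz_ang[i, 2], xyz_ang[i, 3],
                  atoms$element[i])
  }, character(1))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL record; coordinates are written in Angstrom
#' (internal nanometre coordinates are multiplied by 10), the unit every PDB
#' reader expects.
#'
#' @param trajectory A `varsite_trajectory`.
#' @param path Output path for the multi-model PDB; a single-model topology
#'   PDB is written alongside when `topology_path` is given.
#' @param topology_path Optional path for a topology PDB (frame 1).
#' @export
write_trajectory_pdb <- function(trajectory, path, topology_path = NULL) {
  stopifnot(inherits(trajectory, "varsite_trajectory"))
  atoms <- trajectory$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(pdb_atom_block(atoms, trajectory$coords[, , f] * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(topology_path)) {
    writeLines(c(pdb_atom_block(atoms, trajectory$coords[, , 1] * 10), "END"),
               topology_path)
  }
  invisible(path)
}
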