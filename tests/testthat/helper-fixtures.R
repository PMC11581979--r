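# shared in-code fixtures; everything is generated, nothing read from disk

# minimal PDB text: protein CA atoms at given coordinates plus one ligand
writeToyPdb <- function(path, residues, ligand) {
  lines <- character()
  serial <- 1L
  for (i in seq_len(nrow(residues))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, residues$resno[i], residues$x[i], residues$y[i], residues$z[i]))
    serial <- serial + 1L
  }
  for (i in seq_len(nrow(ligand))) {
    lines <- c(lines, sprintf(
      "HETATM%5d  C%d  LIG A %3d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, 900L, ligand$x[i], ligand$y[i], ligand$z[i]))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  path
}

# small deterministic cassette for oligo tests
toyCassette <- function(len = 60L, seed = 42L) {
  genParentCassette(length = len, seed = seed, flankLen = 12L)
}

# hand-built landscape with purely additive effects
additiveLandscape <- function(parentSeq, effects) {
  # effects: named numeric, names like "K50Q"
  m <- parseMutations(names(effects))
  epistaticLandscape(parentSeq,
                     additive = data.frame(position = m$position, aa = m$mut_aa,
                                           effect = unname(effects)))
}
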