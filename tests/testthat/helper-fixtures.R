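# Small structures built in code and reused across tests.

toy_topology <- function(n, name = "CA", resname = "ALA", element = "C") {
  topology(data.frame(
    serial = seq_len(n), name = name, element = element,
    residue_name = resname, residue_number = seq_len(n), chain = "A",
    het = FALSE, stringsAsFactors = FALSE))
}

# non-degenerate 4-atom structure
tetra_coords <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.4, 1.2, 0.1), c(0.2, 0.3, 1.7))
}

# a 5-model PDB written in code (2 residues, one HETATM)
write_test_pdb <- function(path, n_models = 1, perturb = 0) {
  lines <- character(0)
  base <- rbind(c(1.234, 2.345, 3.456), c(4.0, 5.5, 6.25), c(0.5, -1.5, 2.0))
  for (m in seq_len(n_models)) {
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- base + (m - 1) * perturb
    lines <- c(lines,
      sprintf("ATOM  %5d  N   ALA A  12    %8.3f%8.3f%8.3f  1.00  0.00           N",
              1, xyz[1, 1], xyz[1, 2], xyz[1, 3]),
      sprintf("ATOM  %5d  CA  ALA A  12    %8.3f%8.3f%8.3f  1.00  0.00           C",
              2, xyz[2, 1], xyz[2, 2], xyz[2, 3]),
      sprintf("HETATM%5d MG    MG A 201    %8.3f%8.3f%8.3f  1.00  0.00          MG",
              3, xyz[3, 1], xyz[3, 2], xyz[3, 3]))
    if (n_models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# trajectory with explicit per-frame coordinate list (list of N x 3)
traj_from_frames <- function(topo, frames) {
  trajectory(topo, do.call(rbind, lapply(frames, function(m) as.vector(t(m)))))
}
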