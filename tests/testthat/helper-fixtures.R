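# Shared fixtures: tiny hand-written PDB files, random rotations, and
# small models.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a tiny syntactically valid PDB with the given atom rows
write_pdb_lines <- function(rows, path = tempfile(fileext = ".pdb")) {
  writeLines(c(rows, "END"), path)
  path
}

pdb_atom <- function(serial, name, res, chain, resno, x, y, z,
                     occ = 1.00, alt = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, res, chain, resno, x, y, z, occ, 0.00, element)
}

# three complete residues on chain A
three_residue_pdb <- function() {
  rows <- c(
    pdb_atom(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom(2, "CA", "ALA", "A", 1, 1.46, 0.0, 0.0),
    pdb_atom(3, "C", "ALA", "A", 1, 2.0, 1.4, 0.0),
    pdb_atom(4, "N", "GLY", "A", 2, 3.3, 1.5, 0.2),
    pdb_atom(5, "CA", "GLY", "A", 2, 4.3, 2.5, 0.3),
    pdb_atom(6, "C", "GLY", "A", 2, 5.3, 3.0, 0.1),
    pdb_atom(7, "N", "SER", "A", 3, 6.5, 3.6, 0.5),
    pdb_atom(8, "CA", "SER", "A", 3, 7.5, 4.5, 0.4),
    pdb_atom(9, "C", "SER", "A", 3, 8.6, 5.0, 0.9))
  write_pdb_lines(rows)
}

# default small fixture used across model tests
fixture_backbone <- function(seed = 2, jitter = 0.2) {
  synthetic_backbone(list(c("helix", 14), c("strand", 8), c("coil", 8)),
                     seed = seed, jitter = jitter)
}

small_model <- function(g, n_terms = 2, seed = 7) {
  gvp_model(node_scalar_dim = ncol(g$node_scalar),
            edge_scalar_dim = ncol(g$edge_scalar), n_terms = n_terms,
            hidden_s = 12, hidden_v = 4, n_layers = 2, msg_depth = 2,
            edge_v = 2, collapse_dim = 8, n_super = 4, n_heads = 2,
            seed = seed)
}

# independent two-plane dihedral oracle (normals + signed angle)
dihedral_oracle <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ang <- acos(pmin(pmax(sum(n1 * n2) /
                          sqrt(sum(n1^2) * sum(n2^2)), -1), 1))
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}
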