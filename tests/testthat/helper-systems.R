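# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

toy_system <- function() {
  if (is.null(.cache$toy)) .cache$toy <- build_toy_pic(seed = 1)
  .cache$toy
}

small_duplex <- function() {
  if (is.null(.cache$dna)) .cache$dna <- build_bdna("ACGTACGTAC")
  .cache$dna
}

# a minimal all-atom PDB text fixture (two protein residues: GLY, ALA)
write_two_residue_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   2.500   3.200  1.00  0.00           C",
    "ATOM      4  N   ALA A   2       3.000   2.800   3.500  1.00  0.00           N",
    "ATOM      5  CA  ALA A   2       4.000   3.100   4.000  1.00  0.00           C",
    "ATOM      6  C   ALA A   2       5.000   3.400   4.400  1.00  0.00           C",
    "END"), path)
  path
}

# one DNA nucleotide with phosphate, sugar and base groups
write_nucleotide_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  P    DA T   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  OP1  DA T   1       1.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  OP2  DA T   1       0.000   1.000   0.000  1.00  0.00           O",
    "ATOM      4  O5'  DA T   1       0.000   0.000   1.000  1.00  0.00           O",
    "ATOM      5  C5'  DA T   1       1.500   1.500   1.500  1.00  0.00           C",
    "ATOM      6  C4'  DA T   1       2.000   2.000   2.000  1.00  0.00           C",
    "ATOM      7  C3'  DA T   1       2.500   2.000   2.500  1.00  0.00           C",
    "ATOM      8  C2'  DA T   1       3.000   2.500   2.500  1.00  0.00           C",
    "ATOM      9  C1'  DA T   1       3.500   3.000   3.000  1.00  0.00           C",
    "ATOM     10  O4'  DA T   1       2.500   3.000   2.000  1.00  0.00           O",
    "ATOM     11  N9   DA T   1       4.500   3.500   3.500  1.00  0.00           N",
    "ATOM     12  C8   DA T   1       5.000   4.000   4.000  1.00  0.00           C",
    "ATOM     13  N7   DA T   1       5.500   4.500   4.000  1.00  0.00           N",
    "ATOM     14  C5   DA T   1       5.500   4.500   5.000  1.00  0.00           C",
    "ATOM     15  C6   DA T   1       6.000   5.000   5.500  1.00  0.00           C",
    "ATOM     16  N1   DA T   1       6.000   5.000   6.500  1.00  0.00           N",
    "ATOM     17  C2   DA T   1       5.500   4.500   7.000  1.00  0.00           C",
    "ATOM     18  N3   DA T   1       5.000   4.000   6.500  1.00  0.00           N",
    "ATOM     19  C4   DA T   1       5.000   4.000   5.500  1.00  0.00           C",
    "END"), path)
  path
}

# altloc fixture: CA with A (occupancy 0.7) and B (0.3)
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       1.000   2.000   3.000  0.70  0.00           C",
    "ATOM      3  CA BGLY A   1       9.000   9.000   9.000  0.30  0.00           C",
    "ATOM      4  C   GLY A   1       2.000   2.500   3.200  1.00  0.00           C",
    "ATOM      5  N   ALA A   2       3.000   2.800   3.500  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       4.000   3.100   4.000  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       5.000   3.400   4.400  1.00  0.00           C",
    "END"), path)
  path
}

# a random protein+DNA cg_topology for contact-detection oracles
random_cg_instance <- function(n_prot, n_dna_res, seed, spread = 15) {
  set.seed(seed)
  nb <- n_prot + 3 * n_dna_res
  beads <- data.frame(
    bead_id = seq_len(nb),
    chain_id = c(rep("A", n_prot), rep("T", 3 * n_dna_res)),
    residue_index = c(seq_len(n_prot), rep(seq_len(n_dna_res), each = 3)),
    kind = c(rep("CA", n_prot), rep(c("P", "S", "B"), n_dna_res)),
    identity = c(sample(c("A", "K", "L"), n_prot, TRUE),
                 rep(sample(c("A", "C", "G", "T"), n_dna_res, TRUE), each = 3)),
    stringsAsFactors = FALSE)
  coords <- matrix(runif(nb * 3, 0, spread), nb, 3)
  cg_topology(beads, coords,
              chain_table = data.frame(chain_id = c("A", "T"),
                                       role = c("protein", "template"),
                                       stringsAsFactors = FALSE))
}
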