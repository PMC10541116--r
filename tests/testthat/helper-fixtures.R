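# Small in-code fixtures shared across test files.

# Quick record table builder: recs("A",10,"B",20, score=50) etc.
recs <- function(pa, ra, pb, rb, score = 50, fdr = 0.005,
                 dataset_id = "XL1", spectral_count = 1L) {
  xl_records(pa, ra, pb, rb, score = score, fdr = fdr,
             dataset_id = dataset_id, spectral_count = spectral_count)
}

# Structure from a coordinate matrix: one chain, author numbers 1..n
# (or as given), glycine sequence.
struct_from_coords <- function(coords, chain = "A", id = "TEST",
                               author_numbers = NULL, aa = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(author_numbers)) author_numbers <- seq_len(n)
  if (is.null(aa)) aa <- rep("G", n)
  xl_structure(id, data.frame(
    chain = chain, author_number = author_numbers, icode = "",
    aa = aa, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

merge_structures <- function(id, ...) {
  xl_structure(id, do.call(rbind, lapply(list(...), function(s) s$residues)))
}

# Three-residue PDB fragment with an altloc pair and a residue gap,
# plus the equivalent mmCIF content.
write_pdb_fragment <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A  10       0.500   1.000   2.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A  12       4.000   5.000   6.000  0.40  0.00           C",
    "ATOM      4  CA BGLY A  12       4.500   5.500   6.500  0.60  0.00           C",
    "ATOM      5  CA  SER A  13       7.000   8.000   9.000  1.00  0.00           C",
    "ATOM      6  CB  SER A  13       7.500   8.500   9.500  1.00  0.00           C",
    "END"), path)
  path
}

write_cif_fragment <- function(path) {
  writeLines(c(
    "data_frag",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 10 ? 0.500 1.000 2.000 1.00 0.00 ? 10 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 10 ? 1.000 2.000 3.000 1.00 0.00 ? 10 ALA A CA 1",
    "ATOM 3 C CA A GLY A 1 12 ? 4.000 5.000 6.000 0.40 0.00 ? 12 GLY A CA 1",
    "ATOM 4 C CA B GLY A 1 12 ? 4.500 5.500 6.500 0.60 0.00 ? 12 GLY A CA 1",
    "ATOM 5 C CA . SER A 1 13 ? 7.000 8.000 9.000 1.00 0.00 ? 13 SER A CA 1",
    "ATOM 6 C CB . SER A 1 13 ? 7.500 8.500 9.500 1.00 0.00 ? 13 SER A CB 1"),
    path)
  path
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
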