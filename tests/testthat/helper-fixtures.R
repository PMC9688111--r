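# Small on-the-fly fixtures written to tempfiles.

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

fasta_file <- function(...) tmp_file(c(...), ext = ".fasta")

# A 3-residue toy PDB (glycine backbone), chain A, residues 1-3.
toy_pdb_lines <- function() {
  atom <- function(serial, name, resseq, icode = " ", chain = "A") {
    sprintf("ATOM  %5d  %-3s GLY %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
            serial, name, chain, resseq, icode,
            serial * 1.0, serial * 2.0, serial * 3.0, 1.00, 20.00, "N")
  }
  c(atom(1, "N", 1), atom(2, "CA", 1), atom(3, "C", 1),
    atom(4, "N", 2), atom(5, "CA", 2), atom(6, "C", 2),
    atom(7, "N", 3), atom(8, "CA", 3), atom(9, "C", 3),
    "TER", "END")
}

# Study-condition family configurations used across tests: a reference
# taxon sp01 always carries the motif planted at linker block 2, offset 5.
planted_family_config <- function(seed, extra_motifs = list(),
                                  carriers = c("sp01", "sp02", "sp03")) {
  simulation_config(
    n_taxa = 6L, seed = seed,
    motifs = c(list(list(block = 2L, offset = 5L,
                         configuration = "canonical", taxa = carriers)),
               extra_motifs))
}

two_clade_config <- function(seed = 1L) {
  simulation_config(
    tree = "fixed",
    newick = "((A:0.05,B:0.05):0.45,(C:0.05,D:0.05):0.45,E:0.5);",
    seed = seed)
}
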