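# Shared fixtures built in code.

# a small catalog of real Set 1 scales, usable as a toy screening family
toy_catalog <- function(ids = c("volume", "hydrophobicity", "p_helix",
                                "flexibility", "isoelectric_point")) {
  full <- aa_catalog()
  keep <- match(ids, full$info$descriptor_id)
  structure(list(info = full$info[keep, , drop = FALSE],
                 values = full$values[keep, , drop = FALSE]),
            class = "aa_catalog")
}

# minimal PDB text: one CA + N atom per residue, strict fixed columns
make_pdb_lines <- function(residues, chain = "A", b = 20) {
  serial <- 0L
  out <- character()
  for (r in residues) {
    for (nm in c("N", "CA")) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, "ALA", chain, r,
        1.0 * serial, 2.0, 3.0, 1.00, b, substr(nm, 1, 1)))
    }
  }
  c(out, "TER", "END")
}

# tab-delimited preference rows in the 22/23/24-field dialect
make_pref_lines <- function(n = 2, n_fields = 22, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    p <- round(runif(20), 4)
    f <- c("A", i, p)
    if (n_fields >= 23) f <- c(f, 10)
    if (n_fields == 24) f <- c(f, 0.5)
    paste(f, collapse = "\t")
  }, "")
}
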