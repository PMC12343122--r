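# Small deterministic fixtures built in code.

# A site_matrix with b perfect compositional blocks of m sites each:
# within-block similarity 1, between-block 0; geography concordant.
block_matrix <- function(b = 2L, m = 3L, species_per_block = 6L) {
  n <- b * m
  ids <- sprintf("s%02d", seq_len(n))
  taxa <- unlist(lapply(seq_len(b), function(g)
    sprintf("t%02d_%02d", g, seq_len(species_per_block))))
  inc <- matrix(0L, n, length(taxa), dimnames = list(ids, taxa))
  for (g in seq_len(b)) {
    rows <- ((g - 1L) * m + 1L):(g * m)
    cols <- ((g - 1L) * species_per_block + 1L):(g * species_per_block)
    inc[rows, cols] <- 1L
  }
  coords <- cbind(latitude = rep(seq(0, by = 20, length.out = b), each = m) +
                    rep(seq(0, 0.5, length.out = m), b),
                  longitude = rep(10, n))
  rownames(coords) <- ids
  site_matrix(inc, coords)
}

# Random binary site_matrix (rejecting empty assemblages/taxa).
random_matrix <- function(n_sites, n_taxa, p = 0.4) {
  repeat {
    inc <- matrix(rbinom(n_sites * n_taxa, 1L, p), n_sites, n_taxa,
                  dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                  sprintf("t%02d", seq_len(n_taxa))))
    if (all(rowSums(inc) > 0L) && all(colSums(inc) > 0L)) break
  }
  coords <- cbind(latitude = runif(n_sites, -60, 60),
                  longitude = runif(n_sites, -170, 170))
  rownames(coords) <- rownames(inc)
  site_matrix(inc, coords)
}

write_occ_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
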