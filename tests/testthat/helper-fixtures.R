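# Shared in-code fixtures for the test suite.

# A tiny 2-group design of `reps` runs per group.
tiny_design <- function(groups = c("A", "B"), reps = 3L) {
  data.frame(run = as.vector(outer(seq_len(reps), groups,
                                   function(r, g) paste0(g, r))),
             group = factor(rep(groups, each = reps), levels = groups),
             replicate = rep(seq_len(reps), length(groups)),
             stringsAsFactors = FALSE)
}

# An area_matrix from a plain numeric matrix, labelling as needed.
tiny_matrix <- function(m, accessions = NULL, runs = NULL, up = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- accessions %||% paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- runs %||% paste0("run", seq_len(ncol(m)))
  area_matrix(m, unique_peptides = up)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force digestion oracle: enumerate every boundary pair
# (start, end); a substring is a peptide iff both ends are cleavage
# boundaries, it spans at most `missed` internal sites, and its length is
# within bounds. Cleavage sites found with a perl regex lookahead,
# independent of the implementation's residue scan.
oracle_digest_count <- function(sequence, missed = 0L, min_len = 7L,
                                max_len = 30L, proline_rule = TRUE) {
  n <- nchar(sequence)
  if (n == 0L) return(0L)
  pat <- if (proline_rule) "[KR](?!P)" else "[KR]"
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  sites <- if (m[1] == -1L) integer(0) else as.integer(m)
  sites <- sites[sites < n]
  bounds <- c(0L, sites, n)
  count <- 0L
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (j <= i) next
      len <- bounds[j] - bounds[i]
      internal <- j - i - 1L
      if (internal <= missed && len >= min_len && len <= max_len)
        count <- count + 1L
    }
  }
  count
}

# A random proteome small enough for exhaustive oracles.
random_sequences <- function(n, seed, min_len = 20L, max_len = 120L,
                             kr = 0.11) {
  cfg <- synthetic_config(n_proteins = n, kr_density = kr, seed = seed,
                          term_size_range = c(2L, min(10L, n)))
  p <- generate_proteome(cfg)
  substr(p, 1L, pmin(nchar(p), max_len))
}
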