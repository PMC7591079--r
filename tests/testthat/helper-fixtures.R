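# Shared fixtures: tiny hand-made alignments and independent oracles used
# across test files.

# quartet alignment from four sequences (role order focal, sister, out1, out2)
quartet <- function(f, s, o1, o2, id = "OGTEST", offset = 0L) {
  codon_alignment(id, c(focal = f, sister = s, out1 = o1, out2 = o2), offset)
}

# an alignment identical across taxa except for specified single-base edits
# edits: list(list(taxon, position, base), ...)
edited_quartet <- function(base_seq, edits = list(), id = "OGTEST",
                           offset = 0L) {
  seqs <- rep(base_seq, 4)
  names(seqs) <- c("focal", "sister", "out1", "out2")
  for (e in edits) {
    ch <- strsplit(seqs[[e[[1]]]], "")[[1]]
    ch[e[[2]]] <- e[[3]]
    seqs[[e[[1]]]] <- paste(ch, collapse = "")
  }
  codon_alignment(id, seqs, offset)
}

# independent translate-and-compare oracle for single-base codon changes
oracle_effect_kind <- function(ref_codon, alt_codon) {
  gc <- Biostrings::GENETIC_CODE
  ra <- unname(gc[ref_codon]); aa <- unname(gc[alt_codon])
  if (ra == aa) "synonymous"
  else if (aa == "*") "stop_gain"
  else if (ra == "*") "stop_loss"
  else "non_synonymous"
}

# two-sided hypergeometric enumeration oracle for a 2x2 table
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# default small config for fast simulation tests
fast_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 12L, gene_length_codons = c(80L, 120L),
         fraction_candidates = 0.25, seed = 99L),
    list(...))
  do.call(sim_config, args)
}
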