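# Codon-level machinery shared by the simulator, the NG86 counter and the
# M0 likelihood: the 61 sense codons of the standard genetic code, their
# single-step neighbour structure, and the GY94 rate matrix.

.codon_cache <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (stop codons excluded),
#'   in lexicographic order.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

#' Translate a codon with the standard genetic code
#'
#' @param codon character vector of nucleotide triplets.
#' @return Single-letter amino acids, `"*"` for stop, `NA` for triplets
#'   containing characters outside A/C/G/T.
#' @export
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  codon <- toupper(codon)
  out <- unname(gc[codon])
  out[is.na(out) | !grepl("^[ACGT]{3}$", codon)] <- NA_character_
  out[!is.na(out) & out == ""] <- NA_character_
  # Biostrings uses "*" for stops already
  out
}

# Builds (once) the codon index tables:
#   codons: 61 sense codons; aa: their amino acids
#   pair tables for all ordered single-step sense->sense changes with
#   transition and synonymy flags; per-codon NG86 site fractions.
codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  bases <- c("A", "C", "G", "T")
  all64 <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
                 1, paste0, collapse = "")
  all64 <- sort(all64)
  aa64 <- unname(Biostrings::GENETIC_CODE[all64])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  n <- length(sense)       # 61
  idx <- seq_len(n)
  names(idx) <- sense

  # ordered single-nucleotide changes among sense codons
  from <- integer(0); to <- integer(0); pos <- integer(0)
  ts <- logical(0); syn <- logical(0)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  split3 <- do.call(rbind, strsplit(sense, ""))
  for (i in idx) {
    for (p in 1:3) {
      for (b in bases) {
        if (b == split3[i, p]) next
        mut <- split3[i, ]
        mut[p] <- b
        cod <- paste0(mut, collapse = "")
        j <- idx[cod]
        if (is.na(j)) next               # change into a stop codon
        from <- c(from, i); to <- c(to, unname(j)); pos <- c(pos, p)
        ts <- c(ts, purine[split3[i, p]] == purine[b])
        syn <- c(syn, aa[i] == aa[j])
      }
    }
  }
  pairs <- data.frame(from = from, to = to, pos = pos,
                      transition = ts, synonymous = syn)

  # NG86 site fractions per codon: at each position, the fraction of the 3
  # possible changes that are synonymous (changes to stops count as
  # non-synonymous, i.e. they stay in the denominator).
  s_sites <- numeric(n)
  for (i in idx) {
    syn_frac <- 0
    for (p in 1:3) {
      nsyn <- sum(pairs$from == i & pairs$pos == p & pairs$synonymous)
      syn_frac <- syn_frac + nsyn / 3
    }
    s_sites[i] <- syn_frac
  }

  .codon_cache$tables <- list(codons = sense, aa = aa, index = idx,
                              pairs = pairs, s_sites = s_sites,
                              n_sites = 3 - s_sites)
  .codon_cache$tables
}

#' GY94 codon substitution rate matrix
#'
#' Builds the 61x61 generator of the Goldman-Yang (1994) codon model:
#' the rate from codon i to codon j is zero if the codons differ at more
#' than one position, and otherwise
#' \eqn{\pi_j \kappa^{ts} \omega^{ns}} where \eqn{ts} indicates a
#' transition and \eqn{ns} a non-synonymous change. Rows sum to zero and
#' the matrix is rescaled so that the expected number of substitutions per
#' codon per unit time is one at stationarity.
#'
#' @param kappa transition/transversion rate ratio, `>= 0`.
#' @param omega non-synonymous/synonymous rate ratio, `>= 0`.
#' @param pi stationary distribution over the 61 sense codons; defaults to
#'   uniform (1/61).
#' @return 61x61 matrix with codon dimnames; attribute `"pi"` carries the
#'   stationary distribution used.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = NULL) {
  if (!is.finite(kappa) || !is.finite(omega) || kappa < 0 || omega < 0)
    stop("kappa and omega must be finite and non-negative")
  tb <- codon_tables()
  n <- length(tb$codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  if (length(pi) != n || any(!is.finite(pi)) || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability distribution over the 61 sense codons")
  Q <- matrix(0, n, n, dimnames = list(tb$codons, tb$codons))
  p <- tb$pairs
  rate <- pi[p$to] * ifelse(p$transition, kappa, 1) * ifelse(p$synonymous, 1, omega)
  Q[cbind(p$from, p$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  attr(Q, "pi") <- pi
  Q
}

# Transition probability matrices exp(Q t) for several branch lengths,
# via the symmetrized eigendecomposition of the reversible generator
# (B = D^{1/2} Q D^{-1/2} is symmetric for pi-reversible Q).
gy94_pmats <- function(Q, times) {
  pi <- attr(Q, "pi")
  sq <- sqrt(pi)
  B <- sweep(sq * Q, 2, sq, "/")           # D^{1/2} Q D^{-1/2}, symmetric
  B <- (B + t(B)) / 2                      # enforce exact symmetry
  eg <- eigen(B, symmetric = TRUE)
  V <- eg$vectors
  lapply(times, function(t) {
    E <- V %*% (exp(eg$values * t) * t(V))
    P <- sweep((1 / sq) * E, 2, sq, "*")   # D^{-1/2} E D^{1/2}
    P[P < 0] <- 0                          # clip eigen round-off
    dimnames(P) <- dimnames(Q)
    P
  })
}
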