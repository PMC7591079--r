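# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
# Site counts come from the per-codon synonymous fractions precomputed in
# codon_tables(); multi-difference codons are resolved by averaging over
# all orderings of single-base steps, excluding paths through stop codons.

#' NG86 synonymous/non-synonymous site counts for one codon
#'
#' At each codon position the fraction of the three possible single-base
#' changes that are synonymous contributes to the synonymous site count;
#' changes into stop codons count as non-synonymous. The two counts always
#' sum to 3.
#'
#' @param codon a sense codon (string over ACGT).
#' @return Named numeric vector `c(n_sites = ..., s_sites = ...)`.
#' @export
ng86_sites <- function(codon) {
  tb <- codon_tables()
  i <- tb$index[toupper(codon)]
  if (is.na(i)) stop("not a sense codon: ", codon)
  c(n_sites = tb$n_sites[i], s_sites = tb$s_sites[i])
}

# all orderings of 1..k (k <= 3)
.orderings <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# (syn, nonsyn) differences between two sense codons, averaged over
# single-step paths that avoid stop-codon intermediates; if every path is
# blocked, all paths are used and steps touching a stop count as
# non-synonymous.
codon_path_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- .orderings[[d]]
  tally <- function(ord, allow_stops) {
    cur <- a; syn <- 0; nonsyn <- 0
    for (p in diff_pos[ord]) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (!allow_stops && (aa1 == "*" || aa2 == "*")) return(NULL)
      if (aa1 == "*" || aa2 == "*") nonsyn <- nonsyn + 1
      else if (aa1 == aa2) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stops = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

#' Pairwise NG86 dN/dS
#'
#' Counts synonymous and non-synonymous sites (averaged over the two
#' sequences) and differences codon by codon, converts to proportions
#' `pN = Nd/N`, `pS = Sd/S`, and applies the Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3} p)}. Codons containing a gap,
#' `N`, or an internal stop in either sequence are skipped. `dS = 0`
#' leaves omega undefined (flagged, not infinite). Symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b equal-length, in-frame nucleotide strings.
#' @return Object of class `ng86`: list with `N`, `S`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS`, `omega`, `omega_defined`, `codons_compared`.
#' @export
ng86_pair <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  if (nchar(seq_a) %% 3 != 0) stop("sequence length must be a multiple of 3")
  tb <- codon_tables()
  ncod <- nchar(seq_a) %/% 3
  starts <- 3 * (seq_len(ncod) - 1) + 1
  ca <- substring(seq_a, starts, starts + 2)
  cb <- substring(seq_b, starts, starts + 2)
  ok <- ca %in% tb$codons & cb %in% tb$codons
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  ia <- tb$index[ca]; ib <- tb$index[cb]
  S <- (sum(tb$s_sites[ia]) + sum(tb$s_sites[ib])) / 2
  N <- 3 * length(ca) - S
  diffs <- c(syn = 0, nonsyn = 0)
  for (k in which(ca != cb)) diffs <- diffs + codon_path_diffs(ca[k], cb[k])
  Sd <- unname(diffs["syn"]); Nd <- unname(diffs["nonsyn"])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 3 / 4 || pN >= 3 / 4)
    stop("substitution saturation: Jukes-Cantor correction undefined")
  dS <- -3 / 4 * log(1 - 4 / 3 * pS)
  dN <- -3 / 4 * log(1 - 4 / 3 * pN)
  omega_defined <- dS > 0
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS,
                 omega = if (omega_defined) dN / dS else NA_real_,
                 omega_defined = omega_defined,
                 codons_compared = length(ca)),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, digits = 4, ...) {
  cat("NG86 pairwise dN/dS\n")
  cat(sprintf("  codons compared: %d\n", x$codons_compared))
  cat(sprintf("  N = %.*f  S = %.*f  (N + S = %g)\n",
              digits, x$N, digits, x$S, x$N + x$S))
  cat(sprintf("  Nd = %.*f  Sd = %.*f\n", digits, x$Nd, digits, x$Sd))
  cat(sprintf("  dN = %.*f  dS = %.*f  omega = %s\n",
              digits, x$dN, digits, x$dS,
              if (x$omega_defined) formatC(x$omega, digits = digits,
                                           format = "f") else "undefined (dS = 0)"))
  invisible(x)
}
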