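# Maximum-likelihood fit of the GY94/M0 codon model on the fixed unrooted
# quartet ((focal, sister), out1, out2): one omega and one kappa shared by
# all sites and branches, five branch lengths, likelihood by Felsenstein
# pruning over compressed codon-site patterns.

# Encode an alignment as codon-state indices per taxon, dropping codons
# with gaps/N/stops in any taxon; returns compressed site patterns.
codon_patterns <- function(aln, max_gap_frac = 0.5) {
  tb <- codon_tables()
  aln <- trim_to_frame(aln)
  ncod <- aln$length %/% 3L
  starts <- 3L * (seq_len(ncod) - 1L) + 1L
  idx <- sapply(aln$seqs, function(s) {
    unname(tb$index[substring(s, starts, starts + 2L)])
  })
  if (ncod == 1L) idx <- matrix(idx, nrow = 1L)
  ok <- rowSums(is.na(idx)) == 0L
  if (mean(!ok) > max_gap_frac)
    stop(sprintf("more than %.0f%% of codons unusable (gaps/N/stops)",
                 100 * max_gap_frac))
  idx <- idx[ok, , drop = FALSE]
  if (!nrow(idx)) stop("no usable codons")
  key <- apply(idx, 1, paste, collapse = ".")
  tab <- table(key)
  first <- idx[!duplicated(key), , drop = FALSE]
  rownames(first) <- key[!duplicated(key)]
  list(patterns = first[names(tab), , drop = FALSE],
       weights = as.integer(tab),
       n_codons = nrow(idx))
}

# Log-likelihood of the quartet under GY94/M0 (compiled pruning kernel).
# pat: list from codon_patterns(); kappa, omega, t (5 branch lengths in
# order focal, sister, out1, out2, internal).
m0_loglik <- function(pat, kappa, omega, t, pi = NULL) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  quartet_loglik_cpp(pat$patterns - 1L, as.numeric(pat$weights),
                     Q, attr(Q, "pi"), t)
}

# Pure-R reference implementation of the same likelihood, kept as an
# independent cross-check of the compiled kernel.
m0_loglik_r <- function(pat, kappa, omega, t, pi = NULL) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  pi <- attr(Q, "pi")
  P <- gy94_pmats(Q, t)
  X <- pat$patterns
  inner <- P[[3]][, X[, 3], drop = FALSE] * P[[4]][, X[, 4], drop = FALSE]
  up <- P[[5]] %*% inner
  L <- pi * P[[1]][, X[, 1], drop = FALSE] *
    P[[2]][, X[, 2], drop = FALSE] * up
  site <- colSums(L)
  if (any(site <= 0) || any(!is.finite(site))) return(-Inf)
  sum(pat$weights * log(site))
}

#' Fit the GY94/M0 codon model to a quartet alignment
#'
#' Maximizes the pruning log-likelihood over \eqn{(\kappa, \omega)} and the
#' five branch lengths of the unrooted topology
#' `((focal, sister), out1, out2)` with Nelder-Mead on log-transformed
#' parameters from three starts (\eqn{\omega_0 \in \{0.2, 1, 3\}}),
#' declaring convergence at a relative log-likelihood change below 1e-8.
#' The log-parameterization keeps all rates positive and avoids boundary
#' traps as \eqn{\omega \to 0}. An alignment with no variable codons
#' carries no information about omega; the fit is then returned with
#' `converged = FALSE` and `omega = NA` rather than failing.
#'
#' @param aln a `codon_alignment`, trimmed and in role order.
#' @param pi codon stationary distribution (default uniform over the 61
#'   sense codons; see [gy94_rate_matrix()]).
#' @param max_gap_frac maximum tolerated fraction of unusable codons.
#' @param control optimizer overrides passed to [stats::optim()].
#' @return Object of class `m0_fit` with elements `omega`, `kappa`,
#'   `branch_lengths` (focal, sister, out1, out2, internal),
#'   `log_likelihood`, `converged`, `n_codons`, `n_patterns`, `method`.
#' @export
fit_m0 <- function(aln, pi = NULL, max_gap_frac = 0.5, control = list()) {
  pat <- codon_patterns(aln, max_gap_frac)
  variable <- any(apply(pat$patterns, 1,
                        function(r) length(unique(r)) > 1L))
  if (!variable) {
    return(structure(list(omega = NA_real_, kappa = NA_real_,
                          branch_lengths = stats::setNames(rep(NA_real_, 5),
                            c("focal", "sister", "out1", "out2", "internal")),
                          log_likelihood = NA_real_, converged = FALSE,
                          n_codons = pat$n_codons,
                          n_patterns = nrow(pat$patterns),
                          method = "GY94_M0"),
                     class = "m0_fit"))
  }
  # crude initial branch lengths from codon-level p-distances
  X <- pat$patterns; w <- pat$weights
  pdist <- function(i, j) sum(w * (X[, i] != X[, j])) / sum(w)
  t0 <- max(mean(c(pdist(1, 2), pdist(3, 4))) / 2, 0.01)
  negll <- function(lp) {
    v <- exp(lp)
    -m0_loglik(pat, kappa = v[1], omega = v[2], t = v[3:7], pi = pi)
  }
  # three documented starts (omega 0.2, 1, 3) explored coarsely, then the
  # best polished to the 1e-8 relative-likelihood convergence criterion
  coarse <- utils::modifyList(list(maxit = 250L, reltol = 1e-6), control)
  polish <- utils::modifyList(list(maxit = 800L, reltol = 1e-8), control)
  starts <- lapply(c(0.2, 1, 3), function(w0)
    log(c(2, w0, rep(t0, 4), t0 / 2)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, negll, method = "Nelder-Mead", control = coarse)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best <- stats::optim(best$par, negll, method = "Nelder-Mead",
                       control = polish)
  v <- exp(best$par)
  structure(list(omega = unname(v[2]), kappa = unname(v[1]),
                 branch_lengths = stats::setNames(unname(v[3:7]),
                   c("focal", "sister", "out1", "out2", "internal")),
                 log_likelihood = -best$value,
                 converged = best$convergence == 0L,
                 n_codons = pat$n_codons,
                 n_patterns = nrow(pat$patterns),
                 method = "GY94_M0"),
            class = "m0_fit")
}

#' @export
print.m0_fit <- function(x, digits = 4, ...) {
  cat("GY94/M0 maximum-likelihood fit (quartet topology)\n")
  if (is.na(x$omega)) {
    cat(sprintf("  no variable codons among %d: omega undefined\n", x$n_codons))
    return(invisible(x))
  }
  cat(sprintf("  omega = %.*f   kappa = %.*f\n",
              digits, x$omega, digits, x$kappa))
  cat(sprintf("  log-likelihood = %.*f  (%d codons, %d patterns)\n",
              digits, x$log_likelihood, x$n_codons, x$n_patterns))
  cat("  branch lengths (subst/codon):\n")
  print(round(x$branch_lengths, digits))
  if (!x$converged) cat("  warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.m0_fit <- function(object, ...) {
  c(omega = object$omega, kappa = object$kappa, object$branch_lengths)
}

#' @export
logLik.m0_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 7L, nobs = object$n_codons,
            class = "logLik")
}

#' Screen orthogroups for positive selection
#'
#' Runs either the quartet M0 maximum-likelihood fit (`"GY94_M0"`) or the
#' pairwise NG86 estimate on the focal/sister pair (`"NG86_focal_pair"`)
#' over a set of alignments.
#'
#' @param alns named list of `codon_alignment` objects (role order).
#' @param method `"GY94_M0"` or `"NG86_focal_pair"`.
#' @param ... passed to [fit_m0()].
#' @return data.frame with one row per orthogroup: `orthogroup_id`,
#'   `method`, `omega`, `omega_defined`, `dN`, `dS`, `kappa`, `logL`,
#'   `converged`.
#' @export
screen_omega <- function(alns, method = c("GY94_M0", "NG86_focal_pair"), ...) {
  method <- match.arg(method)
  rows <- lapply(alns, function(a) {
    a <- trim_to_frame(a)
    if (method == "GY94_M0") {
      f <- fit_m0(a, ...)
      data.frame(orthogroup_id = a$orthogroup_id, method = method,
                 omega = f$omega, omega_defined = !is.na(f$omega),
                 dN = NA_real_, dS = NA_real_, kappa = f$kappa,
                 logL = f$log_likelihood, converged = f$converged,
                 stringsAsFactors = FALSE)
    } else {
      r <- ng86_pair(a$seqs[[1]], a$seqs[[2]])
      data.frame(orthogroup_id = a$orthogroup_id, method = method,
                 omega = r$omega, omega_defined = r$omega_defined,
                 dN = r$dN, dS = r$dS, kappa = NA_real_, logL = NA_real_,
                 converged = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
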