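# Comparative annotation statistics: exact binomial 50:50 acceptance
# regions for per-term two-species counts, Fisher tests on level A
# contingency tables, chi-squared tests on level B distributions,
# Benjamini-Hochberg-adjusted enrichment against the transcriptome, and
# two-proportion comparisons with Wald confidence limits. Standard tests
# are delegated to stats (fisher.test, chisq.test, p.adjust); the
# acceptance-region construction is the module's own.

#' Test configuration
#'
#' @param alpha two-sided test level (default 0.05).
#' @param fdr Benjamini-Hochberg threshold for the enrichment scan.
#' @param ci_method `"exact_binomial"` (default) or `"normal_wald"` for
#'   the 50:50 acceptance region.
#' @param n_range totals for which acceptance regions are tabulated.
#' @return List of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, fdr = 0.05,
                        ci_method = c("exact_binomial", "normal_wald"),
                        n_range = c(2L, 200L)) {
  stopifnot(alpha > 0, alpha < 1, fdr > 0, fdr < 1)
  structure(list(alpha = alpha, fdr = fdr,
                 ci_method = match.arg(ci_method),
                 n_range = as.integer(n_range)),
            class = "test_config")
}

#' Acceptance region for an equal (50:50) split
#'
#' For a term with `n` sequences split between two species, the region of
#' proportions compatible with Binomial(n, 0.5) at level `alpha`.
#' The exact method keeps every count `k` whose two-sided exact binomial
#' p-value `min(1, 2 P(X <= min(k, n-k)))` exceeds `alpha` and maps the
#' kept counts to proportions; by the symmetry of the null this is the
#' smallest symmetric acceptance region. The Wald method returns
#' \eqn{0.5 \pm z_{1-\alpha/2}\sqrt{0.25/n}}.
#'
#' @param n total count, `>= 2`.
#' @param alpha test level.
#' @param method `"exact_binomial"` or `"normal_wald"`.
#' @return Numeric `c(lo, hi)`, symmetric about 0.5.
#' @export
equal_ratio_acceptance <- function(n, alpha = 0.05,
                                   method = c("exact_binomial", "normal_wald")) {
  method <- match.arg(method)
  if (n < 2) stop("acceptance region defined for n >= 2 only")
  if (method == "normal_wald") {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(0.25 / n)
    return(c(lo = max(0, 0.5 - half), hi = min(1, 0.5 + half)))
  }
  k <- 0:n
  pval <- pmin(1, 2 * stats::pbinom(pmin(k, n - k), n, 0.5))
  keep <- k[pval > alpha]
  c(lo = min(keep) / n, hi = max(keep) / n)
}

#' Scan per-term two-species counts against the 50:50 acceptance region
#'
#' One comparison per term with total `n >= 2`: the focal proportion is
#' compared with the acceptance region for an equal split at the
#' configured level; terms outside the region are significant, with the
#' overrepresented species recorded as direction. Raw outliers are
#' reported without multiplicity adjustment (the region plays the role of
#' a plotted confidence band, not a family-wise test).
#'
#' @param counts data.frame with columns `term_id`, `count_focal`,
#'   `count_sister`.
#' @param config a [test_config()].
#' @return data.frame: `term_id`, `count_focal`, `count_sister`, `n`,
#'   `ratio`, `lo`, `hi`, `significant`, `direction`
#'   (`"focal"`/`"sister"`/`"none"`).
#' @export
term_ratio_scan <- function(counts, config = test_config()) {
  n <- counts$count_focal + counts$count_sister
  keep <- n >= 2
  counts <- counts[keep, , drop = FALSE]
  n <- n[keep]
  reg <- t(vapply(n, equal_ratio_acceptance, numeric(2),
                  alpha = config$alpha, method = config$ci_method))
  ratio <- counts$count_focal / n
  sig <- ratio < reg[, 1] | ratio > reg[, 2]
  data.frame(term_id = counts$term_id,
             count_focal = counts$count_focal,
             count_sister = counts$count_sister,
             n = n, ratio = ratio, lo = reg[, 1], hi = reg[, 2],
             significant = sig,
             direction = ifelse(!sig, "none",
                                ifelse(ratio > reg[, 2], "focal", "sister")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of tables no more likely than the one
#' observed (the convention of [stats::fisher.test()], which does the
#' computation).
#'
#' @param a,b,c,d non-negative integer cells, rows = groups.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table: test undefined")
  min(1, stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value)
}

#' Species-wise Fisher tests on KEGG level A counts
#'
#' For each level A category, tests the 2x2 table
#' `[count, total - count]` x species, where the totals are the numbers of
#' annotated candidate sequences per species.
#'
#' @param counts data.frame with columns `category`, `count_focal`,
#'   `count_sister`.
#' @param totals named numeric `c(focal = ..., sister = ...)`.
#' @param config a [test_config()].
#' @return `counts` with added `p` and `significant`.
#' @export
levelA_fisher <- function(counts, totals, config = test_config()) {
  if (any(counts$count_focal > totals[["focal"]]) ||
      any(counts$count_sister > totals[["sister"]]))
    stop("category count exceeds the species total")
  p <- mapply(function(cf, cs)
    fisher_exact_2x2(cf, totals[["focal"]] - cf,
                     cs, totals[["sister"]] - cs),
    counts$count_focal, counts$count_sister)
  counts$p <- unname(p)
  counts$significant <- counts$p < config$alpha
  counts
}

#' Chi-squared test of level B distributions between species
#'
#' Pearson chi-squared (no continuity correction) on the r x 2 table of
#' per-level-B counts by species within one level A category; rows with
#' zero margin are dropped with a warning, and small expected counts
#' (any E < 5) are flagged in the result.
#'
#' @param tab matrix or data.frame, rows = level B categories,
#'   2 columns = species.
#' @return List: `statistic`, `df`, `p`, `expected`, `small_expected`.
#' @export
levelB_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2) stop("need an r x 2 table")
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-margin row(s) dropped")
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("need at least 2 non-empty rows")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected,
       small_expected = any(ct$expected < 5))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Step-up adjusted values (order-invariant, capped at 1).
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Term enrichment of the candidate set against the transcriptome
#'
#' Per term: 2x2 table of (in term / not in term) x (candidate /
#' rest-of-transcriptome), two-sided Fisher, Benjamini-Hochberg
#' adjustment across terms; significant iff adjusted p < `fdr`.
#'
#' @param candidate_table,transcriptome_table annotation data.frames with
#'   columns `orthogroup_id`, `term_id`; candidate genes must be a subset
#'   of transcriptome genes.
#' @param candidate_genes,transcriptome_genes gene universes (default:
#'   the ids present in each table).
#' @param config a [test_config()].
#' @return data.frame per term: counts, `p`, `p_adjusted`, `significant`,
#'   `direction` (`"over"`/`"under"`).
#' @export
enrichment_vs_transcriptome <- function(candidate_table, transcriptome_table,
                                        candidate_genes = NULL,
                                        transcriptome_genes = NULL,
                                        config = test_config()) {
  if (is.null(candidate_genes))
    candidate_genes <- unique(candidate_table$orthogroup_id)
  if (is.null(transcriptome_genes))
    transcriptome_genes <- unique(transcriptome_table$orthogroup_id)
  if (!all(candidate_genes %in% transcriptome_genes))
    stop("candidate gene set must be a subset of the transcriptome")
  rest <- setdiff(transcriptome_genes, candidate_genes)
  terms <- sort(unique(transcriptome_table$term_id))
  res <- lapply(terms, function(t) {
    in_term <- unique(transcriptome_table$orthogroup_id[
      transcriptome_table$term_id == t])
    a <- length(intersect(candidate_genes, in_term))
    b <- length(candidate_genes) - a
    cc <- length(intersect(rest, in_term))
    d <- length(rest) - cc
    data.frame(term_id = t, cand_in = a, cand_out = b,
               rest_in = cc, rest_out = d,
               p = fisher_exact_2x2(a, b, cc, d),
               direction = if (a / max(1, a + b) >= cc / max(1, cc + d))
                 "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_fdr(out$p)
  out$significant <- out$p_adjusted < config$fdr
  out
}

#' Category proportions: candidate set vs transcriptome
#'
#' Per category: proportions in the candidate and transcriptome sets with
#' Wald 95\% confidence limits \eqn{\hat p \pm z\sqrt{\hat p(1-\hat p)/n}}
#' and a pooled two-proportion z-test at the configured level.
#'
#' @param counts data.frame with columns `category`, `count_candidate`,
#'   `count_transcriptome`.
#' @param n_candidate,n_transcriptome set totals (sequences with an
#'   annotation in the respective set).
#' @param config a [test_config()].
#' @return data.frame with proportions, CI bounds, `z`, `p`,
#'   `significant`, `direction` (`"higher"`/`"lower"` in candidates).
#' @export
proportion_comparison_vs_transcriptome <- function(counts, n_candidate,
                                                   n_transcriptome,
                                                   config = test_config()) {
  if (n_candidate == 0 || n_transcriptome == 0)
    stop("set totals must be positive")
  z975 <- stats::qnorm(1 - config$alpha / 2)
  p1 <- counts$count_candidate / n_candidate
  p2 <- counts$count_transcriptome / n_transcriptome
  ci <- function(p, n) z975 * sqrt(p * (1 - p) / n)
  pool <- (counts$count_candidate + counts$count_transcriptome) /
    (n_candidate + n_transcriptome)
  se <- sqrt(pool * (1 - pool) * (1 / n_candidate + 1 / n_transcriptome))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(category = counts$category,
             prop_candidate = p1,
             ci_lo_candidate = pmax(0, p1 - ci(p1, n_candidate)),
             ci_hi_candidate = pmin(1, p1 + ci(p1, n_candidate)),
             prop_transcriptome = p2,
             ci_lo_transcriptome = pmax(0, p2 - ci(p2, n_transcriptome)),
             ci_hi_transcriptome = pmin(1, p2 + ci(p2, n_transcriptome)),
             z = z, p = p, significant = p < config$alpha,
             direction = ifelse(p1 >= p2, "higher", "lower"),
             stringsAsFactors = FALSE, row.names = NULL)
}
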