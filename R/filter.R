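# Orthogroup-level quality filters: codon-frame trimming, pairwise
# identity, and the keep/drop decision combining identity, length and
# taxon-completeness rules.

#' Filter configuration
#'
#' Defaults mirror the screening thresholds: orthogroups whose pairwise
#' similarity falls below 90\% are discarded (paralog guard) and
#' sequences shorter than 200 bp are removed.
#'
#' @param min_identity minimum pairwise identity kept, in (0, 1];
#'   the boundary is inclusive (identity exactly at the threshold is kept).
#' @param min_length_bp minimum trimmed alignment length in bp.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_identity = 0.90, min_length_bp = 200L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_length_bp >= 3)
  structure(list(min_identity = min_identity,
                 min_length_bp = as.integer(min_length_bp)),
            class = "filter_config")
}

#' Trim an alignment to whole codons
#'
#' Removes the leading columns before the frame offset and any trailing
#' columns forming an incomplete codon; the returned alignment has frame
#' offset 0 and a length divisible by 3. Idempotent.
#'
#' @param aln a `codon_alignment`.
#' @return Trimmed `codon_alignment`.
#' @export
trim_to_frame <- function(aln) {
  start <- aln$frame_offset + 1L
  ncod <- (aln$length - aln$frame_offset) %/% 3L
  if (ncod < 1L) stop("trimming leaves an empty alignment")
  end <- aln$frame_offset + 3L * ncod
  if (start == 1L && end == aln$length && aln$frame_offset == 0L) return(aln)
  seqs <- vapply(aln$seqs, substr, character(1), start = start, stop = end)
  codon_alignment(aln$orthogroup_id, seqs, 0L)
}

#' Pairwise sequence identity
#'
#' Fraction of matching columns among comparable columns; columns where
#' either sequence carries a gap or N are excluded from numerator and
#' denominator. Symmetric in its arguments.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) stop("no comparable columns: identity undefined")
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Apply the orthogroup filters
#'
#' An orthogroup is kept iff all six pairwise identities are at least
#' `min_identity`, its trimmed length is at least `min_length_bp`, and all
#' four taxa are present. Every input receives exactly one outcome in the
#' report.
#'
#' @param alns named list of trimmed `codon_alignment` objects.
#' @param config a [filter_config()].
#' @return List with `kept` (the surviving alignments) and `report`, a
#'   data.frame with columns `orthogroup_id`, `outcome`
#'   (`kept`/`dropped_identity`/`dropped_length`/`dropped_missing_taxon`),
#'   `length`, `min_pairwise_identity`.
#' @export
filter_orthogroups <- function(alns, config = filter_config()) {
  outcomes <- character(length(alns))
  minid <- rep(NA_real_, length(alns))
  lens <- integer(length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    lens[i] <- a$length
    if (length(a$seqs) != 4L) {
      outcomes[i] <- "dropped_missing_taxon"
      next
    }
    if (a$length < config$min_length_bp) {
      outcomes[i] <- "dropped_length"
      next
    }
    cmb <- utils::combn(4L, 2L)
    ids <- apply(cmb, 2, function(p)
      pairwise_identity(a$seqs[[p[1]]], a$seqs[[p[2]]]))
    minid[i] <- min(ids)
    outcomes[i] <- if (min(ids) < config$min_identity) "dropped_identity" else "kept"
  }
  report <- data.frame(
    orthogroup_id = vapply(alns, `[[`, character(1), "orthogroup_id"),
    outcome = outcomes,
    length = lens,
    min_pairwise_identity = minid,
    stringsAsFactors = FALSE, row.names = NULL)
  list(kept = alns[outcomes == "kept"], report = report)
}
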