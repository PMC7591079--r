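# Variant calling from a quartet alignment, species-specificity
# classification with outgroup polarization, and codon-aware coding-effect
# annotation. Sites are represented as data frames (one row per variant
# column) so downstream screens can filter and join them directly.

#' Call variant sites from a quartet alignment
#'
#' One record per alignment column with at least two distinct bases among
#' `A,C,G,T` across the four taxa. Columns containing a gap or `N` in any
#' taxon are excluded from calling (ambiguity is treated as missing data);
#' their positions are returned in the `excluded` attribute for audit.
#'
#' The REF allele is the majority allele across the four taxa; ties are
#' broken toward the allele shared by both outgroups, then alphabetically.
#' ALT collects the remaining alleles in alphabetical order.
#'
#' @param aln a `codon_alignment` whose sequences are in role order
#'   (focal, sister, out1, out2).
#' @return data.frame with columns `orthogroup_id`, `position`, `focal`,
#'   `sister`, `out1`, `out2`, `ref`, `alt`, `specificity`; sorted by
#'   position. Attribute `excluded`: integer positions skipped for gaps/N.
#' @export
call_variant_sites <- function(aln) {
  m <- aln_matrix(aln)
  good <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = 4L)) == 4L
  nvar <- apply(m, 2, function(col) length(unique(col)))
  keep <- which(good & nvar >= 2L)
  sites <- data.frame(
    orthogroup_id = character(0), position = integer(0),
    focal = character(0), sister = character(0),
    out1 = character(0), out2 = character(0),
    ref = character(0), alt = character(0), specificity = character(0),
    stringsAsFactors = FALSE)
  if (length(keep)) {
    rows <- lapply(keep, function(j) {
      b <- m[, j]
      ref <- majority_allele(b)
      alt <- sort(setdiff(unique(b), ref))
      data.frame(orthogroup_id = aln$orthogroup_id, position = j,
                 focal = b[1], sister = b[2], out1 = b[3], out2 = b[4],
                 ref = ref, alt = paste(alt, collapse = ","),
                 specificity = classify_specificity(b),
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, rows)
    rownames(sites) <- NULL
  }
  attr(sites, "excluded") <- which(!good)
  sites
}

# Majority allele of a 4-taxon column; ties -> outgroup-shared allele if it
# is among the tied ones, else the alphabetically first tied allele.
majority_allele <- function(bases) {
  tab <- table(bases)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  if (bases[3] == bases[4] && bases[3] %in% top) return(bases[3])
  sort(top)[1]
}

#' Classify the species-specificity of a variant column
#'
#' The strict classes require three-way unanimity: a site is
#' `focal_specific_strict` iff the focal base differs from the other three
#' taxa and sister, out1 and out2 carry the same base — which polarizes the
#' focal allele as derived on the focal lineage (`sister_specific_strict`
#' symmetrically). `focal_vs_sister_only` marks biallelic sites where focal
#' and sister differ but the three non-focal taxa are not unanimous (each
#' allele shared with one outgroup); such sites separate the looser
#' focal-vs-sister screen from the strict one. Columns with focal == sister
#' but variation among the outgroups are `shared`; anything else
#' (three or four distinct alleles across taxa) is `other`.
#'
#' @param bases character vector of 4 bases in role order
#'   (focal, sister, out1, out2).
#' @return One of `"focal_specific_strict"`, `"sister_specific_strict"`,
#'   `"focal_vs_sister_only"`, `"shared"`, `"other"`, `"undetermined"`.
#' @export
classify_specificity <- function(bases) {
  if (length(bases) != 4L) stop("need exactly 4 bases (role order)")
  if (any(!bases %in% c("A", "C", "G", "T"))) return("undetermined")
  f <- bases[1]; s <- bases[2]; o1 <- bases[3]; o2 <- bases[4]
  if (f != s && s == o1 && s == o2) return("focal_specific_strict")
  if (s != f && f == o1 && f == o2) return("sister_specific_strict")
  if (f == s) return("shared")
  if (length(unique(bases)) == 2L) return("focal_vs_sister_only")
  "other"
}

#' Codon-level effect of a single-base change
#'
#' Maps a 1-based alignment position to its codon, builds the reference
#' codon from the column-wise majority context, substitutes the alternate
#' allele at the within-codon position, and compares translations under the
#' standard genetic code.
#'
#' @param aln a `codon_alignment`.
#' @param position 1-based alignment column; must exceed `frame_offset`.
#' @param alt_base the deviant allele.
#' @param ref_base reference allele; defaults to the majority allele of
#'   the column.
#' @param frame_offset overrides the alignment's frame offset.
#' @return List of class `coding_effect`: `codon_index`, `codon_position`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `kind` (one of
#'   `synonymous`, `non_synonymous`, `stop_gain`, `stop_loss`,
#'   `undetermined`).
#' @export
coding_effect <- function(aln, position, alt_base, ref_base = NULL,
                          frame_offset = aln$frame_offset) {
  position <- as.integer(position)
  if (position <= frame_offset || position > aln$length)
    stop("position outside the coding frame")
  off <- position - frame_offset
  codon_index <- (off - 1L) %/% 3L + 1L
  codon_position <- off - 3L * (codon_index - 1L)
  cols <- frame_offset + (3L * (codon_index - 1L) + 1L):(3L * codon_index)
  if (max(cols) > aln$length)
    return(effect_record(codon_index, codon_position, NA, NA, "undetermined"))
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  if (any(!m %in% c("A", "C", "G", "T")))
    return(effect_record(codon_index, codon_position, NA, NA, "undetermined"))
  ref_ctx <- apply(m, 2, majority_allele)
  if (!is.null(ref_base)) ref_ctx[codon_position] <- ref_base
  ref_codon <- paste(ref_ctx, collapse = "")
  alt_ctx <- ref_ctx
  alt_ctx[codon_position] <- alt_base
  alt_codon <- paste(alt_ctx, collapse = "")
  effect_record(codon_index, codon_position, ref_codon, alt_codon,
                kind = NULL)
}

effect_record <- function(codon_index, codon_position, ref_codon, alt_codon,
                          kind = NULL) {
  if (is.null(kind)) {
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    kind <- if (is.na(ref_aa) || is.na(alt_aa)) "undetermined"
      else if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "non_synonymous"
  } else {
    ref_aa <- NA_character_; alt_aa <- NA_character_
  }
  structure(list(codon_index = codon_index, codon_position = codon_position,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, kind = kind),
            class = "coding_effect")
}

#' @export
print.coding_effect <- function(x, ...) {
  cat(sprintf("<coding_effect> codon %d pos %d: %s->%s (%s %d %s) %s\n",
              x$codon_index, x$codon_position,
              x$ref_codon, x$alt_codon, x$ref_aa, x$codon_index, x$alt_aa,
              x$kind))
  invisible(x)
}

#' Annotate called sites with coding effects
#'
#' For each variant site the deviant allele is chosen by specificity class
#' (the single deviant taxon's base for strict sites, the focal base
#' otherwise) and its codon effect computed; results are bound onto the
#' sites table. Report notation mirrors the field convention
#' `{ref_base} {position} {alt_base}` / `{ref_aa} {codon_index} {alt_aa}`.
#'
#' @param aln a `codon_alignment`.
#' @param sites output of [call_variant_sites()].
#' @return `sites` with added columns `codon_index`, `codon_position`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `kind`,
#'   `nt_notation`, `aa_notation`.
#' @export
annotate_sites <- function(aln, sites) {
  n <- nrow(sites)
  add <- data.frame(codon_index = integer(n), codon_position = integer(n),
                    ref_codon = character(n), alt_codon = character(n),
                    ref_aa = character(n), alt_aa = character(n),
                    kind = character(n), nt_notation = character(n),
                    aa_notation = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    alt <- switch(sites$specificity[i],
                  focal_specific_strict = sites$focal[i],
                  sister_specific_strict = sites$sister[i],
                  sites$focal[i])
    ref <- if (alt == sites$ref[i]) strsplit(sites$alt[i], ",")[[1]][1]
           else sites$ref[i]
    if (sites$position[i] <= aln$frame_offset) {
      eff <- effect_record(NA_integer_, NA_integer_, NA, NA, "undetermined")
    } else {
      eff <- coding_effect(aln, sites$position[i], alt_base = alt,
                           ref_base = ref)
    }
    add$codon_index[i] <- eff$codon_index
    add$codon_position[i] <- eff$codon_position
    add$ref_codon[i] <- as.character(eff$ref_codon)
    add$alt_codon[i] <- as.character(eff$alt_codon)
    add$ref_aa[i] <- as.character(eff$ref_aa)
    add$alt_aa[i] <- as.character(eff$alt_aa)
    add$kind[i] <- eff$kind
    add$nt_notation[i] <- sprintf("%s %d %s", ref, sites$position[i], alt)
    add$aa_notation[i] <- if (eff$kind %in% c("undetermined")) NA_character_
      else sprintf("%s %d %s", eff$ref_aa, eff$codon_index, eff$alt_aa)
  }
  out <- cbind(sites, add)
  attr(out, "excluded") <- attr(sites, "excluded")
  out
}
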