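# Candidate-gene assembly: the quartet screen (positive selection by M0
# plus strict focal-specific non-synonymous substitutions) and the
# two-species comparative screen (per-species species-specific
# non-synonymous SNP sets intersected with the pairwise omega filter).

qualifying_sites <- function(sites, side = c("focal", "sister"),
                             specificity_mode = c("strict", "pairwise")) {
  side <- match.arg(side)
  specificity_mode <- match.arg(specificity_mode)
  if (!nrow(sites)) return(sites[0, ])
  nonsyn <- sites$kind == "non_synonymous"
  hit <- if (specificity_mode == "strict") {
    want <- if (side == "focal") "focal_specific_strict" else "sister_specific_strict"
    sites$specificity == want
  } else {
    sites$focal != sites$sister
  }
  sites[hit & nonsyn, , drop = FALSE]
}

#' Quartet candidate-gene screen
#'
#' A gene is a candidate iff its M0 omega estimate exceeds 1 and it
#' carries at least one strictly focal-specific non-synonymous
#' substitution (the focal base differs while sister and both outgroups
#' are unanimous, polarizing the allele as derived on the focal lineage).
#' `specificity_mode = "pairwise"` relaxes the site criterion to any
#' non-synonymous focal/sister difference, for auditing the looser screen.
#'
#' @param alns named list of trimmed `codon_alignment` objects.
#' @param omega_map data.frame from [screen_omega()] with method
#'   `"GY94_M0"`.
#' @param specificity_mode `"strict"` (default) or `"pairwise"`.
#' @return List of class `candidate_set`: `genes` (data.frame with
#'   `orthogroup_id`, `omega`, `n_snps`, `nt_changes`, `aa_changes`) and
#'   `sites` (all qualifying sites, annotated).
#' @export
approach1 <- function(alns, omega_map, specificity_mode = "strict") {
  sel <- omega_map$omega_defined & !is.na(omega_map$omega) & omega_map$omega > 1
  pos_ids <- omega_map$orthogroup_id[sel]
  genes <- list(); all_sites <- list()
  for (id in pos_ids) {
    a <- alns[[id]]
    if (is.null(a)) next
    sites <- annotate_sites(a, call_variant_sites(a))
    q <- qualifying_sites(sites, "focal", specificity_mode)
    if (!nrow(q)) next
    omega <- omega_map$omega[omega_map$orthogroup_id == id][1]
    genes[[id]] <- data.frame(
      orthogroup_id = id, omega = omega, n_snps = nrow(q),
      nt_changes = paste(q$nt_notation, collapse = "; "),
      aa_changes = paste(q$aa_notation, collapse = "; "),
      stringsAsFactors = FALSE)
    all_sites[[id]] <- q
  }
  out <- list(
    genes = if (length(genes)) do.call(rbind, c(genes, make.row.names = FALSE))
            else data.frame(orthogroup_id = character(0), omega = numeric(0),
                            n_snps = integer(0), nt_changes = character(0),
                            aa_changes = character(0)),
    sites = if (length(all_sites))
              do.call(rbind, c(all_sites, make.row.names = FALSE))
            else NULL)
  class(out) <- "candidate_set"
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidate genes\n", nrow(x$genes)))
  if (nrow(x$genes)) {
    counts <- table(x$genes$n_snps)
    cat("  substitutions per gene:",
        paste(sprintf("%s had %s", counts, names(counts)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Set-algebra summary of two species' candidate sets
#'
#' @param set_focal,set_sister character vectors of orthogroup ids.
#' @return Named list: sizes, intersection and unique counts
#'   (`unique = size - intersection`, by inclusion-exclusion).
#' @export
species_set_counts <- function(set_focal, set_sister) {
  set_focal <- unique(set_focal); set_sister <- unique(set_sister)
  inter <- length(intersect(set_focal, set_sister))
  list(n_focal = length(set_focal), n_sister = length(set_sister),
       n_intersection = inter,
       unique_focal = length(set_focal) - inter,
       unique_sister = length(set_sister) - inter)
}

#' Two-species comparative candidate screen
#'
#' Builds, per species, the set of orthogroups carrying at least one
#' species-specific non-synonymous SNP, then applies one shared pairwise
#' omega filter (NG86 on the focal/sister pair, omega > 1) to both sets.
#' Genes qualifying for both species (at different sites) form the
#' intersection; unique counts follow by set difference.
#'
#' @param alns named list of trimmed `codon_alignment` objects.
#' @param pair_omega_map data.frame from [screen_omega()] with method
#'   `"NG86_focal_pair"`.
#' @param specificity_mode `"strict"` or `"pairwise"`.
#' @return List of class `species_candidate_sets`: `set_focal`,
#'   `set_sister` (character vectors after the omega filter), `counts`
#'   (from [species_set_counts()]), and `pre_omega` (the per-species sets
#'   before the omega filter).
#' @export
approach2 <- function(alns, pair_omega_map, specificity_mode = "strict") {
  pre_f <- character(0); pre_s <- character(0)
  for (id in names(alns)) {
    a <- alns[[id]]
    sites <- annotate_sites(a, call_variant_sites(a))
    if (nrow(qualifying_sites(sites, "focal", specificity_mode))) {
      pre_f <- c(pre_f, id)
    }
    if (nrow(qualifying_sites(sites, "sister", specificity_mode))) {
      pre_s <- c(pre_s, id)
    }
  }
  m <- pair_omega_map
  pos <- m$orthogroup_id[m$omega_defined & !is.na(m$omega) & m$omega > 1]
  set_f <- intersect(pre_f, pos)
  set_s <- intersect(pre_s, pos)
  out <- list(set_focal = set_f, set_sister = set_s,
              counts = species_set_counts(set_f, set_s),
              pre_omega = list(set_focal = pre_f, set_sister = pre_s))
  class(out) <- "species_candidate_sets"
  out
}

#' @export
print.species_candidate_sets <- function(x, ...) {
  c <- x$counts
  cat("<species_candidate_sets>\n")
  cat(sprintf("  focal: %d (unique %d)   sister: %d (unique %d)   shared: %d\n",
              c$n_focal, c$unique_focal, c$n_sister, c$unique_sister,
              c$n_intersection))
  invisible(x)
}
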