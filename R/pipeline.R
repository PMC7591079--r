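# End-to-end orchestration: trim -> filter -> SNP call -> omega screens ->
# candidate screens -> annotation statistics, with every intermediate
# table written and a manifest recording configuration, seed and row
# counts per stage for reproducibility.

# per-term counts of set members annotated to each term
term_counts_from_sets <- function(anno, set_focal, set_sister,
                                  term_col = "term_id") {
  terms <- sort(unique(anno[[term_col]]))
  cf <- vapply(terms, function(t) {
    length(intersect(set_focal,
                     anno$orthogroup_id[anno[[term_col]] == t]))
  }, integer(1))
  cs <- vapply(terms, function(t) {
    length(intersect(set_sister,
                     anno$orthogroup_id[anno[[term_col]] == t]))
  }, integer(1))
  data.frame(term_id = terms, count_focal = cf, count_sister = cs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full screening pipeline
#'
#' Trims and filters the orthogroup alignments, calls and classifies
#' variant sites, runs the requested omega screens, assembles the quartet
#' candidate list (approach "quartet") and/or the two-species comparative
#' sets (approach "pairwise") with their annotation statistics, writes all
#' intermediate tables to `out_dir` (if given), and returns everything
#' with a manifest.
#'
#' @param alignments named list of `codon_alignment` objects, or a FASTA
#'   path (then `roles` is required).
#' @param go,kegg annotation data.frames (may be NULL; annotation
#'   statistics are then skipped).
#' @param roles [species_roles()] used when reading FASTA.
#' @param filter [filter_config()].
#' @param tests [test_config()].
#' @param approaches subset of `c("quartet", "pairwise")`.
#' @param specificity_mode `"strict"` or `"pairwise"` site criterion.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param out_dir output directory for TSV/JSON artifacts, or NULL.
#' @return List of class `pipeline_result`: `filter_report`, `sites`,
#'   `omega_m0`, `omega_pair`, `candidates`, `species_sets`,
#'   `term_scan`, `levelA`, `levelB`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(alignments, go = NULL, kegg = NULL, roles = NULL,
                         filter = filter_config(), tests = test_config(),
                         approaches = c("quartet", "pairwise"),
                         specificity_mode = "strict",
                         seed = 1L, out_dir = NULL) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  if (is.character(alignments)) {
    if (is.null(roles)) stop("roles are required when reading FASTA")
    alignments <- read_alignments(alignments, roles)
  }
  n_input <- length(alignments)
  trimmed <- lapply(alignments, trim_to_frame)
  flt <- filter_orthogroups(trimmed, filter)
  kept <- flt$kept

  sites <- do.call(rbind, c(lapply(kept, function(a)
    annotate_sites(a, call_variant_sites(a))), make.row.names = FALSE))

  res <- list(filter_report = flt$report, sites = sites,
              omega_m0 = NULL, omega_pair = NULL,
              candidates = NULL, species_sets = NULL,
              term_scan = NULL, levelA = NULL, levelB = NULL,
              enrichment = NULL)

  if ("quartet" %in% approaches) {
    res$omega_m0 <- screen_omega(kept, "GY94_M0")
    res$candidates <- approach1(kept, res$omega_m0, specificity_mode)
  }
  if ("pairwise" %in% approaches) {
    res$omega_pair <- screen_omega(kept, "NG86_focal_pair")
    res$species_sets <- approach2(kept, res$omega_pair, specificity_mode)
    if (!is.null(go)) {
      tc <- term_counts_from_sets(go, res$species_sets$set_focal,
                                  res$species_sets$set_sister)
      res$term_scan <- term_ratio_scan(tc, tests)
      cand_all <- union(res$species_sets$set_focal,
                        res$species_sets$set_sister)
      if (length(cand_all))
        res$enrichment <- enrichment_vs_transcriptome(
          go[go$orthogroup_id %in% cand_all, , drop = FALSE], go,
          candidate_genes = cand_all,
          transcriptome_genes = names(kept), config = tests)
    }
    if (!is.null(kegg)) {
      ka <- unique(kegg[, c("orthogroup_id", "level_a")])
      names(ka)[2] <- "term_id"
      la <- term_counts_from_sets(ka, res$species_sets$set_focal,
                                  res$species_sets$set_sister)
      names(la)[1] <- "category"
      totals <- c(
        focal = length(intersect(res$species_sets$set_focal,
                                 unique(kegg$orthogroup_id))),
        sister = length(intersect(res$species_sets$set_sister,
                                  unique(kegg$orthogroup_id))))
      if (all(totals > 0) && nrow(la))
        res$levelA <- levelA_fisher(la, totals, tests)
      # level B chi-squared within each level A category
      res$levelB <- list()
      for (cat in unique(kegg$level_a)) {
        kb <- unique(kegg[kegg$level_a == cat,
                          c("orthogroup_id", "level_b")])
        names(kb)[2] <- "term_id"
        bc <- term_counts_from_sets(kb, res$species_sets$set_focal,
                                    res$species_sets$set_sister)
        tab <- as.matrix(bc[, c("count_focal", "count_sister")])
        rownames(tab) <- bc$term_id
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]
        if (nrow(tab) >= 2 && all(colSums(tab) > 0))
          res$levelB[[cat]] <- levelB_chi2(tab)
      }
    }
  }

  res$manifest <- list(
    seed = seed,
    approaches = approaches,
    specificity_mode = specificity_mode,
    filter = unclass(filter),
    tests = unclass(tests)[c("alpha", "fdr", "ci_method")],
    counts = list(
      input = n_input,
      kept = length(kept),
      dropped = n_input - length(kept),
      variant_sites = if (is.null(sites)) 0L else nrow(sites),
      candidates = if (is.null(res$candidates)) NA_integer_
                   else nrow(res$candidates$genes),
      set_focal = if (is.null(res$species_sets)) NA_integer_
                  else res$species_sets$counts$n_focal,
      set_sister = if (is.null(res$species_sets)) NA_integer_
                   else res$species_sets$counts$n_sister))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(flt$report, "filter_report.tsv")
    wt(sites, "sites.tsv")
    wt(res$omega_m0, "omega_m0.tsv")
    wt(res$omega_pair, "omega_pair.tsv")
    if (!is.null(res$candidates)) wt(res$candidates$genes, "candidates.tsv")
    wt(res$term_scan, "term_ratio_scan.tsv")
    wt(res$levelA, "kegg_levelA_fisher.tsv")
    wt(res$enrichment, "go_enrichment.tsv")
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat(sprintf("  orthogroups: %d in, %d kept, %d dropped\n",
              m$input, m$kept, m$dropped))
  cat(sprintf("  variant sites: %d\n", m$variant_sites))
  if (!is.na(m$candidates))
    cat(sprintf("  quartet candidates: %d\n", m$candidates))
  if (!is.na(m$set_focal))
    cat(sprintf("  comparative sets: focal %d, sister %d\n",
                m$set_focal, m$set_sister))
  invisible(x)
}
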