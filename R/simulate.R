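# Synthetic-study generator: codon alignments evolved on the quartet
# topology under GY94 with per-branch selection regimes, planted
# focal-lineage non-synonymous substitutions, planted filter contaminants,
# and GO/KEGG annotation tables — all tied to a ground-truth ledger so
# every downstream stage can be scored against what was planted.

#' Simulation configuration
#'
#' Defaults describe a quartet of closely related fish species with a more
#' distant outgroup pair: short terminal branches (~2-6 substitutions per
#' 100 codons), transition bias kappa = 2, strong purifying selection on
#' background genes (omega = 0.2) and positive selection (omega = 3) on
#' candidate genes, whose focal terminal branch is further elevated by
#' `focal_branch_omega_multiplier`. Candidate genes additionally carry
#' 1-3 planted focal-specific non-synonymous substitutions at otherwise
#' conserved codons, so site-level truth is exact.
#'
#' @param n_genes number of orthogroups (contaminants included).
#' @param gene_length_codons length range (codons) sampled uniformly.
#' @param branch_lengths named vector (focal, sister, out1, out2,
#'   internal), expected substitutions per codon.
#' @param kappa transition/transversion rate ratio.
#' @param omega_background,omega_candidate dN/dS for the two gene classes.
#' @param focal_branch_omega_multiplier factor applied to the candidate
#'   omega on the focal terminal branch.
#' @param fraction_candidates proportion of non-contaminant genes planted
#'   as candidates.
#' @param planted_snps_per_candidate inclusive range of focal-specific
#'   non-synonymous substitutions planted per candidate gene.
#' @param contamination named counts `c(identity = ..., short = ...)` of
#'   planted filter violations (low pairwise identity; length < 200 bp).
#' @param n_go_terms,n_kegg_pathways_per_b sizes of the annotation universe.
#' @param planted_go_enriched number of GO terms planted as enriched among
#'   candidate genes relative to the transcriptome.
#' @param seed master seed; per-gene seeds derive from it by the counter
#'   scheme `(seed + 7919 * gene_index) mod (2^31 - 1)`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length_codons = c(100L, 300L),
                       branch_lengths = c(focal = 0.02, sister = 0.02,
                                          out1 = 0.04, out2 = 0.06,
                                          internal = 0.02),
                       kappa = 2,
                       omega_background = 0.2,
                       omega_candidate = 3,
                       focal_branch_omega_multiplier = 2,
                       fraction_candidates = 0.1,
                       planted_snps_per_candidate = c(1L, 3L),
                       contamination = c(identity = 0L, short = 0L),
                       n_go_terms = 30L,
                       n_kegg_pathways_per_b = 2L,
                       planted_go_enriched = 0L,
                       seed = 1L) {
  rates <- c(branch_lengths, kappa, omega_background, omega_candidate,
             focal_branch_omega_multiplier)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (fraction_candidates < 0 || fraction_candidates > 1)
    stop("fraction_candidates must lie in [0, 1]")
  gene_length_codons <- as.integer(gene_length_codons)
  if (any(gene_length_codons < 1L)) stop("gene lengths must be >= 1 codon")
  stopifnot(all(c("focal", "sister", "out1", "out2", "internal") %in%
                  names(branch_lengths)))
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_codons = gene_length_codons,
                 branch_lengths = branch_lengths, kappa = kappa,
                 omega_background = omega_background,
                 omega_candidate = omega_candidate,
                 focal_branch_omega_multiplier = focal_branch_omega_multiplier,
                 fraction_candidates = fraction_candidates,
                 planted_snps_per_candidate = as.integer(planted_snps_per_candidate),
                 contamination = contamination,
                 n_go_terms = as.integer(n_go_terms),
                 n_kegg_pathways_per_b = as.integer(n_kegg_pathways_per_b),
                 planted_go_enriched = as.integer(planted_go_enriched),
                 seed = as.integer(seed)),
            class = "sim_config")
}

gene_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% (2^31 - 1))
}

# per-branch omega vector for a gene class
branch_omegas <- function(config, gene_class) {
  w <- switch(gene_class,
              background = rep(config$omega_background, 5),
              contaminant_identity = rep(config$omega_background, 5),
              contaminant_short = rep(config$omega_background, 5),
              candidate = {
                v <- rep(config$omega_candidate, 5)
                v[1] <- v[1] * config$focal_branch_omega_multiplier
                v
              },
              stop("unknown gene class: ", gene_class))
  names(w) <- c("focal", "sister", "out1", "out2", "internal")
  w
}

# evolve one column-set of codon states down one branch (vectorized over
# identical parent states)
evolve_branch <- function(parent_states, P) {
  child <- integer(length(parent_states))
  for (p in unique(parent_states)) {
    sel <- parent_states == p
    child[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE, prob = P[p, ])
  }
  child
}

#' Simulate one quartet codon alignment
#'
#' Evolves a gap-free, in-frame alignment of four sequences from a
#' stationary root along `((focal, sister), out1, out2)` under GY94
#' transition matrices; substitutions into stop codons have rate zero, so
#' internal stops never arise. For candidate genes, focal-specific
#' non-synonymous substitutions are planted at codons conserved across all
#' four simulated sequences (guaranteeing strict specificity of the
#' planted sites) and their alignment positions recorded.
#'
#' @param config a [sim_config()].
#' @param gene_class `"background"`, `"candidate"`,
#'   `"contaminant_identity"` or `"contaminant_short"`.
#' @param seed integer seed for this gene.
#' @param orthogroup_id id for the returned alignment.
#' @param n_codons gene length; defaults to a draw from the configured
#'   range (contaminant_short draws 30-66 codons, i.e. < 200 bp).
#' @return `codon_alignment` with taxa `focal, sister, out1, out2`;
#'   attribute `planted_positions` (1-based nucleotide positions of planted
#'   substitutions) and `omega_branches`.
#' @export
simulate_alignment <- function(config, gene_class = "background",
                               seed = config$seed,
                               orthogroup_id = "OG0000001",
                               n_codons = NULL) {
  set.seed(seed)
  tb <- codon_tables()
  rng <- config$gene_length_codons
  if (is.null(n_codons)) {
    n_codons <- if (gene_class == "contaminant_short")
      sample(30:66, 1) else
      if (length(rng) > 1) sample(rng[1]:rng[2], 1) else rng
  }
  w <- branch_omegas(config, gene_class)
  t <- config$branch_lengths[c("focal", "sister", "out1", "out2", "internal")]
  Ps <- lapply(seq_along(w), function(k) {
    Q <- gy94_rate_matrix(config$kappa, w[k])
    gy94_pmats(Q, t[k])[[1]]
  })
  pi <- rep(1 / 61, 61)
  root <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  node_out <- evolve_branch(root, Ps[[5]])       # internal branch
  states <- list(focal = evolve_branch(root, Ps[[1]]),
                 sister = evolve_branch(root, Ps[[2]]),
                 out1 = evolve_branch(node_out, Ps[[3]]),
                 out2 = evolve_branch(node_out, Ps[[4]]))

  planted <- integer(0)
  if (gene_class == "candidate") {
    k <- sample(config$planted_snps_per_candidate[1]:
                  config$planted_snps_per_candidate[2], 1)
    conserved <- which(states$focal == states$sister &
                         states$sister == states$out1 &
                         states$out1 == states$out2)
    k <- min(k, length(conserved))
    for (cod in conserved[sample.int(length(conserved), k)]) {
      from <- states$focal[cod]
      opts <- tb$pairs[tb$pairs$from == from & !tb$pairs$synonymous, ]
      pick <- opts[sample.int(nrow(opts), 1), ]
      states$focal[cod] <- pick$to
      planted <- c(planted, 3L * (cod - 1L) + pick$pos)
    }
    planted <- sort(planted)
  }

  seqs <- vapply(states, function(st)
    paste(tb$codons[st], collapse = ""), character(1))

  if (gene_class == "contaminant_identity") {
    # scramble a quarter of the focal sequence: identity <= 0.75 + noise,
    # safely below any 90% threshold
    len <- nchar(seqs[["focal"]])
    cols <- sample.int(len, ceiling(0.25 * len))
    ch <- strsplit(seqs[["focal"]], "")[[1]]
    for (j in cols) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    seqs[["focal"]] <- paste(ch, collapse = "")
  }

  aln <- codon_alignment(orthogroup_id, seqs, 0L)
  attr(aln, "planted_positions") <- planted
  attr(aln, "omega_branches") <- w
  aln
}

#' Simulate a complete synthetic study
#'
#' Generates `n_genes` orthogroup alignments (candidates, background and
#' contaminants), GO and KEGG annotation tables, and a truth ledger.
#' Class assignment is deterministic in the config: the first
#' `contamination` genes are contaminants, then `fraction_candidates` of
#' the remainder are candidates. GO terms are assigned independently at a
#' background rate; terms planted as enriched attach to candidate genes
#' with high probability (0.9 vs 0.05 background), giving
#' candidate-vs-transcriptome enrichment a known positive control.
#'
#' @param config a [sim_config()].
#' @param dir if non-NULL, writes `alignments.fasta`, `go.tsv`,
#'   `kegg.tsv` and `truth.json` there.
#' @return List with `alignments` (named list), `go` and `kegg`
#'   (data.frames), and `truth` (list with `genes` data.frame and `terms`
#'   data.frame).
#' @export
simulate_study <- function(config, dir = NULL) {
  n_id <- as.integer(config$contamination[["identity"]])
  n_sh <- as.integer(config$contamination[["short"]])
  n_clean <- config$n_genes - n_id - n_sh
  if (n_clean < 0) stop("contamination counts exceed n_genes")
  n_cand <- round(config$fraction_candidates * n_clean)
  classes <- c(rep("contaminant_identity", n_id),
               rep("contaminant_short", n_sh),
               rep("candidate", n_cand),
               rep("background", n_clean - n_cand))
  ids <- sprintf("OG%07d", seq_len(config$n_genes))

  alns <- vector("list", config$n_genes)
  planted <- character(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    alns[[i]] <- simulate_alignment(config, classes[i],
                                    seed = gene_seed(config$seed, i),
                                    orthogroup_id = ids[i])
    pp <- attr(alns[[i]], "planted_positions")
    planted[i] <- paste(pp, collapse = ",")
  }
  names(alns) <- ids

  genes <- data.frame(
    gene_id = ids, class = classes,
    length_bp = vapply(alns, `[[`, numeric(1), "length"),
    omega_focal = vapply(classes, function(cl)
      branch_omegas(config, cl)[["focal"]], numeric(1)),
    omega_other = vapply(classes, function(cl)
      branch_omegas(config, cl)[["sister"]], numeric(1)),
    planted_positions = planted,
    stringsAsFactors = FALSE, row.names = NULL)

  # annotation tables (seeded after the alignments, same master seed)
  set.seed(gene_seed(config$seed, config$n_genes + 1L))
  anno <- simulate_annotation_tables(config, ids, classes)

  truth <- list(genes = genes, terms = anno$terms)
  out <- list(alignments = alns, go = anno$go, kegg = anno$kegg,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_alignments(alns, file.path(dir, "alignments.fasta"))
    utils::write.table(anno$go, file.path(dir, "go.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(anno$kegg, file.path(dir, "kegg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

# KEGG hierarchy used by the generator: the six canonical level A
# categories, a few level B children each.
kegg_hierarchy <- function() {
  list(
    "Metabolism" = c("Carbohydrate metabolism", "Energy metabolism",
                     "Lipid metabolism"),
    "Genetic Information Processing" = c("Transcription", "Translation",
                                         "Replication and repair"),
    "Environmental Information Processing" = c("Signal transduction",
                                               "Membrane transport"),
    "Cellular Processes" = c("Cell growth and death", "Transport and catabolism"),
    "Organismal Systems" = c("Immune system", "Nervous system",
                             "Circulatory system"),
    "Human Diseases" = c("Cancer: specific types", "Infectious disease"))
}

simulate_annotation_tables <- function(config, ids, classes) {
  n <- length(ids)
  go_ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  go_names <- sprintf("synthetic term %d", seq_len(config$n_go_terms))
  cats <- c("biological_process", "molecular_function", "cellular_component")
  go_cat <- sample(cats, config$n_go_terms, replace = TRUE)
  base_p <- stats::runif(config$n_go_terms, 0.02, 0.10)
  enriched <- integer(0)
  if (config$planted_go_enriched > 0)
    enriched <- seq_len(config$planted_go_enriched)
  rows <- list()
  for (t in seq_len(config$n_go_terms)) {
    p_cand <- if (t %in% enriched) 0.9 else base_p[t]
    p_back <- if (t %in% enriched) 0.05 else base_p[t]
    p <- ifelse(classes == "candidate", p_cand, p_back)
    hit <- stats::runif(n) < p
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup_id = ids[hit], term_id = go_ids[t],
        term_name = go_names[t], category = go_cat[t],
        stringsAsFactors = FALSE)
  }
  go <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup_id = character(0), term_id = character(0),
               term_name = character(0), category = character(0))

  kh <- kegg_hierarchy()
  level_a <- rep(names(kh), vapply(kh, length, integer(1)))
  level_b <- unlist(kh, use.names = FALSE)
  npw <- config$n_kegg_pathways_per_b
  pw_a <- rep(level_a, each = npw)
  pw_b <- rep(level_b, each = npw)
  pw <- sprintf("map%05d", seq_along(pw_a))
  has_kegg <- stats::runif(n) < 0.6
  pick <- sample.int(length(pw), sum(has_kegg), replace = TRUE)
  kegg <- data.frame(orthogroup_id = ids[has_kegg],
                     ko = sprintf("K%05d", pick),
                     pathway = pw[pick],
                     level_b = pw_b[pick],
                     level_a = pw_a[pick],
                     stringsAsFactors = FALSE)
  terms <- data.frame(term_id = go_ids,
                      planted_enriched = seq_len(config$n_go_terms) %in% enriched,
                      stringsAsFactors = FALSE)
  list(go = go, kegg = kegg, terms = terms)
}

#' Simulate per-term two-species count tables with planted asymmetries
#'
#' Generates the count structure consumed by [term_ratio_scan()]: null
#' terms draw their focal count from Binomial(n, 0.5); planted terms use
#' the specified asymmetric split. Used to calibrate and power-test the
#' 50:50 acceptance-region scan independently of sequence simulation.
#'
#' @param n_terms number of null terms.
#' @param n_range range of per-term totals (sampled uniformly).
#' @param planted data.frame with columns `count_focal`, `count_sister`
#'   (one planted term per row), or NULL.
#' @param seed integer seed.
#' @return data.frame `term_id`, `count_focal`, `count_sister`, `planted`.
#' @export
simulate_term_counts <- function(n_terms = 50L, n_range = c(2L, 60L),
                                 planted = NULL, seed = 1L) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], n_terms, replace = TRUE)
  cf <- stats::rbinom(n_terms, n, 0.5)
  out <- data.frame(term_id = sprintf("TERM:%04d", seq_len(n_terms)),
                    count_focal = cf, count_sister = n - cf,
                    planted = FALSE, stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    pl <- data.frame(term_id = sprintf("PLANT:%04d", seq_len(nrow(planted))),
                     count_focal = planted$count_focal,
                     count_sister = planted$count_sister,
                     planted = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out, pl)
  }
  out
}
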