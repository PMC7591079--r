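# Minimal VCF 4.2 emitter for alignment-called sites: CHROM is the
# orthogroup id, POS the 1-based alignment column, samples are the four
# haploid taxa in role order. INFO carries the specificity class and the
# coding effect so downstream consumers need no side table.

#' Write called sites as VCF 4.2
#'
#' @param aln the `codon_alignment` the sites were called on.
#' @param sites sites table from [call_variant_sites()] (optionally
#'   annotated with [annotate_sites()]).
#' @param path output file.
#' @param roles optional [species_roles()]; taxon labels for the sample
#'   columns (defaults to the alignment's sequence names).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(aln, sites, path, roles = NULL) {
  taxa <- if (is.null(roles)) names(aln$seqs) else unname(roles)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", aln$orthogroup_id, aln$length),
    "##INFO=<ID=SPEC,Number=1,Type=String,Description=\"Species-specificity class\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect kind\">",
    "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino acid change (ref_aa codon_index alt_aa)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", taxa), collapse = "\t"))
  body <- character(0)
  if (nrow(sites)) {
    body <- vapply(seq_len(nrow(sites)), function(i) {
      alleles <- c(sites$ref[i], strsplit(sites$alt[i], ",")[[1]])
      gt <- vapply(c(sites$focal[i], sites$sister[i],
                     sites$out1[i], sites$out2[i]),
                   function(b) as.character(match(b, alleles) - 1L),
                   character(1))
      info <- sprintf("SPEC=%s", sites$specificity[i])
      if ("kind" %in% names(sites)) {
        info <- paste0(info, ";EFF=", sites$kind[i])
        if (!is.na(sites$aa_notation[i]))
          info <- paste0(info, ";AAC=", gsub(" ", "_", sites$aa_notation[i]))
      }
      paste(c(sites$orthogroup_id[i], sites$position[i], ".",
              sites$ref[i], sites$alt[i], ".", "PASS", info, "GT", gt),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
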