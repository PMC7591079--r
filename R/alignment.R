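# The per-orthogroup alignment container and species-role configuration.
# An orthogroup alignment holds exactly four equal-length nucleotide
# sequences (one per taxon); coordinates are 1-based alignment columns
# throughout the package.

#' Species role assignment on the quartet tree
#'
#' The analysis runs on the fixed unrooted topology
#' `((focal, sister), out1, out2)`: the focal taxon carries the derived
#' phenotype, the sister taxon is its closest relative, and two outgroups
#' polarize lineage-specific alleles.
#'
#' @param focal,sister,out1,out2 taxon labels as they appear in FASTA
#'   headers.
#' @return Named character vector of class `species_roles`.
#' @export
species_roles <- function(focal, sister, out1, out2) {
  r <- c(focal = focal, sister = sister, out1 = out1, out2 = out2)
  if (anyDuplicated(r)) stop("species roles must be distinct taxa")
  class(r) <- "species_roles"
  r
}

#' Construct a codon alignment
#'
#' @param orthogroup_id single string identifying the orthogroup.
#' @param seqs named character vector: taxon -> nucleotide string over
#'   `A,C,G,T,N,-`. Exactly four taxa, all sequences the same length.
#' @param frame_offset 0-based count of alignment columns before the first
#'   complete codon (default 0).
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(orthogroup_id, seqs, frame_offset = 0L) {
  if (length(seqs) != 4L || is.null(names(seqs)))
    stop("a codon alignment needs exactly 4 named sequences")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("unequal sequence lengths in orthogroup %s", orthogroup_id))
  if (any(grepl("[^ACGTN-]", seqs)))
    stop(sprintf("invalid characters in orthogroup %s", orthogroup_id))
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L) stop("frame_offset must be >= 0")
  if (lens[1] - frame_offset < 3L)
    stop("alignment too short for a single codon after the frame offset")
  structure(list(orthogroup_id = as.character(orthogroup_id),
                 seqs = seqs,
                 frame_offset = frame_offset,
                 length = unname(lens[1])),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s: %d taxa x %d columns (frame offset %d)\n",
              x$orthogroup_id, length(x$seqs), x$length, x$frame_offset))
  invisible(x)
}

# character matrix view (taxa x columns), used by several modules
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  m
}

#' Read orthogroup alignments from FASTA
#'
#' Headers follow the `{orthogroup_id}|{taxon}` convention; a single file
#' may hold one orthogroup or many (grouping is by the header prefix).
#' Orthogroups missing one of the four role-assigned taxa, or with unequal
#' sequence lengths, are skipped with a warning.
#'
#' @param path FASTA file.
#' @param roles a [species_roles()] object.
#' @param frame_offset frame offset applied to every alignment (per-gene
#'   offsets can be set on the returned objects).
#' @return Named list of `codon_alignment` objects, keyed by orthogroup id.
#' @export
read_alignments <- function(path, roles, frame_offset = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  if (any(!grepl("|", hdr, fixed = TRUE)))
    stop("malformed FASTA header (expected '{orthogroup}|{taxon}'): ",
         hdr[!grepl("|", hdr, fixed = TRUE)][1])
  og <- sub("\\|.*$", "", hdr)
  taxon <- sub("^[^|]*\\|", "", hdr)
  out <- list()
  for (g in unique(og)) {
    sel <- og == g
    tx <- taxon[sel]
    sq <- as.character(ss[sel])
    names(sq) <- tx
    if (!all(roles %in% tx)) {
      warning(sprintf("orthogroup %s: missing taxon, skipped", g))
      next
    }
    sq <- sq[unname(roles)]          # role order: focal, sister, out1, out2
    if (length(unique(nchar(sq))) != 1L) {
      warning(sprintf("orthogroup %s: unequal sequence lengths, skipped", g))
      next
    }
    out[[g]] <- codon_alignment(g, sq, frame_offset)
  }
  out
}

#' Write orthogroup alignments to FASTA
#'
#' @param alns list of `codon_alignment` objects.
#' @param path output file.
#' @export
write_alignments <- function(alns, path) {
  lines <- unlist(lapply(alns, function(a) {
    as.vector(rbind(sprintf(">%s|%s", a$orthogroup_id, names(a$seqs)),
                    unname(a$seqs)))
  }))
  writeLines(lines, path)
  invisible(path)
}
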