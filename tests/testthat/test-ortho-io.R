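# Alignment I/O, frame trimming, pairwise identity and the orthogroup
# filters.

roles <- species_roles("tsho", "comp", "tama", "pete")

test_that("FASTA round trip preserves sequences and grouping", {
  st <- simulate_study(fast_config())
  f <- tempfile(fileext = ".fasta")
  write_alignments(st$alignments, f)
  rd <- read_alignments(f, species_roles("focal", "sister", "out1", "out2"))
  expect_setequal(names(rd), names(st$alignments))
  expect_identical(rd[[3]]$seqs, st$alignments[[3]]$seqs)

  # grouping equals an independent header scan
  lines <- readLines(f)
  hdr <- lines[startsWith(lines, ">")]
  oracle_groups <- table(sub("\\|.*$", "", sub("^>", "", hdr)))
  expect_equal(length(rd), length(oracle_groups))
  expect_true(all(vapply(rd, function(a) length(a$seqs), integer(1)) == 4))
})

test_that("orthogroups with a missing taxon are skipped with a warning", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">OG1|tsho", "ATGAAA", ">OG1|comp", "ATGAAA",
               ">OG1|tama", "ATGAAA", ">OG1|pete", "ATGAAA",
               ">OG2|tsho", "ATGCCC", ">OG2|comp", "ATGCCC",
               ">OG2|tama", "ATGCCC"), f)
  expect_warning(rd <- read_alignments(f, roles), "missing taxon")
  expect_identical(names(rd), "OG1")
})

test_that("unequal lengths within an orthogroup are rejected", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">OG1|tsho", "ATGAAA", ">OG1|comp", "ATGAAACCC",
               ">OG1|tama", "ATGAAA", ">OG1|pete", "ATGAAA"), f)
  expect_warning(rd <- read_alignments(f, roles), "unequal")
  expect_length(rd, 0)
})

test_that("trim_to_frame handles offsets and trailing partial codons", {
  # length 12, offset 0: unchanged
  a <- edited_quartet("ATGAAACCCGGG")
  expect_identical(trim_to_frame(a)$seqs, a$seqs)
  # length 14, offset 1: columns 2..13 kept
  b <- edited_quartet("TATGAAACCCGGGA", offset = 1L)
  tb <- trim_to_frame(b)
  expect_equal(tb$length, 12)
  expect_identical(unname(tb$seqs[1]), "ATGAAACCCGGG")
  expect_equal(tb$frame_offset, 0)
  # length 5, offset 0: columns 1..3 kept
  cc <- edited_quartet("ATGAA")
  expect_identical(unname(trim_to_frame(cc)$seqs[1]), "ATG")
  # idempotent
  expect_identical(trim_to_frame(tb), tb)
})

test_that("pairwise identity counts comparable columns only", {
  expect_equal(pairwise_identity(strrep("A", 100), strrep("A", 100)), 1.0)
  a <- paste(c(rep("A", 90), rep("C", 10)), collapse = "")
  b <- strrep("A", 100)
  expect_equal(pairwise_identity(a, b), 0.90)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACNT", "ACGT"), 1.0)
  expect_error(pairwise_identity("---", "AAA"), "comparable")
  # symmetry on random pairs
  set.seed(12)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE), collapse = "")
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
})

test_that("filters apply thresholds at the documented boundaries", {
  base <- strrep("ATGAAACCCGGGTTTAC", 12)  # 204 bp, stop-free
  ok <- edited_quartet(substr(base, 1, 201), id = "OGOK")
  # identity 0.89 on one pair -> dropped; 0.90 -> kept
  mk_id <- function(frac_mm, id) {
    n <- 200 * 3
    seq0 <- strrep("ATGAAACCCG", 60)
    ch <- strsplit(seq0, "")[[1]]
    mm <- seq_len(round((1 - frac_mm) * nchar(seq0)))
    ch[mm] <- ifelse(ch[mm] == "A", "C", "A")
    quartet(paste(ch, collapse = ""), seq0, seq0, seq0, id = id)
  }
  a89 <- mk_id(0.89, "OG89"); a90 <- mk_id(0.90, "OG90")
  expect_equal(pairwise_identity(a89$seqs[[1]], a89$seqs[[2]]), 0.89)
  expect_equal(pairwise_identity(a90$seqs[[1]], a90$seqs[[2]]), 0.90)
  short <- edited_quartet(substr(base, 1, 198), id = "OGSHORT")  # 198 bp
  res <- filter_orthogroups(list(OGOK = ok, OG89 = a89, OG90 = a90,
                                 OGSHORT = short))
  out <- stats::setNames(res$report$outcome, res$report$orthogroup_id)
  expect_equal(unname(out["OGOK"]), "kept")
  expect_equal(unname(out["OG89"]), "dropped_identity")
  expect_equal(unname(out["OG90"]), "kept")
  expect_equal(unname(out["OGSHORT"]), "dropped_length")
  expect_equal(nrow(res$report), 4)
})

test_that("filtering is order-independent", {
  st <- simulate_study(sim_config(n_genes = 10L, fraction_candidates = 0,
                                  contamination = c(identity = 2L, short = 2L),
                                  gene_length_codons = c(70L, 90L), seed = 14L))
  alns <- lapply(st$alignments, trim_to_frame)
  r1 <- filter_orthogroups(alns)
  perm <- rev(seq_along(alns))
  r2 <- filter_orthogroups(alns[perm])
  o1 <- stats::setNames(r1$report$outcome, r1$report$orthogroup_id)
  o2 <- stats::setNames(r2$report$outcome, r2$report$orthogroup_id)
  expect_identical(o1[sort(names(o1))], o2[sort(names(o2))])
})

test_that("filter drops exactly the planted contaminants", {
  st <- simulate_study(sim_config(n_genes = 16L, fraction_candidates = 0.25,
                                  contamination = c(identity = 3L, short = 2L),
                                  gene_length_codons = c(70L, 90L), seed = 6L))
  res <- filter_orthogroups(lapply(st$alignments, trim_to_frame))
  dropped <- res$report$orthogroup_id[res$report$outcome != "kept"]
  truth <- st$truth$genes$gene_id[grepl("contaminant",
                                        st$truth$genes$class)]
  expect_setequal(dropped, truth)
})
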