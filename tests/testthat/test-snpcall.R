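# Variant calling, specificity polarization and coding effects.

test_that("identical sequences yield no variant sites", {
  a <- edited_quartet("ATGAAACCCGGG")
  expect_equal(nrow(call_variant_sites(a)), 0)
})

test_that("a single deviant column is called at the right position", {
  a <- edited_quartet("ATGAAACCCGGG",
                      list(list("focal", 5L, "C")))
  s <- call_variant_sites(a)
  expect_equal(nrow(s), 1)
  expect_equal(s$position, 5)
  expect_equal(s$focal, "C")
  expect_equal(s$ref, "A")   # majority allele
  expect_equal(s$alt, "C")
  expect_equal(s$specificity, "focal_specific_strict")
})

test_that("gap and N columns are excluded from calling but logged", {
  a <- edited_quartet("ATGAAACCCGGG",
                      list(list("focal", 5L, "-"),
                           list("sister", 8L, "N"),
                           list("out1", 11L, "T")))
  s <- call_variant_sites(a)
  expect_equal(s$position, 11)
  expect_setequal(attr(s, "excluded"), c(5L, 8L))
})

test_that("calling agrees with a brute-force per-column scan", {
  cfg <- fast_config()
  a <- simulate_alignment(cfg, "candidate", seed = 23L, n_codons = 100L)
  s <- call_variant_sites(a)
  m <- do.call(rbind, strsplit(a$seqs, ""))
  oracle <- which(apply(m, 2, function(col)
    all(col %in% c("A", "C", "G", "T")) && length(unique(col)) >= 2))
  expect_identical(s$position, as.integer(oracle))
  expect_identical(s$position, sort(s$position))
})

test_that("specificity classes follow the three-way unanimity rule", {
  expect_equal(classify_specificity(c("G", "A", "A", "A")),
               "focal_specific_strict")
  expect_equal(classify_specificity(c("A", "G", "A", "A")),
               "sister_specific_strict")
  expect_equal(classify_specificity(c("G", "A", "G", "A")),
               "focal_vs_sister_only")
  expect_equal(classify_specificity(c("A", "A", "G", "G")), "shared")
  expect_equal(classify_specificity(c("A", "C", "G", "T")), "other")
  expect_equal(classify_specificity(c("A", "C", "G", "A")), "other")
  expect_equal(classify_specificity(c("A", "C", "N", "A")), "undetermined")
})

test_that("relabeling the outgroups never changes the classification", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f = bases, s = bases, o1 = bases, o2 = bases,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    b <- unlist(grid[i, ])
    expect_identical(classify_specificity(b),
                     classify_specificity(b[c(1, 2, 4, 3)]))
  }
})

test_that("classes are mutually exclusive and exhaustive over variant columns", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f = bases, s = bases, o1 = bases, o2 = bases,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    b <- unlist(grid[i, ])
    cl <- classify_specificity(b)
    expect_length(cl, 1)
    if (length(unique(b)) == 1) {
      expect_equal(cl, "shared")  # degenerate: no variation
    } else {
      expect_true(cl %in% c("focal_specific_strict", "sister_specific_strict",
                            "focal_vs_sister_only", "shared", "other"))
    }
  }
})

test_that("coding effect maps position 110 to codon 37 (V -> A)", {
  # frame offset 0; codon 37 spans columns 109-111 and reads GTG;
  # a T -> C change at its second position gives GCG: V -> A
  base <- paste(c(rep("ATG", 36), "GTG", rep("AAA", 13)), collapse = "")
  a <- edited_quartet(base, list(list("focal", 110L, "C")))
  eff <- coding_effect(a, 110L, alt_base = "C")
  expect_equal(eff$codon_index, 37)
  expect_equal(eff$codon_position, 2)
  expect_equal(eff$ref_codon, "GTG")
  expect_equal(eff$alt_codon, "GCG")
  expect_equal(eff$ref_aa, "V")
  expect_equal(eff$alt_aa, "A")
  expect_equal(eff$kind, "non_synonymous")
})

test_that("third-position wobble change is synonymous", {
  a <- edited_quartet("ATGGTTAAA", list(list("focal", 6L, "C")))
  eff <- coding_effect(a, 6L, alt_base = "C")
  expect_equal(eff$ref_codon, "GTT")
  expect_equal(eff$alt_codon, "GTC")
  expect_equal(eff$kind, "synonymous")
  expect_equal(eff$ref_aa, eff$alt_aa)
})

test_that("first-position AAA -> GAA is K -> E", {
  a <- edited_quartet("ATGAAACCC", list(list("focal", 4L, "G")))
  eff <- coding_effect(a, 4L, alt_base = "G")
  expect_equal(eff$ref_aa, "K")
  expect_equal(eff$alt_aa, "E")
  expect_equal(eff$kind, "non_synonymous")
})

test_that("frame offset shifts the codon map", {
  a <- edited_quartet("TATGAAACCCGGGA", list(list("focal", 5L, "G")),
                      offset = 1L)
  eff <- coding_effect(a, 5L, alt_base = "G")
  expect_equal(eff$codon_index, 2)
  expect_equal(eff$codon_position, 1)
  expect_error(coding_effect(a, 1L, alt_base = "G"), "frame")
})

test_that("gaps inside the codon give an undetermined effect", {
  a <- edited_quartet("ATGAAACCC", list(list("out2", 6L, "-"),
                                        list("focal", 4L, "G")))
  eff <- coding_effect(a, 4L, alt_base = "G")
  expect_equal(eff$kind, "undetermined")
})

test_that("every single-base codon change matches the translate-and-compare oracle", {
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (cod in sense_codons()) {
    ch <- strsplit(cod, "")[[1]]
    for (p in 1:3) for (b in bases) {
      if (b == ch[p]) next
      alt <- ch; alt[p] <- b
      alt_cod <- paste(alt, collapse = "")
      a <- edited_quartet(paste0("ATG", cod, "AAA"),
                          list(list("focal", 3L + p, b)))
      eff <- coding_effect(a, 3L + p, alt_base = b)
      expect_equal(eff$codon_index, 2)
      expect_equal(eff$ref_codon, cod)
      expect_equal(eff$alt_codon, alt_cod)
      expect_equal(eff$kind, oracle_effect_kind(cod, alt_cod))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 61 * 9)
})

test_that("annotated sites carry field-style notation", {
  a <- edited_quartet("ATGAAACCC", list(list("focal", 4L, "G")))
  s <- annotate_sites(a, call_variant_sites(a))
  expect_equal(s$nt_notation, "A 4 G")
  expect_equal(s$aa_notation, "K 2 E")
})
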