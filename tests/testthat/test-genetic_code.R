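test_that("stop neighbor enumeration matches brute force and rejects stops", {
  expect_identical(stop_neighbors("TGG"), c("TAG", "TGA"))
  expect_identical(stop_neighbors("GGG"), character(0))
  expect_error(stop_neighbors("TAA"), "stop codon")
  expect_error(stop_neighbors("XYZ"), "not a valid codon")
  expect_error(stop_neighbors("AT"), "not a valid codon")

  # every reported neighbor differs at exactly one position and is a stop;
  # deterministic lexicographic order
  for (cod in sample(sense_codons(), 15)) {
    nb <- stop_neighbors(cod)
    expect_identical(nb, sort(nb))
    for (s in nb) {
      expect_true(s %in% stop_codons())
      expect_equal(sum(strsplit(cod, "")[[1]] != strsplit(s, "")[[1]]), 1)
    }
  }
})

test_that("codon classification is derived correctly (18 fragile / 43 robust)", {
  tab <- codon_classification_table()
  expect_equal(nrow(tab), 61)
  expect_equal(sum(tab$status == "fragile"), 18)
  expect_equal(sum(tab$status == "robust"), 43)
  expect_setequal(tab$codon[tab$status == "fragile"], ORACLE_FRAGILE)
  expect_equal(classify_codon("TCA")$status, "fragile")
  expect_equal(classify_codon("TCT")$status, "robust")
  expect_equal(classify_codon("CTG")$status, "robust")
  # fragile iff non-empty neighbor set
  expect_true(all((tab$status == "fragile") == (tab$stop_neighbors != "")))
})

test_that("amino-acid classes partition the 20 amino acids 6/10/4", {
  tab <- amino_acid_classification_table()
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$status == "fragile"), 6)
  expect_equal(sum(tab$status == "robust"), 10)
  expect_equal(sum(tab$status == "facultative"), 4)
  expect_setequal(fragile_amino_acids(), ORACLE_FRAGILE_AA)
  expect_equal(classify_amino_acid("W")$status, "fragile")
  expect_equal(classify_amino_acid("S")$status, "facultative")
  expect_equal(classify_amino_acid("H")$status, "robust")
  expect_error(classify_amino_acid("B"), "not a standard amino acid")

  # fragile AAs have all-fragile codon families; robust all-robust
  ct <- codon_classification_table()
  for (i in seq_len(nrow(tab))) {
    st <- ct$status[ct$amino_acid == tab$amino_acid[i]]
    if (tab$status[i] == "fragile") expect_true(all(st == "fragile"))
    if (tab$status[i] == "robust") expect_true(all(st == "robust"))
    if (tab$status[i] == "facultative") {
      expect_true(any(st == "fragile") && any(st == "robust"))
    }
  }
})

test_that("canonical NFCU groups reproduce the classical lists", {
  g <- nfcu_groups("canonical")
  expect_length(g, 5)
  members <- lapply(g, `[[`, "members")
  fragile <- lapply(g, `[[`, "fragile_members")
  expect_setequal(vapply(members, paste, "", collapse = ","),
                  c("TCA,TCT", "TCC,TCG", "CGA,CGT", "GGA,GGT",
                    "CTA,CTT,TTG"))
  expect_setequal(unlist(fragile), c("TCA", "TCG", "CGA", "GGA", "TTG"))
  # groups are synonymous and GC-homogeneous with a mixed composition
  code <- standard_genetic_code()
  for (gr in g) {
    expect_length(unique(code[gr$members]), 1)
    gcs <- vapply(strsplit(gr$members, ""),
                  function(x) sum(x %in% c("G", "C")), 0L)
    expect_length(unique(gcs), 1)
    expect_gt(length(gr$fragile_members), 0)
    expect_gt(length(setdiff(gr$members, gr$fragile_members)), 0)
  }
})

test_that("derived NFCU groups partition facultative codons by GC content", {
  g <- nfcu_groups("derived")
  expect_length(g, 5)
  ids <- vapply(g, `[[`, "", "group_id")
  # derived Ser GC=1 group gains the robust AGT synonym
  ser1 <- g[[which(ids == "S-GC1")]]
  expect_setequal(ser1$members, c("TCA", "TCT", "AGT"))
  expect_identical(ser1$fragile_members, "TCA")
  leu <- g[[which(ids == "L-GC1")]]
  expect_setequal(leu$members, c("TTG", "CTT", "CTA"))
  # every canonical group is a member-wise subset of the derived partition
  for (cg in nfcu_groups("canonical")) {
    match_g <- Filter(function(dg) dg$amino_acid == cg$amino_acid &&
                        dg$gc_count == cg$gc_count, g)
    expect_length(match_g, 1)
    expect_true(all(cg$members %in% match_g[[1]]$members))
  }
  # TTA (fragile Leu, GC 0) belongs to no group in either mode
  for (mode in c("canonical", "derived")) {
    expect_false(any(vapply(nfcu_groups(mode),
                            function(gr) "TTA" %in% gr$members, TRUE)))
  }
})

test_that("NFAU groups match the family-GC derivation", {
  g <- nfau_groups()
  expect_length(g, 2)
  expect_setequal(g[[1]]$members, c("Y", "K", "N", "F"))
  expect_setequal(g[[1]]$fragile_members, c("Y", "K"))
  expect_setequal(g[[2]]$members, c("Q", "E", "C", "S", "H", "T", "V", "D"))
  expect_setequal(g[[2]]$fragile_members, c("Q", "E", "C"))
  # brute-force re-derivation from family GC fractions
  gc <- family_gc_fraction(amino_acid_classification_table()$amino_acid)
  expect_setequal(names(gc)[abs(gc - 1 / 6) < 1e-12], g[[1]]$members)
  two_codon_or_ser <- names(gc)[abs(gc - 1 / 2) < 1e-12]
  expect_setequal(two_codon_or_ser, g[[2]]$members)
})

test_that("classification table exports as TSV", {
  path <- tempfile(fileext = ".tsv")
  export_codon_table(path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 61)
  expect_named(back, c("codon", "amino_acid", "status", "stop_neighbors"))
  expect_equal(back$status[back$codon == "TGG"], "fragile")
})
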