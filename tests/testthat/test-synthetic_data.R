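test_that("peptide sampling hits closed-form FAU expectations", {
  set.seed(41)
  # psi = 1, uniform base: expected FAU = 6/20
  expect_equal(expected_fau(1), 0.3)
  p1 <- sample_peptide(10000, 1)
  expect_equal(mean(p1 %in% fragile_amino_acids()), 0.3, tolerance = 0.015)
  # psi = 0: no fragile residues at all
  expect_equal(sum(sample_peptide(2000, 0) %in% fragile_amino_acids()), 0)
  # psi = 0.5: closed-form renormalization 0.5*6 / (0.5*6 + 14)
  expect_equal(expected_fau(0.5), 3 / 17)
  p05 <- sample_peptide(10000, 0.5)
  expect_lt(abs(mean(p05 %in% fragile_amino_acids()) - 3 / 17), 0.01)
})

test_that("reverse translation hits closed-form group fractions", {
  set.seed(42)
  # phi = 1: symmetric two-member groups at 1/2
  expect_equal(expected_nfcu(1), (4 * 0.5 + 1 / 3) / 5)
  # phi = 0.8 on the Leu group: expected fraction 0.8/2.8
  cods <- reverse_translate(rep("L", 10000), phi = 0.8)
  leu_group <- cods[cods %in% c("TTG", "CTT", "CTA")]
  expect_equal(mean(leu_group == "TTG"), 0.8 / 2.8, tolerance = 0.02)
  # phi -> 0 drives NFCU to 0
  cods0 <- reverse_translate(sample_peptide(3000, 1), phi = 1e-9)
  expect_equal(.subset2(nfcu(cods0), "value"), 0)
  # translation is faithful
  pep <- sample_peptide(500, 1)
  code <- standard_genetic_code()
  expect_identical(unname(code[reverse_translate(pep, 1)]), pep)
  # per-residue phi vector: depleted region is depleted
  pep2 <- rep("S", 20000)
  phiv <- rep(c(0.3, 1), each = 10000)
  cods2 <- reverse_translate(pep2, phiv)
  frac <- function(idx) {
    g <- cods2[idx][cods2[idx] %in% c("TCA", "TCT")]
    mean(g == "TCA")
  }
  expect_lt(abs(frac(1:10000) - 0.3 / 1.3), 0.03)
  expect_lt(abs(frac(10001:20000) - 0.5), 0.03)
})

test_that("GC targeting biases composition without moving NFCU", {
  set.seed(43)
  pep <- sample_peptide(20000, 1)
  lo <- reverse_translate(pep, 1, gc_target = 0.3)
  hi <- reverse_translate(pep, 1, gc_target = 0.7)
  gc_of <- function(cods) {
    nt <- strsplit(paste(cods, collapse = ""), "")[[1]]
    mean(nt %in% c("G", "C"))
  }
  expect_gt(gc_of(hi), gc_of(lo) + 0.1)
  expect_equal(metric_value(nfcu(lo)), metric_value(nfcu(hi)),
               tolerance = 0.03)
})

test_that("weight calibration helpers invert the closed forms", {
  phi <- phi_for_nfcu_ratio(0.92)
  expect_equal(expected_nfcu(phi) / expected_nfcu(1), 0.92,
               tolerance = 1e-8)
  psi <- psi_for_fau_ratio(0.83)
  expect_equal(expected_fau(psi) / expected_fau(1), 0.83, tolerance = 1e-8)
})

test_that("config validation rejects impossible structures", {
  expect_error(synthetic_config(nfcu_ratio_single = 0), "ratios")
  expect_error(synthetic_config(cds_len_multi = c(10L, 50L)), "30 codons")
  expect_error(synthetic_config(intron_len_range = c(5L, 10L)), "20 nt")
  expect_error(synthetic_config(utr3_len_range = c(50L, 80L)), "100 nt")
  expect_error(synthetic_config(reliable_fraction = 2), "reliable_fraction")
})

test_that("generation is deterministic and round-trips exactly", {
  cfg <- synthetic_config(n_multi = 15L, n_single = 8L, n_histone = 3L,
                          seed = 99L, genes_per_contig = 10L)
  d1 <- tempfile()
  d2 <- tempfile()
  g1 <- build_genome(cfg, d1)
  g2 <- build_genome(cfg, d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gff3), readLines(g2$gff3))
  expect_identical(readLines(g1$manifest_path),
                   readLines(g2$manifest_path))

  gms <- load_annotation(g1$fasta, g1$gff3)
  expect_equal(gms$n_genes, 26)
  man <- g1$manifest
  for (i in seq_len(nrow(man))) {
    tm <- gms$models[[man$gene_id[i]]]
    expect_equal(length(tm$cds_codons), man$cds_len[i])
    expect_equal(tm$n_exons, man$exon_count[i])
    # realized metrics recomputable from the emitted files
    expect_equal(.subset2(nfcu(tm$cds_codons), "value"),
                 man$realized_nfcu[i], tolerance = 1e-12)
    expect_equal(.subset2(fau(strsplit(tm$peptide, "")[[1]]), "value"),
                 man$realized_fau[i], tolerance = 1e-12)
    expect_identical(tm$strand, man$strand[i])
  }
  # both strands used
  expect_setequal(unique(man$strand), c("+", "-"))
})

test_that("unreliable genes are emitted at the configured rate and kinds", {
  cfg <- synthetic_config(n_multi = 60L, n_single = 0L, seed = 7L,
                          reliable_fraction = 0.5)
  gen <- build_genome(cfg, tempfile())
  gms <- load_annotation(gen$fasta, gen$gff3)
  rel <- vapply(gms$models, is_reliable_last_exon, TRUE)
  expect_equal(unname(rel[gen$manifest$gene_id]), gen$manifest$reliable)
  expect_gt(sum(!rel), 10)
  expect_gt(sum(rel), 10)
})

test_that("realized median NFCU increases monotonically in phi", {
  set.seed(44)
  med <- vapply(c(0.25, 0.5, 1, 2), function(ph) {
    vals <- vapply(1:300, function(i) {
      .subset2(nfcu(reverse_translate(sample_peptide(200, 1), ph)), "value")
    }, 0)
    median(vals, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("junction phases are uniform over 0/1/2", {
  cfg <- synthetic_config(n_multi = 120L, n_single = 0L, seed = 5L,
                          exon_lambda = 3)
  gen <- build_genome(cfg, tempfile())
  gms <- load_annotation(gen$fasta, gen$gff3)
  phases <- unlist(lapply(gms$models, function(tm)
    tm$cds_segments$phase[-1]))
  expect_gt(length(phases), 300)
  p <- stats::chisq.test(table(factor(phases, levels = 0:2)))$p.value
  expect_gt(p, 0.001)
})

test_that("ortholog simulation + NG86 estimation are mutually consistent", {
  set.seed(45)
  # scaled-down consistency check (the full 200-replicate version runs in
  # the acceptance suite)
  ka <- ks <- numeric(30)
  for (i in 1:30) {
    a <- reverse_translate(sample_peptide(300, 1), 1)
    b <- simulate_ortholog(a, target_ks = 0.4, omega = 0.25)
    r <- ng86(a, b)
    ka[i] <- r$ka
    ks[i] <- r$ks
  }
  expect_equal(mean(ks), 0.4, tolerance = 0.08)
  expect_equal(mean(ka), 0.25 * 0.4, tolerance = 0.025)
})
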