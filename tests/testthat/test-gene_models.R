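# 20 codons + stop = 63 CDS nt; exon splits chosen per test to set the
# phase of each junction (phase = cumulative CDS nt %% 3 at the junction)

test_that("plus-strand toy gene round-trips through the loader", {
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(21L, 18L, 24L))
  gms <- load_annotation(fx$fasta, fx$gff3)
  expect_equal(gms$n_genes, 1)
  tm <- gms$models[[1]]
  expect_identical(tm$cds_codons, fx$codons)
  expect_equal(tm$n_exons, 3)
  expect_equal(tm$strand, "+")
  expect_equal(tm$utr3_len, 120)
  expect_identical(tm$flags, character(0))
  expect_equal(tm$stop_codon, "TAA")
})

test_that("minus-strand mirror yields the identical codon sequence", {
  fx_p <- toy_gene_files(tempfile(), exon_cds_nt = c(22L, 17L, 24L),
                         strand = "+")
  fx_m <- toy_gene_files(tempfile(), exon_cds_nt = c(22L, 17L, 24L),
                         strand = "-")
  tm_p <- load_annotation(fx_p$fasta, fx_p$gff3)$models[[1]]
  tm_m <- load_annotation(fx_m$fasta, fx_m$gff3)$models[[1]]
  expect_identical(tm_m$cds_codons, tm_p$cds_codons)
  expect_identical(tm_m$exon_of_codon, tm_p$exon_of_codon)
  expect_equal(tm_m$strand, "-")
})

test_that("validation flags internal stops and missing terminal stops", {
  cods <- rep("GCT", 20)
  cods[8] <- "TAA"
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(21L, 42L), codons = cods)
  gms <- load_annotation(fx$fasta, fx$gff3)
  expect_true("internal_stop" %in% gms$models[[1]]$flags)
  expect_match(gms$validation$flags, "internal_stop")

  fx2 <- toy_gene_files(tempfile(), exon_cds_nt = c(21L, 42L),
                        stop_codon = "GGG")  # CDS not ending in a stop
  tm2 <- load_annotation(fx2$fasta, fx2$gff3)$models[[1]]
  expect_true("no_terminal_stop" %in% tm2$flags)
  expect_false(is_reliable_last_exon(tm2))

  expect_error(load_annotation(tempfile(), fx$gff3))
})

test_that("representative transcript: longest peptide, then smallest id", {
  mk <- function(id, len) list(transcript_id = id, peptide_length = len)
  expect_equal(select_representative_transcript(
    list(mk("t2", 100), mk("t1", 250)))$transcript_id, "t1")
  expect_equal(select_representative_transcript(
    list(mk("t2", 100), mk("t1", 100)))$transcript_id, "t1")
  expect_equal(select_representative_transcript(
    list(mk("t9", 70)))$transcript_id, "t9")
})

test_that("exon counting includes non-coding exons", {
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(33L, 30L),
                       extra_noncoding_exon = TRUE)
  tm <- load_annotation(fx$fasta, fx$gff3)$models[[1]]
  expect_equal(exon_count(tm), 3)  # 2 coding + 1 non-coding 3' exon
  fx1 <- toy_gene_files(tempfile(), exon_cds_nt = 63L)
  expect_equal(exon_count(load_annotation(fx1$fasta, fx1$gff3)$models[[1]]),
               1)
})

test_that("reliable-last-exon criteria (stop, downstream exon, 3' UTR)", {
  ok <- toy_gene_files(tempfile(), exon_cds_nt = c(33L, 30L),
                       utr3_nt = 150L)
  expect_true(is_reliable_last_exon(
    load_annotation(ok$fasta, ok$gff3)$models[[1]]))
  short <- toy_gene_files(tempfile(), exon_cds_nt = c(33L, 30L),
                          utr3_nt = 40L)
  expect_false(is_reliable_last_exon(
    load_annotation(short$fasta, short$gff3)$models[[1]]))
  down <- toy_gene_files(tempfile(), exon_cds_nt = c(33L, 30L),
                         extra_noncoding_exon = TRUE)
  tm <- load_annotation(down$fasta, down$gff3)$models[[1]]
  expect_true(tm$has_downstream_noncoding_exon)
  expect_false(is_reliable_last_exon(tm))
})

test_that("codon-to-exon assignment respects junction phase", {
  # phase-0 junctions: no spanning codons
  fx0 <- toy_gene_files(tempfile(), exon_cds_nt = c(21L, 18L, 24L))
  tm0 <- load_annotation(fx0$fasta, fx0$gff3)$models[[1]]
  expect_equal(sum(is.na(tm0$exon_of_codon)), 0)
  expect_equal(tm0$exon_of_codon, rep(1:3, c(7, 6, 7)))

  # phase-1 junction after 22 nt: codon 8 (nt 22-24) spans exons 1-2
  fx1 <- toy_gene_files(tempfile(), exon_cds_nt = c(22L, 41L))
  tm1 <- load_annotation(fx1$fasta, fx1$gff3)$models[[1]]
  expect_equal(which(is.na(tm1$exon_of_codon)), 8)

  # phase-2 junction after 23 nt: codon 8 spans
  fx2 <- toy_gene_files(tempfile(), exon_cds_nt = c(23L, 40L))
  tm2 <- load_annotation(fx2$fasta, fx2$gff3)$models[[1]]
  expect_equal(which(is.na(tm2$exon_of_codon)), 8)

  # bookkeeping identity: exon-complete + spanning = total
  for (tm in list(tm0, tm1, tm2)) {
    ec <- assign_codons_to_exons(tm)
    expect_equal(sum(vapply(ec, function(e) length(e$codons), 0L)) +
                   sum(is.na(tm$exon_of_codon)),
                 length(tm$cds_codons))
    # reconstruction: concatenating exon codons plus spanning codons in
    # index order reproduces the CDS
    got <- character(length(tm$cds_codons))
    for (e in ec) got[which(!is.na(tm$exon_of_codon) &
                              tm$exon_of_codon == e$exon_index)] <- e$codons
    span <- which(is.na(tm$exon_of_codon))
    got[span] <- tm$cds_codons[span]
    expect_identical(got, tm$cds_codons)
  }

  # single-exon CDS: everything in exon 1
  fxs <- toy_gene_files(tempfile(), exon_cds_nt = 63L)
  tms <- load_annotation(fxs$fasta, fxs$gff3)$models[[1]]
  expect_equal(tms$exon_of_codon, rep(1L, 20))
})

test_that("cds_in_last_exon", {
  # all CDS in final exon of 2: exon 1 is pure 5' UTR -> represented by
  # giving exon 1 zero CDS; build via extra exon trick: CDS spans exons 2-3
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(30L, 33L))
  tm <- load_annotation(fx$fasta, fx$gff3)$models[[1]]
  expect_false(cds_in_last_exon(tm))
  fx1 <- toy_gene_files(tempfile(), exon_cds_nt = 63L)
  expect_true(is.na(cds_in_last_exon(
    load_annotation(fx1$fasta, fx1$gff3)$models[[1]])))
})

test_that("boundary windows: exact placement, size and reason codes", {
  # phase-0: upstream 120 codons (360 nt), last exon 150 codons + stop
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(180L, 180L, 453L),
                       utr3_nt = 150L)
  tm <- load_annotation(fx$fasta, fx$gff3)$models[[1]]
  w <- extract_boundary_windows(tm)
  expect_true(w$eligible)
  expect_length(w$five_prime_window, 50)
  expect_length(w$three_prime_window, 50)
  # junction at CDS nt 360 -> 3' window = codons 121..170,
  # 5' window ends at codon floor((360-50)/3) = 103 -> codons 54..103
  expect_equal(w$three_start_codon, 121)
  expect_equal(w$five_start_codon, 54)
  expect_identical(as.character(w$three_prime_window),
                   tm$cds_codons[121:170])
  expect_identical(as.character(w$five_prime_window), tm$cds_codons[54:103])
  expect_gte(w$buffer_used_nt, 50)
  # windows are disjoint
  expect_equal(intersect(54:103, 121:170), integer(0))

  # phase-2 junction (361 nt upstream): spanning codon 121 in neither window
  fx2 <- toy_gene_files(tempfile(), exon_cds_nt = c(180L, 181L, 452L),
                        utr3_nt = 150L)
  tm2 <- load_annotation(fx2$fasta, fx2$gff3)$models[[1]]
  expect_equal(which(is.na(tm2$exon_of_codon)), 121)
  w2 <- extract_boundary_windows(tm2)
  expect_true(w2$eligible)
  expect_equal(w2$three_start_codon, 122)
  expect_false(121 %in% c(seq(w2$five_start_codon, length.out = 50),
                          seq(w2$three_start_codon, length.out = 50)))
  # 5' window: floor((361-50)/3) = 103
  expect_equal(w2$five_start_codon + 49L, 103)

  # ineligibility reasons
  single <- toy_gene_files(tempfile(), exon_cds_nt = 363L)
  expect_equal(extract_boundary_windows(
    load_annotation(single$fasta, single$gff3)$models[[1]])$reason,
    "single_exon")
  unrel <- toy_gene_files(tempfile(), exon_cds_nt = c(180L, 453L),
                          utr3_nt = 40L)
  expect_equal(extract_boundary_windows(
    load_annotation(unrel$fasta, unrel$gff3)$models[[1]])$reason,
    "unreliable_last_exon")
  short_last <- toy_gene_files(tempfile(), exon_cds_nt = c(360L, 273L),
                               utr3_nt = 150L)  # last exon 90 codons
  expect_equal(extract_boundary_windows(
    load_annotation(short_last$fasta, short_last$gff3)$models[[1]])$reason,
    "last_exon_too_short")
  short_up <- toy_gene_files(tempfile(), exon_cds_nt = c(120L, 453L),
                             utr3_nt = 150L)  # 40 upstream codons
  expect_equal(extract_boundary_windows(
    load_annotation(short_up$fasta, short_up$gff3)$models[[1]])$reason,
    "insufficient_upstream_codons")
})

test_that("strand invariance: windows and metrics unchanged on minus strand", {
  fx_p <- toy_gene_files(tempfile(), exon_cds_nt = c(181L, 180L, 452L),
                         utr3_nt = 150L, strand = "+")
  fx_m <- toy_gene_files(tempfile(), exon_cds_nt = c(181L, 180L, 452L),
                         utr3_nt = 150L, strand = "-")
  tm_p <- load_annotation(fx_p$fasta, fx_p$gff3)$models[[1]]
  tm_m <- load_annotation(fx_m$fasta, fx_m$gff3)$models[[1]]
  w_p <- extract_boundary_windows(tm_p)
  w_m <- extract_boundary_windows(tm_m)
  expect_identical(as.character(w_p$five_prime_window),
                   as.character(w_m$five_prime_window))
  expect_identical(as.character(w_p$three_prime_window),
                   as.character(w_m$three_prime_window))
  expect_equal(metric_value(nfcu(tm_p$cds_codons)),
               metric_value(nfcu(tm_m$cds_codons)))
})

test_that("ESE density merges overlapping hits; partition follows coverage", {
  expect_equal(ese_density("ACGTAC", "ACGTAC"), 1)
  expect_equal(ese_density("TTTTTTTTTTTT", "ACGTAC"), 0)
  expect_equal(ese_density("ACG", "ACGTAC"), 0)  # shorter than 6 nt
  # hits at 1 and 5 cover nt 1..10 of 12
  expect_equal(ese_density("ACGTACGTACGT", "ACGTAC"), 10 / 12)
  expect_error(ese_density("ACGTAC", character(0)), "empty")

  part <- partition_codons_by_ese(c("ACG", "TAC", "TTT"), "ACGTAC")
  expect_identical(as.character(part$overlapping), c("ACG", "TAC"))
  expect_identical(as.character(part$external), "TTT")
  # codon sharing exactly one covered nucleotide is overlapping
  part2 <- partition_codons_by_ese(c("TTT", "TAC", "GTA", "CAA"),
                                   "ACGTAC", context = "TTTTACGTACAA",
                                   offset_nt = 0L)
  expect_identical(as.character(part2$overlapping), c("TAC", "GTA", "CAA"))
  # exhaustive and disjoint
  expect_equal(length(part2$overlapping) + length(part2$external), 4)
})

test_that("Fop raw and GC-controlled modes", {
  opt <- c("GCC", "AAG", "CTG")
  expect_equal(fop(c("GCC", "GCC", "AAG"), opt), 1)
  expect_true(is.na(fop(c("ATG", "TGG"), opt)))  # single-codon families only
  expect_error(fop(c("GCC"), character(0)), "empty")
  # raw: 2 optimal of 3 multi-family codons (ATG excluded)
  expect_equal(fop(c("GCC", "AAA", "CTG", "ATG"), opt), 2 / 3)
  # gc_controlled: subgroups mixing optimal/non-optimal at equal GC:
  # Ala GC=2 {GCA,GCT} vs {GCC,GCG}? GCC and GCG have GC 2? compute:
  # GCC gc=3, GCA gc=2, GCT gc=2, GCG gc=3 -> subgroup {GCC,GCG} mixes
  # optimal GCC with non-optimal GCG
  v <- fop(c("GCC", "GCG", "GCA"), opt, mode = "gc_controlled")
  expect_equal(v, 1 / 2)  # only the GC=3 subgroup counts: 1 of 2
})

test_that("structural table summarizes per-gene fields", {
  fx <- toy_gene_files(tempfile(), exon_cds_nt = c(33L, 30L),
                       utr3_nt = 150L)
  gms <- load_annotation(fx$fasta, fx$gff3)
  df <- structural_table(gms, hexamers = "ACGTAC")
  expect_equal(nrow(df), 1)
  expect_equal(df$exon_count, 2)
  expect_equal(df$cds_len_nt, 60)
  expect_true(df$reliable_last_exon)
  expect_false(df$cds_in_last_exon)
})
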