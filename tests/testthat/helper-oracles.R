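# Independent oracles: hard-coded reference tables and brute-force metric
# implementations, deliberately separate from the package's derivation path.

# the 18 fragile codons (reference table; the package must *derive* these)
ORACLE_FRAGILE <- c("TTA", "TTG", "TCA", "TCG", "TAT", "TAC", "TGT", "TGC",
                    "TGG", "CAA", "CAG", "CGA", "AAA", "AAG", "AGA", "GAA",
                    "GAG", "GGA")

ORACLE_FRAGILE_AA <- c("C", "Q", "E", "K", "W", "Y")

# canonical NFCU groups as (members, fragile) pairs
ORACLE_NFCU_GROUPS <- list(
  list(members = c("TCA", "TCT"), fragile = "TCA"),
  list(members = c("TCG", "TCC"), fragile = "TCG"),
  list(members = c("CGA", "CGT"), fragile = "CGA"),
  list(members = c("GGA", "GGT"), fragile = "GGA"),
  list(members = c("TTG", "CTT", "CTA"), fragile = "TTG"))

ORACLE_NFAU_GROUPS <- list(
  list(members = c("Y", "K", "N", "F"), fragile = c("Y", "K")),
  list(members = c("Q", "E", "C", "S", "H", "T", "V", "D"),
       fragile = c("Q", "E", "C")))

oracle_fcu <- function(codons) {
  codons <- codons[!grepl("N", codons) &
                     !(codons %in% c("TAA", "TAG", "TGA"))]
  if (!length(codons)) return(NA_real_)
  sum(codons %in% ORACLE_FRAGILE) / length(codons)
}

oracle_nfcu <- function(codons) {
  fr <- numeric(0)
  for (g in ORACLE_NFCU_GROUPS) {
    den <- 0
    num <- 0
    for (cd in codons) {
      if (cd %in% g$members) {
        den <- den + 1
        if (cd %in% g$fragile) num <- num + 1
      }
    }
    if (den > 0) fr <- c(fr, num / den)
  }
  if (!length(fr)) return(NA_real_)
  mean(fr)
}

oracle_fau <- function(res) {
  res <- res[res %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
  if (!length(res)) return(NA_real_)
  sum(res %in% ORACLE_FRAGILE_AA) / length(res)
}

oracle_nfau <- function(res) {
  fr <- numeric(0)
  for (g in ORACLE_NFAU_GROUPS) {
    den <- sum(res %in% g$members)
    if (den > 0) fr <- c(fr, sum(res %in% g$fragile) / den)
  }
  if (!length(fr)) return(NA_real_)
  mean(fr)
}

random_sense_codons <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

# Hand-built toy gene fixture: explicit coordinate arithmetic, written
# independently of the synthetic_data generator.
#
# exon_cds_nt: CDS nucleotides per exon (sum must be 3 * n codons + 3 for
# the stop). The gene sits on contig "chrT" with 5 nt padding either side.
toy_gene_files <- function(dir, exon_cds_nt, strand = "+",
                           utr5_nt = 10L, utr3_nt = 120L, intron_nt = 30L,
                           codons = NULL, stop_codon = "TAA",
                           extra_noncoding_exon = FALSE,
                           gene_id = "gT", tx_id = "mT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_cod <- (sum(exon_cds_nt) - 3L) / 3L
  stopifnot(n_cod == as.integer(n_cod))
  if (is.null(codons)) {
    pool <- setdiff(sense_codons(), c("TAA", "TAG", "TGA"))
    codons <- rep_len(pool, n_cod)
    codons[1] <- "ATG"
  }
  cds_nt <- paste(c(codons, stop_codon), collapse = "")
  utr5 <- paste(rep_len(c("A", "C"), utr5_nt), collapse = "")
  utr3 <- paste(rep_len(c("G", "T"), utr3_nt), collapse = "")
  intron <- paste0("GT", paste(rep("C", intron_nt - 4L), collapse = ""), "AG")

  n_ex <- length(exon_cds_nt)
  bounds <- cumsum(c(0L, exon_cds_nt))
  cds_parts <- substring(cds_nt, bounds[-length(bounds)] + 1L, bounds[-1])
  exon_parts <- cds_parts
  exon_parts[1] <- paste0(utr5, exon_parts[1])
  exon_parts[n_ex] <- paste0(exon_parts[n_ex],
                             if (extra_noncoding_exon) "" else utr3)
  if (extra_noncoding_exon) exon_parts <- c(exon_parts, utr3)

  # local plus-strand coordinates
  pos <- 0L
  exon_loc <- matrix(0L, length(exon_parts), 2L)
  pieces <- character(0)
  for (e in seq_along(exon_parts)) {
    exon_loc[e, ] <- c(pos + 1L, pos + nchar(exon_parts[e]))
    pieces <- c(pieces, exon_parts[e])
    pos <- pos + nchar(exon_parts[e])
    if (e < length(exon_parts)) {
      pieces <- c(pieces, intron)
      pos <- pos + nchar(intron)
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  glen <- nchar(gene_seq)
  cds_loc <- matrix(0L, n_ex, 2L)
  for (e in seq_len(n_ex)) {
    off <- if (e == 1L) utr5_nt else 0L
    cds_loc[e, ] <- c(exon_loc[e, 1] + off,
                      exon_loc[e, 1] + off + nchar(cds_parts[e]) - 1L)
  }
  cum <- cumsum(c(0L, nchar(cds_parts)))
  phases <- (3L - cum[-length(cum)] %% 3L) %% 3L
  u5_loc <- c(exon_loc[1, 1], exon_loc[1, 1] + utr5_nt - 1L)
  u3_loc <- if (extra_noncoding_exon) {
    exon_loc[nrow(exon_loc), , drop = FALSE]
  } else {
    matrix(c(cds_loc[n_ex, 2] + 1L, cds_loc[n_ex, 2] + utr3_nt), 1L)
  }

  pad <- 5L
  contig <- paste0("AAAAA", gene_seq, "AAAAA")
  if (strand == "-") {
    contig <- paste(rev(strsplit(chartr("ACGT", "TGCA", contig), "")[[1]]),
                    collapse = "")
  }
  tr <- function(m) {  # local -> genomic (1-based) under the strand
    m <- matrix(m, ncol = 2L)
    if (strand == "+") m + pad else
      cbind(pad + glen - m[, 2] + 1L, pad + glen - m[, 1] + 1L)
  }
  line <- function(m, type, id, parent = NULL, phase = ".") {
    m <- tr(m)
    vapply(seq_len(nrow(m)), function(i) {
      attrs <- paste0("ID=", id, if (!is.null(parent))
        paste0(";Parent=", parent) else "")
      sprintf("chrT\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s", type, m[i, 1],
              m[i, 2], strand,
              if (length(phase) > 1L) phase[i] else phase, attrs)
    }, "")
  }
  gff <- c("##gff-version 3",
           line(c(1L, glen), "gene", gene_id),
           line(c(1L, glen), "mRNA", tx_id, gene_id),
           unlist(lapply(seq_len(nrow(exon_loc)), function(e)
             line(exon_loc[e, ], "exon", paste0(tx_id, ".e", e), tx_id))),
           unlist(lapply(seq_len(n_ex), function(e)
             line(cds_loc[e, ], "CDS", paste0(tx_id, ".cds"), tx_id,
                  phase = as.character(phases[e])))),
           line(u5_loc, "five_prime_UTR", paste0(tx_id, ".u5"), tx_id),
           unlist(lapply(seq_len(nrow(u3_loc)), function(e)
             line(u3_loc[e, ], "three_prime_UTR",
                  paste0(tx_id, ".u3.", e), tx_id))))
  fasta <- file.path(dir, "toy.fasta")
  gff3 <- file.path(dir, "toy.gff3")
  writeLines(c(">chrT", contig), fasta)
  writeLines(gff, gff3)
  list(fasta = fasta, gff3 = gff3, codons = codons,
       exon_cds_nt = exon_cds_nt, n_codons = n_cod)
}
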