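# Synthetic gene-model generator: emits FASTA + GFF3 + a truth manifest so
# every pipeline stage can be validated at desk scale against known
# generative parameters. Fragile-codon weighting (phi) acts within
# synonymous families, so codon-level depletion is controlled independently
# of amino-acid composition (psi) and of the GC target, which only biases
# choices among equal-fragility synonyms.

#' Expected NFCU under a fragile-codon weight
#'
#' Closed-form expectation of the per-group fragile fraction when fragile
#' codons are weighted `phi` relative to robust synonyms within each group:
#' for a group with f fragile and r robust members the fraction is
#' phi*f / (phi*f + r); the value is the unweighted mean over groups, i.e.
#' exactly what NFCU estimates on long sequences.
#'
#' @param phi Fragile-codon weight (> 0 scalar or vector).
#' @param groups NFCU groups (canonical by default).
#' @return Expected NFCU value(s).
#' @export
expected_nfcu <- function(phi, groups = nfcu_groups()) {
  vapply(phi, function(ph) {
    mean(vapply(groups, function(g) {
      f <- length(g$fragile_members)
      r <- length(g$members) - f
      ph * f / (ph * f + r)
    }, 0))
  }, 0)
}

#' Expected FAU under a fragile-amino-acid weight
#'
#' With base frequencies `base` (default uniform over the 20 amino acids)
#' and fragile residues reweighted by `psi`, the expected fragile fraction
#' is psi*B_f / (psi*B_f + B_r) where B_f and B_r are the base mass of
#' fragile and non-fragile amino acids.
#'
#' @param psi Fragile amino-acid weight (>= 0 scalar or vector).
#' @param base Named base frequencies over the 20 amino acids.
#' @return Expected FAU value(s).
#' @export
expected_fau <- function(psi, base = NULL) {
  if (is.null(base)) base <- stats::setNames(rep(1 / 20, 20), AA20)
  bf <- sum(base[fragile_amino_acids()])
  br <- sum(base) - bf
  vapply(psi, function(ps) ps * bf / (ps * bf + br), 0)
}

.solve_weight <- function(target, fn, interval = c(1e-6, 1e3)) {
  stats::uniroot(function(w) fn(w) - target, interval, tol = 1e-12)$root
}

#' Calibrate phi / psi for a target metric ratio
#'
#' Finds the weight whose expected metric equals `ratio` times the expected
#' metric at the reference weight, using the closed forms [expected_nfcu()]
#' and [expected_fau()].
#'
#' @param ratio Target ratio of expected metric to the reference.
#' @param reference Reference expected value (defaults to the weight-1
#'   expectation).
#' @return The calibrated weight.
#' @export
phi_for_nfcu_ratio <- function(ratio, reference = expected_nfcu(1)) {
  .solve_weight(ratio * reference, expected_nfcu)
}

#' @rdname phi_for_nfcu_ratio
#' @export
psi_for_fau_ratio <- function(ratio, reference = expected_fau(1)) {
  .solve_weight(ratio * reference, expected_fau)
}

#' Sample a random peptide with weighted fragile amino acids
#'
#' Residues are drawn independently with probability proportional to
#' `psi * base` for fragile amino acids (C, Q, E, K, W, Y) and `base`
#' otherwise. With a uniform base, expected FAU is psi*6 / (psi*6 + 14).
#'
#' @param length Number of residues (>= 1).
#' @param psi Fragile amino-acid weight (>= 0).
#' @param base Named base frequencies over the 20 amino acids (default
#'   uniform).
#' @return Character vector of residues.
#' @export
sample_peptide <- function(length, psi = 1, base = NULL) {
  stopifnot(length >= 1, psi >= 0)
  if (is.null(base)) base <- stats::setNames(rep(1 / 20, 20), AA20)
  w <- base[AA20]
  fr <- AA20 %in% fragile_amino_acids()
  w[fr] <- w[fr] * psi
  sample(AA20, length, replace = TRUE, prob = w / sum(w))
}

#' Reverse-translate a peptide with weighted fragile codons
#'
#' Within each synonymous family, fragile codons are weighted `phi` relative
#' to robust synonyms, and every codon is additionally weighted
#' `gc_target^g * (1 - gc_target)^(3 - g)` (g = its G+C count), which biases
#' composition toward the GC target without disturbing within-group ratios
#' (group members share the same GC count). For an NFCU group with f fragile
#' and r robust members the expected fragile fraction is
#' phi*f / (phi*f + r).
#'
#' @param peptide Character vector of residues (or a single string).
#' @param phi Fragile-codon weight; a scalar, or one value per residue
#'   (used to give different regions of a gene different weights).
#' @param gc_target Target GC proportion in `[0.05, 0.95]` (default 0.5,
#'   i.e. no compositional bias).
#' @return Character vector of codons.
#' @export
reverse_translate <- function(peptide, phi = 1, gc_target = 0.5) {
  res <- .as_residues(peptide)
  stopifnot(all(res %in% AA20), all(phi > 0),
            gc_target >= 0.05, gc_target <= 0.95)
  n <- length(res)
  phi <- rep_len(phi, n)
  ct <- codon_classification_table()
  out <- character(n)
  for (aa in unique(res)) {
    fam <- ct$codon[ct$amino_acid == aa]
    frag <- ct$status[ct$amino_acid == aa] == "fragile"
    gc <- .codon_gc(fam)
    gc_w <- gc_target^gc * (1 - gc_target)^(3 - gc)
    idx <- which(res == aa)
    for (ph in unique(phi[idx])) {
      sel <- idx[phi[idx] == ph]
      w <- ifelse(frag, ph, 1) * gc_w
      if (length(fam) == 1L) {
        out[sel] <- fam
      } else {
        out[sel] <- sample(fam, length(sel), replace = TRUE,
                           prob = w / sum(w))
      }
    }
  }
  out
}

.random_nt <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(NUCS, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults describe the desk-scale stand-in for the genome-wide analysis:
#' 2000 multi-exon and 500 single-exon genes; multi-exon genes carry the
#' reference codon usage upstream (phi = 1) with last-exon fragile codons
#' depleted to an expected last/upstream NFCU ratio of 0.93; single-exon
#' genes are depleted to an expected single/multi gene-level NFCU ratio of
#' 0.92 and fragile amino acids to an expected FAU ratio of 0.83; the
#' histone-like class (absent by default) is depleted more strongly
#' (NFCU ratio 0.68, FAU ratio 0.76). The gene-level expectation for
#' multi-exon genes accounts for the depleted last-exon share of codons
#' (E[1/exon_count] under the exon-count distribution), so the configured
#' intergenic ratio is the true gene-level ratio, not the upstream-only one.
#'
#' @param n_multi,n_single,n_histone Genes per class.
#' @param exon_lambda Multi-exon count is 2 + Poisson(exon_lambda).
#' @param cds_len_multi,cds_len_single,cds_len_histone Inclusive codon-count
#'   ranges (length-2 integer vectors) sampled uniformly.
#' @param nfcu_ratio_single,nfcu_ratio_histone Target gene-level NFCU ratios
#'   versus multi-exon genes.
#' @param nfcu_ratio_last Target last-exon/upstream NFCU ratio within
#'   multi-exon genes.
#' @param fau_ratio_single,fau_ratio_histone Target FAU ratios versus
#'   multi-exon genes.
#' @param gc_range Per-gene GC target drawn uniformly from this range.
#' @param intron_len_range,utr3_len_range,utr5_len,spacer_range Structure
#'   lengths in nt.
#' @param reliable_fraction Fraction of multi-exon genes built to satisfy
#'   the reliable-last-exon criteria (the rest get a short 3' UTR or a
#'   downstream non-coding exon).
#' @param genes_per_contig Genes placed per synthetic contig.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_multi = 2000L, n_single = 500L,
                             n_histone = 0L,
                             exon_lambda = 4,
                             cds_len_multi = c(150L, 700L),
                             cds_len_single = c(100L, 500L),
                             cds_len_histone = c(100L, 160L),
                             nfcu_ratio_single = 0.92,
                             nfcu_ratio_histone = 0.68,
                             nfcu_ratio_last = 0.93,
                             fau_ratio_single = 0.83,
                             fau_ratio_histone = 0.76,
                             gc_range = c(0.4, 0.6),
                             intron_len_range = c(60L, 200L),
                             utr3_len_range = c(120L, 300L),
                             utr5_len = 100L,
                             spacer_range = c(100L, 300L),
                             reliable_fraction = 1,
                             genes_per_contig = 100L,
                             seed = 1L) {
  cfg <- list(n_multi = n_multi, n_single = n_single, n_histone = n_histone,
              exon_lambda = exon_lambda,
              cds_len_multi = cds_len_multi, cds_len_single = cds_len_single,
              cds_len_histone = cds_len_histone,
              nfcu_ratio_single = nfcu_ratio_single,
              nfcu_ratio_histone = nfcu_ratio_histone,
              nfcu_ratio_last = nfcu_ratio_last,
              fau_ratio_single = fau_ratio_single,
              fau_ratio_histone = fau_ratio_histone,
              gc_range = gc_range, intron_len_range = intron_len_range,
              utr3_len_range = utr3_len_range, utr5_len = utr5_len,
              spacer_range = spacer_range,
              reliable_fraction = reliable_fraction,
              genes_per_contig = genes_per_contig, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @param config A configuration list.
#' @export
validate_synthetic_config <- function(config) {
  with(config, {
    if (any(c(nfcu_ratio_single, nfcu_ratio_histone, nfcu_ratio_last,
              fau_ratio_single, fau_ratio_histone) <= 0)) {
      stop("all target ratios must be > 0", call. = FALSE)
    }
    if (min(cds_len_multi) < 30L || min(cds_len_single) < 30L ||
        min(cds_len_histone) < 30L) {
      stop("CDS length ranges must be >= 30 codons", call. = FALSE)
    }
    if (min(intron_len_range) < 20L) {
      stop("introns must be >= 20 nt (GT..AG plus interior)", call. = FALSE)
    }
    if (min(utr3_len_range) < 100L) {
      stop("reliable 3' UTR range must be >= 100 nt; the unreliable class ",
           "is generated separately via reliable_fraction", call. = FALSE)
    }
    if (reliable_fraction < 0 || reliable_fraction > 1) {
      stop("reliable_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (gc_range[1] < 0.05 || gc_range[2] > 0.95) {
      stop("gc_range outside [0.05, 0.95]", call. = FALSE)
    }
  })
  invisible(config)
}

# expected fraction of CDS codons falling in the last exon under the
# exon-count distribution (uniform cut points => expected share 1/k)
.expected_last_share <- function(exon_lambda, kmax = 60L) {
  k <- 2L + 0:kmax
  w <- stats::dpois(0:kmax, exon_lambda)
  sum(w / k) / sum(w)
}

# derive per-class sampling weights from the configured target ratios
.generator_weights <- function(config) {
  e1 <- expected_nfcu(1)
  phi_last <- .solve_weight(config$nfcu_ratio_last * e1, expected_nfcu)
  w_last <- .expected_last_share(config$exon_lambda)
  # gene-level multi-exon expectation mixes upstream and depleted last exon
  e_multi_gene <- (1 - w_last) * e1 + w_last * expected_nfcu(phi_last)
  list(
    phi_upstream = 1,
    phi_last = phi_last,
    phi_single = .solve_weight(config$nfcu_ratio_single * e_multi_gene,
                               expected_nfcu),
    phi_histone = .solve_weight(config$nfcu_ratio_histone * e_multi_gene,
                                expected_nfcu),
    psi_multi = 1,
    psi_single = .solve_weight(config$fau_ratio_single * expected_fau(1),
                               expected_fau),
    psi_histone = .solve_weight(config$fau_ratio_histone * expected_fau(1),
                                expected_fau),
    expected_multi_gene_nfcu = e_multi_gene)
}

#' Generate a synthetic genome (FASTA + GFF3 + truth manifest)
#'
#' Builds gene models on synthetic contigs (both strands, non-overlapping,
#' separated by random spacers): multi-exon genes receive GT..AG-flanked
#' introns at uniformly random CDS nucleotide boundaries (so junction phases
#' are uniform over 0/1/2), a 5' UTR, a terminal stop codon and a 3' UTR of
#' at least 100 nt for the reliable fraction; unreliable genes get either a
#' short 3' UTR or a downstream non-coding exon. Per-class fragile codon
#' and amino-acid weights are derived from the configured target ratios (see
#' [synthetic_config()]); within multi-exon genes, codons completely encoded
#' by the last exon use `phi_last`, all others (including any
#' junction-spanning codon) `phi_upstream`. The emitted files round-trip
#' exactly through
#' [load_annotation()], and identical config + seed give byte-identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return A list with `fasta`, `gff3`, `manifest_path` (file paths),
#'   `manifest` (data.frame: gene_id, class, strand, exon_count, cds_len,
#'   phi_upstream, phi_last, psi, gc_target, utr3_len, reliable,
#'   realized_nfcu, realized_fau, seed) and `weights` (the derived per-class
#'   weights).
#' @export
build_genome <- function(config = synthetic_config(), dir = tempfile("syngenome")) {
  validate_synthetic_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  wts <- .generator_weights(config)

  classes <- c(rep("multi_exon", config$n_multi),
               rep("single_exon", config$n_single),
               rep("histone_like", config$n_histone))
  n_genes <- length(classes)
  if (n_genes == 0L) stop("no genes requested", call. = FALSE)

  gff <- c("##gff-version 3")
  contigs <- list()
  cur <- list()        # growing pieces of the current contig
  cur_len <- 0L
  contig_i <- 1L
  manifest <- vector("list", n_genes)

  flush_contig <- function() {
    if (cur_len > 0L) {
      contigs[[sprintf("ctg%03d", contig_i)]] <<- paste(unlist(cur),
                                                        collapse = "")
      contig_i <<- contig_i + 1L
      cur <<- list()
      cur_len <<- 0L
    }
  }

  for (gi in seq_len(n_genes)) {
    if (gi > 1L && (gi - 1L) %% config$genes_per_contig == 0L) flush_contig()
    cls <- classes[gi]
    gid <- sprintf("gene%05d", gi)
    tid <- sprintf("tx%05d", gi)
    strand <- if (gi %% 2L == 1L) "+" else "-"
    gc <- stats::runif(1, config$gc_range[1], config$gc_range[2])

    len_range <- switch(cls, multi_exon = config$cds_len_multi,
                        single_exon = config$cds_len_single,
                        histone_like = config$cds_len_histone)
    cds_len <- sample(len_range[1]:len_range[2], 1L)
    n_exons <- if (cls == "multi_exon") {
      2L + stats::rpois(1, config$exon_lambda)
    } else 1L

    psi <- switch(cls, multi_exon = wts$psi_multi,
                  single_exon = wts$psi_single,
                  histone_like = wts$psi_histone)
    pep <- sample_peptide(cds_len, psi)

    # intron cut points within the stop-stripped CDS (after nt p)
    L0 <- 3L * cds_len
    cuts <- if (n_exons > 1L) {
      sort(sample(seq_len(L0 - 1L), n_exons - 1L))
    } else integer(0)

    phi_up <- switch(cls, multi_exon = wts$phi_upstream,
                     single_exon = wts$phi_single,
                     histone_like = wts$phi_histone)
    phi_last <- if (cls == "multi_exon") wts$phi_last else phi_up
    codon_start <- 3L * seq_len(cds_len) - 2L
    phi_vec <- ifelse(n_exons > 1L & codon_start > if (length(cuts))
      cuts[length(cuts)] else 0L, phi_last, phi_up)
    if (n_exons == 1L) phi_vec <- rep(phi_up, cds_len)

    codons <- reverse_translate(pep, phi_vec, gc)
    stop_cod <- sample(stop_codons(), 1L)
    cds_nt <- paste(c(codons, stop_cod), collapse = "")

    reliable <- cls != "multi_exon" ||
      stats::runif(1) <= config$reliable_fraction
    unreliable_kind <- if (reliable) "none" else
      sample(c("short_utr3", "downstream_exon"), 1L)
    utr3_len <- if (unreliable_kind == "short_utr3") {
      sample(20L:80L, 1L)
    } else {
      sample(config$utr3_len_range[1]:config$utr3_len_range[2], 1L)
    }
    utr5 <- .random_nt(config$utr5_len, gc)
    utr3 <- .random_nt(utr3_len, gc)

    # exon nucleotide content in transcript coordinates
    # exon 1..n: cds split at cuts; stop + 3' UTR appended to final exon,
    # 5' UTR prepended to exon 1
    bounds <- c(0L, cuts, L0 + 3L)  # stop travels with the last exon
    cds_parts <- substring(cds_nt, bounds[-length(bounds)] + 1L,
                           bounds[-1])
    exon_parts <- cds_parts
    exon_parts[1] <- paste0(utr5, exon_parts[1])
    exon_parts[length(exon_parts)] <- paste0(exon_parts[length(exon_parts)],
                                             utr3)
    extra_exon <- NULL
    if (unreliable_kind == "downstream_exon") {
      # split the 3' UTR across an extra non-coding exon
      half <- utr3_len %/% 2L
      exon_parts[length(exon_parts)] <-
        paste0(cds_parts[length(cds_parts)], substring(utr3, 1L, half))
      extra_exon <- substring(utr3, half + 1L, utr3_len)
      exon_parts <- c(exon_parts, extra_exon)
    }
    n_exons_total <- length(exon_parts)
    introns <- vapply(seq_len(max(n_exons_total - 1L, 0L)), function(i) {
      ilen <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1L)
      paste0("GT", .random_nt(ilen - 4L, gc), "AG")
    }, "")

    # assemble plus-strand gene sequence and local coordinates
    pieces <- character(0)
    exon_coords <- matrix(0L, nrow = n_exons_total, ncol = 2L)
    pos <- 0L
    for (e in seq_len(n_exons_total)) {
      exon_coords[e, 1] <- pos + 1L
      pos <- pos + nchar(exon_parts[e])
      exon_coords[e, 2] <- pos
      pieces <- c(pieces, exon_parts[e])
      if (e < n_exons_total) {
        pieces <- c(pieces, introns[e])
        pos <- pos + nchar(introns[e])
      }
    }
    gene_seq <- paste(pieces, collapse = "")
    gene_len <- nchar(gene_seq)

    # CDS segments in local transcript-plus coordinates
    n_cds_exons <- length(cds_parts)
    cds_coords <- matrix(0L, nrow = n_cds_exons, ncol = 2L)
    for (e in seq_len(n_cds_exons)) {
      off <- if (e == 1L) config$utr5_len else 0L
      cds_coords[e, 1] <- exon_coords[e, 1] + off
      cds_coords[e, 2] <- cds_coords[e, 1] + nchar(cds_parts[e]) - 1L
    }
    cum <- cumsum(c(0L, nchar(cds_parts)))
    phases <- (3L - cum[-length(cum)] %% 3L) %% 3L

    # UTR coordinates (local): 5' UTR in exon 1; 3' UTR after the stop
    utr5_coords <- c(exon_coords[1, 1], exon_coords[1, 1] + config$utr5_len - 1L)
    utr3_coords <- matrix(0L, nrow = 0L, ncol = 2L)
    if (utr3_len > 0L) {
      u3s <- cds_coords[n_cds_exons, 2] + 1L
      if (is.null(extra_exon)) {
        utr3_coords <- rbind(utr3_coords, c(u3s, u3s + utr3_len - 1L))
      } else {
        utr3_coords <- rbind(
          utr3_coords,
          c(u3s, exon_coords[n_cds_exons, 2]),
          exon_coords[n_exons_total, ])
      }
    }

    # place on contig
    spacer <- .random_nt(sample(config$spacer_range[1]:config$spacer_range[2],
                                1L), 0.5)
    offset <- cur_len + nchar(spacer)
    cur[[length(cur) + 1L]] <- spacer
    cur[[length(cur) + 1L]] <- if (strand == "+") gene_seq else
      .revcomp(gene_seq)
    cur_len <- offset + gene_len
    ctg <- sprintf("ctg%03d", contig_i)

    loc2gen <- function(m) {
      # local plus-strand [a,b] -> genomic 1-based inclusive
      m <- matrix(m, ncol = 2L)
      if (strand == "+") {
        cbind(offset + m[, 1], offset + m[, 2])
      } else {
        cbind(offset + gene_len - m[, 2] + 1L, offset + gene_len - m[, 1] + 1L)
      }
    }
    gl <- function(a, b, type, id = NULL, parent = NULL, phase = ".") {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              ctg, type, a, b, strand, phase, paste(attrs, collapse = ";"))
    }
    g_span <- loc2gen(c(1L, gene_len))
    gff <- c(gff, gl(g_span[1], g_span[2], "gene", id = gid))
    gff <- c(gff, gl(g_span[1], g_span[2], "mRNA", id = tid, parent = gid))
    ex_g <- loc2gen(exon_coords)
    for (e in seq_len(nrow(ex_g))) {
      gff <- c(gff, gl(ex_g[e, 1], ex_g[e, 2], "exon",
                       id = sprintf("%s.e%d", tid, e), parent = tid))
    }
    cds_g <- loc2gen(cds_coords)
    for (e in seq_len(nrow(cds_g))) {
      gff <- c(gff, gl(cds_g[e, 1], cds_g[e, 2], "CDS",
                       id = paste0(tid, ".cds"), parent = tid,
                       phase = as.character(phases[e])))
    }
    u5g <- loc2gen(utr5_coords)
    gff <- c(gff, gl(u5g[1], u5g[2], "five_prime_UTR",
                     id = paste0(tid, ".u5"), parent = tid))
    if (nrow(utr3_coords)) {
      u3g <- loc2gen(utr3_coords)
      for (e in seq_len(nrow(u3g))) {
        gff <- c(gff, gl(u3g[e, 1], u3g[e, 2], "three_prime_UTR",
                         id = sprintf("%s.u3.%d", tid, e), parent = tid))
      }
    }

    manifest[[gi]] <- data.frame(
      gene_id = gid, transcript_id = tid, class = cls, strand = strand,
      exon_count = n_exons_total, cds_len = cds_len,
      phi_upstream = phi_up, phi_last = phi_last, psi = psi,
      gc_target = gc, utr3_len = utr3_len, reliable = reliable,
      realized_nfcu = .nfcu_value(codons),
      realized_fau = .fau_value(pep),
      seed = config$seed, stringsAsFactors = FALSE)
  }
  flush_contig()

  fasta_path <- file.path(dir, "genome.fasta")
  gff_path <- file.path(dir, "genes.gff3")
  manifest_path <- file.path(dir, "manifest.tsv")
  fa_lines <- unlist(lapply(names(contigs), function(nm) {
    s <- contigs[[nm]]
    c(paste0(">", nm),
      substring(s, seq(1L, nchar(s), 70L),
                pmin(seq(1L, nchar(s), 70L) + 69L, nchar(s))))
  }))
  writeLines(fa_lines, fasta_path)
  writeLines(gff, gff_path)
  man <- do.call(rbind, manifest)
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta_path, gff3 = gff_path, manifest_path = manifest_path,
       manifest = man, weights = wts)
}

#' Simulate a diverged ortholog of a CDS
#'
#' Applies Poisson numbers of synonymous and nonsynonymous single-nucleotide
#' substitutions (expectations `target_ks * S` and `omega * target_ks * N`,
#' with S and N the NG86 site counts of the input) at uniformly chosen
#' eligible positions; substitutions creating stop codons are rejected.
#' Repeated hits at the same site arise naturally, which is what the
#' Jukes-Cantor correction in [ng86()] undoes on estimation.
#'
#' @param codons Codon vector or nucleotide string (stop-stripped CDS).
#' @param target_ks Expected synonymous substitutions per synonymous site.
#' @param omega Ka/Ks of the substitution regime (0 = no amino-acid change).
#' @return Character vector of mutated codons, same length as the input.
#' @export
simulate_ortholog <- function(codons, target_ks, omega) {
  stopifnot(target_ks >= 0, omega >= 0)
  if (target_ks > 1.5) {
    warning("target_ks > 1.5: synonymous sites near saturation",
            call. = FALSE)
  }
  cods <- .as_codons(codons)
  if (target_ks == 0) return(cods)
  code <- standard_genetic_code()
  sites <- vapply(cods, .ng86_sites, c(syn = 0, nonsyn = 0))
  S <- sum(sites["syn", ])
  N <- sum(sites["nonsyn", ])
  n_syn <- stats::rpois(1, target_ks * S)
  n_non <- stats::rpois(1, omega * target_ks * N)
  events <- sample(c(rep("syn", n_syn), rep("non", n_non)))
  for (ev in events) {
    repeat {
      i <- sample(length(cods), 1L)
      pos <- sample(3L, 1L)
      nts <- strsplit(cods[i], "")[[1]]
      alt <- sample(setdiff(NUCS, nts[pos]), 1L)
      mut <- nts
      mut[pos] <- alt
      mut <- paste(mut, collapse = "")
      if (code[[mut]] == "*") next
      is_syn <- code[[mut]] == code[[cods[i]]]
      if ((ev == "syn") == is_syn) {
        cods[i] <- mut
        break
      }
    }
  }
  cods
}
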