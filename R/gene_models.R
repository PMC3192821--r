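#' @importFrom rtracklayer import
#' @importFrom GenomicRanges start end strand seqnames
#' @importFrom IRanges IRanges reduce width
#' @importFrom S4Vectors mcols
NULL

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

.translate_codons <- function(codons) {
  code <- standard_genetic_code()
  aa <- code[codons]
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  unname(aa)
}

# Build one transcript model from per-feature data.frames (genomic,
# 1-based inclusive as in GFF3) plus the contig sequence as a character
# string. All derived coordinates are transcript-oriented.
.build_transcript <- function(gene_id, transcript_id, chrom, strand,
                              exons, cdss, utr3_len, utr5_len, contig_seq) {
  flags <- character(0)
  minus <- identical(strand, "-")
  ord <- order(exons$start, decreasing = minus)  # transcription order
  exons <- exons[ord, , drop = FALSE]
  ordc <- order(cdss$start, decreasing = minus)
  cdss <- cdss[ordc, , drop = FALSE]

  # map each CDS segment to its containing exon (cds_segments subset exons)
  seg_exon <- integer(nrow(cdss))
  for (i in seq_len(nrow(cdss))) {
    j <- which(exons$start <= cdss$start[i] & exons$end >= cdss$end[i])
    if (length(j) != 1L) {
      flags <- c(flags, "cds_outside_exon")
      j <- which.min(pmin(abs(exons$start - cdss$start[i]),
                          abs(exons$end - cdss$end[i])))
    }
    seg_exon[i] <- j[1]
  }

  seg_seq <- substring(contig_seq, cdss$start, cdss$end)
  cds_nt <- if (minus) .revcomp(paste(rev(seg_seq), collapse = "")) else
    paste(seg_seq, collapse = "")

  phase0 <- cdss$phase[1]
  if (is.na(phase0)) phase0 <- 0L
  if (phase0 > 0L) {
    cds_nt <- substring(cds_nt, phase0 + 1L, nchar(cds_nt))
    flags <- c(flags, "nonzero_initial_phase")
  }

  if (nchar(cds_nt) %% 3L != 0L) flags <- c(flags, "length_not_multiple_of_3")
  n_full <- nchar(cds_nt) %/% 3L
  codons_full <- substring(cds_nt, 3L * seq_len(n_full) - 2L,
                           3L * seq_len(n_full))
  ends_with_stop <- n_full > 0L && codons_full[n_full] %in% stop_codons()
  if (!ends_with_stop) flags <- c(flags, "no_terminal_stop")
  cds_codons <- if (ends_with_stop) codons_full[-n_full] else codons_full
  if (any(cds_codons %in% stop_codons())) flags <- c(flags, "internal_stop")

  # exon index of every spliced CDS nucleotide (post phase trim)
  seg_len <- cdss$end - cdss$start + 1L
  nt_exon <- rep(seg_exon, seg_len)
  if (phase0 > 0L && length(nt_exon) >= phase0) {
    nt_exon <- nt_exon[-seq_len(phase0)]
  }
  # exon of each retained (stop-stripped) codon; NA if junction-spanning
  n_cod <- length(cds_codons)
  exon_of_codon <- integer(0)
  if (n_cod > 0L) {
    e1 <- nt_exon[3L * seq_len(n_cod) - 2L]
    e2 <- nt_exon[3L * seq_len(n_cod) - 1L]
    e3 <- nt_exon[3L * seq_len(n_cod)]
    exon_of_codon <- ifelse(e1 == e2 & e2 == e3, e1, NA_integer_)
  }

  stop_exon <- if (length(nt_exon)) nt_exon[length(nt_exon)] else NA_integer_
  has_downstream_exon <- !is.na(stop_exon) && stop_exon < nrow(exons)

  peptide <- paste(.translate_codons(cds_codons), collapse = "")

  structure(list(
    gene_id = gene_id, transcript_id = transcript_id,
    seqname = chrom, strand = strand,
    exons = exons, cds_segments = cdss, cds_exon_index = seg_exon,
    cds_codons = cds_codons,
    stop_codon = if (ends_with_stop) codons_full[n_full] else NA_character_,
    peptide = peptide, peptide_length = length(cds_codons),
    exon_of_codon = exon_of_codon,
    n_exons = nrow(exons),
    utr3_len = utr3_len, utr5_len = utr5_len,
    stop_exon = stop_exon,
    has_downstream_noncoding_exon = has_downstream_exon,
    flags = unique(flags)), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "transcript %s (gene %s, %s strand): %d exon(s), %d codons, 3'UTR %d nt%s\n",
    x$transcript_id, x$gene_id, x$strand, x$n_exons,
    length(x$cds_codons), x$utr3_len,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Load gene models from FASTA + GFF3
#'
#' Parses a genome FASTA and a GFF3 annotation (gene/mRNA/exon/CDS and UTR
#' features, 1-based inclusive coordinates), builds strand-resolved
#' transcript models and selects one representative transcript per gene (the
#' one encoding the longest peptide; ties broken by lexicographically
#' smallest transcript identifier). Minus-strand transcripts are
#' reverse-complemented into transcript orientation and CDS phase offsets are
#' honored. Transcripts whose CDS does not end in a stop codon, is not a
#' multiple of 3, or contains internal stops are flagged in the validation
#' table, never silently dropped.
#'
#' @param fasta_path Path to genome FASTA (plain or gzip).
#' @param gff3_path Path to GFF3 annotation.
#' @return Object of class `"gene_model_set"`: a list with `models` (named
#'   list of representative `transcript_model`s, one per gene), `validation`
#'   (per-transcript data.frame of flags) and `n_genes`.
#' @export
load_annotation <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contig <- vapply(as.character(seqs), toupper, "")
  names(contig) <- names(seqs)

  gr <- rtracklayer::import(gff3_path)
  df <- data.frame(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    phase = if (!is.null(gr$phase)) as.integer(as.character(gr$phase))
      else NA_integer_,
    stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_, "")

  missing_seq <- setdiff(unique(df$seqnames), names(contig))
  if (length(missing_seq)) {
    stop("sequence region(s) missing from FASTA: ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  kids <- df[df$type %in% c("exon", "CDS", "three_prime_UTR",
                            "five_prime_UTR"), , drop = FALSE]
  kid_split <- split(seq_len(nrow(kids)), kids$parent)

  models <- vector("list", nrow(mrna))
  val <- vector("list", nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$ID[i]
    gid <- mrna$parent[i]
    ki <- kids[kid_split[[tid]], , drop = FALSE]
    exons <- ki[ki$type == "exon", c("start", "end"), drop = FALSE]
    cdss <- ki[ki$type == "CDS", c("start", "end", "phase"), drop = FALSE]
    if (nrow(exons) == 0L && nrow(cdss) > 0L) {
      exons <- cdss[, c("start", "end"), drop = FALSE]
    }
    if (nrow(cdss) == 0L) {
      val[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                             flags = "non_coding", stringsAsFactors = FALSE)
      next
    }
    tm <- .build_transcript(
      gid, tid, mrna$seqnames[i], mrna$strand[i], exons, cdss,
      utr3_len = sum(ki$end[ki$type == "three_prime_UTR"] -
                       ki$start[ki$type == "three_prime_UTR"] + 1L),
      utr5_len = sum(ki$end[ki$type == "five_prime_UTR"] -
                       ki$start[ki$type == "five_prime_UTR"] + 1L),
      contig_seq = contig[[mrna$seqnames[i]]])
    models[[i]] <- tm
    val[[i]] <- data.frame(
      gene_id = gid, transcript_id = tid,
      flags = paste(tm$flags, collapse = ","), stringsAsFactors = FALSE)
  }
  models <- models[!vapply(models, is.null, TRUE)]
  names(models) <- vapply(models, `[[`, "", "transcript_id")

  # representative transcript per gene
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  reps <- lapply(by_gene, select_representative_transcript)
  reps <- reps[order(names(reps))]

  structure(list(models = reps,
                 validation = do.call(rbind, val),
                 n_genes = length(reps)),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes (%d representative transcripts)\n",
              x$n_genes, length(x$models)))
  flagged <- x$validation$flags != ""
  if (any(flagged)) cat(sprintf("  %d flagged transcript(s)\n", sum(flagged)))
  invisible(x)
}

#' Select the representative transcript of a gene
#'
#' The transcript encoding the longest peptide; ties are broken by the
#' lexicographically smallest transcript identifier so the choice is
#' deterministic.
#'
#' @param transcripts A list of `transcript_model`s belonging to one gene.
#' @return A single `transcript_model`.
#' @export
select_representative_transcript <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  lens <- as.numeric(vapply(transcripts, `[[`, numeric(1),
                            "peptide_length"))
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  transcripts[[order(-lens, ids)[1]]]
}

#' Exon count of a transcript
#'
#' Counts all annotated exons, coding and non-coding. A gene is single-exon
#' iff this count is 1; a non-coding extra exon makes a gene multi-exon.
#'
#' @param transcript A `transcript_model`.
#' @return Integer exon count.
#' @export
exon_count <- function(transcript) {
  transcript$n_exons
}

#' Is the transcript's last exon reliably annotated?
#'
#' True iff (i) the annotated CDS terminates with a stop codon, (ii) no exon
#' lies downstream of the exon containing that stop (so there is no
#' downstream exon junction complex), and (iii) the annotated (spliced)
#' 3' UTR is at least `min_utr3` nucleotides.
#'
#' @param transcript A `transcript_model` (multi-exon).
#' @param min_utr3 Minimum 3' UTR length in nt (default 100).
#' @return Logical.
#' @export
is_reliable_last_exon <- function(transcript, min_utr3 = 100L) {
  !is.na(transcript$stop_codon) &&
    !transcript$has_downstream_noncoding_exon &&
    transcript$utr3_len >= min_utr3
}

#' Assign CDS codons to exons
#'
#' Each stop-stripped CDS codon is assigned to the exon that completely
#' encodes it (in transcript order); codons spanning an exon-exon junction
#' are assigned to no exon.
#'
#' @param transcript A `transcript_model`.
#' @return A list of `exon_codons` records: `exon_index`, `codons`
#'   ([codon_sequence()]), `is_last`. One record per exon containing at least
#'   the possibility of codons (all exons reported, coding or not).
#' @export
assign_codons_to_exons <- function(transcript) {
  n_ex <- transcript$n_exons
  out <- vector("list", n_ex)
  for (e in seq_len(n_ex)) {
    idx <- which(!is.na(transcript$exon_of_codon) &
                   transcript$exon_of_codon == e)
    out[[e]] <- list(
      exon_index = e,
      codons = codon_sequence(transcript$cds_codons[idx],
                              label = sprintf("%s:exon%d",
                                              transcript$transcript_id, e)),
      is_last = e == n_ex)
  }
  out
}

#' Is the CDS completely contained in the last exon?
#'
#' @param transcript A multi-exon `transcript_model`.
#' @return Logical; `NA` for single-exon transcripts (outside the
#'   precondition).
#' @export
cds_in_last_exon <- function(transcript) {
  if (transcript$n_exons < 2L) return(NA)
  all(transcript$cds_exon_index == transcript$n_exons)
}

# CDS nucleotides (stop-stripped coordinates) upstream of the last
# exon-exon junction, i.e. located in exons other than the last one.
.junction_offset <- function(transcript) {
  seg_len <- transcript$cds_segments$end - transcript$cds_segments$start + 1L
  in_last <- transcript$cds_exon_index == transcript$n_exons
  up <- sum(seg_len[!in_last])
  # subtract initial phase trim from the upstream tally, and ignore the
  # terminal stop (it lies in the last exon and does not affect 'up')
  phase0 <- transcript$cds_segments$phase[1]
  if (is.na(phase0)) phase0 <- 0L
  max(up - phase0, 0L)
}

#' Extract NMD boundary windows around the last exon-exon junction
#'
#' For a window-eligible transcript, returns two non-overlapping windows of
#' `window_size` codons flanking the boundary of intron-dependent
#' (EJC-mediated) nonsense surveillance: a 3' window of the first
#' `window_size` codons completely encoded by the last exon (the
#' NMD-compromised side) and a 5' window of `window_size` contiguous codons
#' whose last nucleotide lies at least `buffer_nt` nucleotides upstream of
#' the last exon-exon junction (the NMD-competent side), placed as close to
#' that bound as codon boundaries allow. A codon spanning the junction
#' appears in neither window.
#'
#' Eligibility: the transcript is multi-exon with a reliable last exon (see
#' [is_reliable_last_exon()]), the last exon completely encodes more than
#' `min_last_exon_codons` codons, and at least `window_size` codons are
#' available upstream of the buffer. Ineligible transcripts yield
#' `eligible = FALSE` with a `reason` code (`"single_exon"`,
#' `"unreliable_last_exon"`, `"last_exon_too_short"`,
#' `"insufficient_upstream_codons"`).
#'
#' @param transcript A `transcript_model`.
#' @param window_size Window size in codons (default 50).
#' @param buffer_nt Buffer between the 5' window end and the junction in
#'   nucleotides (default 50; the boundary of EJC-dependent surveillance is
#'   described as 50-55 nt upstream of the last junction, so this is
#'   configurable).
#' @param min_last_exon_codons Last exon must encode more than this many
#'   codons (default 100).
#' @return A list: `eligible` (logical); when eligible, `five_prime_window`
#'   and `three_prime_window` ([codon_sequence()]s), their 1-based start
#'   codon indices `five_start_codon` / `three_start_codon` within the
#'   stop-stripped CDS, and `buffer_used_nt` (realized distance between the
#'   5' window end and the junction); otherwise `reason`.
#' @export
extract_boundary_windows <- function(transcript, window_size = 50L,
                                     buffer_nt = 50L,
                                     min_last_exon_codons = 100L) {
  if (transcript$n_exons < 2L) {
    return(list(eligible = FALSE, reason = "single_exon"))
  }
  if (!is_reliable_last_exon(transcript)) {
    return(list(eligible = FALSE, reason = "unreliable_last_exon"))
  }
  j <- .junction_offset(transcript)
  n_cod <- length(transcript$cds_codons)
  # first codon completely encoded by the last exon
  first_last <- j %/% 3L + 1L + as.integer(j %% 3L != 0L)
  n_last <- n_cod - first_last + 1L
  if (n_last <= min_last_exon_codons) {
    return(list(eligible = FALSE, reason = "last_exon_too_short"))
  }
  # last codon of the 5' window: ends at nt 3k <= j - buffer_nt
  k <- (j - buffer_nt) %/% 3L
  if (k < window_size) {
    return(list(eligible = FALSE, reason = "insufficient_upstream_codons"))
  }
  five <- transcript$cds_codons[(k - window_size + 1L):k]
  three <- transcript$cds_codons[first_last:(first_last + window_size - 1L)]
  list(eligible = TRUE,
       five_prime_window = codon_sequence(
         five, label = paste0(transcript$transcript_id, ":5prime")),
       three_prime_window = codon_sequence(
         three, label = paste0(transcript$transcript_id, ":3prime")),
       five_start_codon = k - window_size + 1L,
       three_start_codon = first_last,
       buffer_used_nt = j - 3L * k)
}

#' Exonic splicing enhancer (ESE) coverage density
#'
#' The fraction of nucleotide positions of `seq` covered by at least one
#' occurrence of any hexamer in the set (overlapping occurrences are merged).
#' Sequences shorter than 6 nt have zero coverage.
#'
#' @param seq A nucleotide string.
#' @param hexamers Character vector of 6-mers (e.g. a RESCUE-ESE set).
#' @return Fraction in `[0, 1]`.
#' @export
ese_density <- function(seq, hexamers) {
  if (!length(hexamers)) stop("hexamer set is empty", call. = FALSE)
  cov <- .ese_coverage_ranges(toupper(seq), toupper(hexamers))
  if (nchar(seq) == 0L) return(0)
  sum(IRanges::width(cov)) / nchar(seq)
}

.ese_coverage_ranges <- function(seq, hexamers) {
  if (nchar(seq) < 6L) return(IRanges::IRanges())
  subj <- Biostrings::DNAString(seq)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unique(hexamers)))
  m <- Biostrings::matchPDict(pd, subj)
  IRanges::reduce(unlist(m))
}

#' Partition codons by ESE overlap
#'
#' A codon overlaps an ESE iff at least one of its three nucleotides is
#' covered by a hexamer occurrence within the surrounding sequence context;
#' the partition into overlapping and external codons is exhaustive and
#' disjoint. By default the context is the concatenation of the codons
#' themselves; pass `context`/`offset_nt` to locate the codons inside a
#' larger CDS (codon i then occupies context nucleotides
#' `offset_nt + 3i - 2 ... offset_nt + 3i`).
#'
#' @param codons A [codon_sequence()] or codon vector.
#' @param hexamers Character vector of 6-mers.
#' @param context Nucleotide string in which coverage is computed (default:
#'   the codons pasted together).
#' @param offset_nt 0-based nucleotide offset of the first codon within
#'   `context`.
#' @return A list with `overlapping` and `external` [codon_sequence()]s.
#' @export
partition_codons_by_ese <- function(codons, hexamers, context = NULL,
                                    offset_nt = 0L) {
  cods <- .as_codons(codons)
  if (is.null(context)) context <- paste(cods, collapse = "")
  cov <- .ese_coverage_ranges(toupper(context), toupper(hexamers))
  covered <- rep(FALSE, nchar(context))
  if (length(cov)) {
    for (i in seq_along(cov)) {
      covered[IRanges::start(cov)[i]:IRanges::end(cov)[i]] <- TRUE
    }
  }
  n <- length(cods)
  starts <- offset_nt + 3L * seq_len(n) - 2L
  hit <- vapply(seq_len(n), function(i) {
    any(covered[starts[i]:(starts[i] + 2L)])
  }, TRUE)
  lab <- attr(codons, "label") %||% NA_character_
  list(overlapping = codon_sequence(cods[hit], label = lab),
       external = codon_sequence(cods[!hit], label = lab))
}

#' Fraction of optimal codons (Fop)
#'
#' `mode = "raw"`: the number of optimal codons divided by the number of
#' codons belonging to amino acids with two or more synonymous codons.
#' `mode = "gc_controlled"`: an NFCU-style normalization — within each
#' synonymous family, codons are partitioned by G+C count, subgroups
#' containing both optimal and non-optimal codons are retained, and the
#' value is the unweighted mean of the per-subgroup optimal fractions
#' (UNDEFINED, `NA`, when no retained subgroup is represented).
#'
#' @param codons A [codon_sequence()] or codon vector.
#' @param optimal_codons Non-empty character vector of species-specific
#'   optimal codons.
#' @param mode `"raw"` or `"gc_controlled"`.
#' @return A single numeric fraction (`NA_real_` when undefined).
#' @export
fop <- function(codons, optimal_codons, mode = c("raw", "gc_controlled")) {
  mode <- match.arg(mode)
  if (!length(optimal_codons)) {
    stop("optimal codon set is empty", call. = FALSE)
  }
  optimal_codons <- toupper(optimal_codons)
  cods <- .as_codons(codons)
  ct <- codon_classification_table()
  if (mode == "raw") {
    fam_size <- table(ct$amino_acid)
    multi_aas <- names(fam_size)[fam_size >= 2L]
    multi_codons <- ct$codon[ct$amino_acid %in% multi_aas]
    den <- sum(cods %in% multi_codons)
    if (den == 0L) return(NA_real_)
    return(sum(cods %in% intersect(optimal_codons, multi_codons)) / den)
  }
  # gc_controlled: GC-matched subgroups mixing optimal and non-optimal
  fracs <- numeric(0)
  for (aa in unique(ct$amino_acid)) {
    fam <- ct$codon[ct$amino_acid == aa]
    if (length(fam) < 2L) next
    for (gc in unique(.codon_gc(fam))) {
      sub <- fam[.codon_gc(fam) == gc]
      opt <- sub %in% optimal_codons
      if (any(opt) && any(!opt)) {
        den <- sum(cods %in% sub)
        if (den > 0L) fracs <- c(fracs, sum(cods %in% sub[opt]) / den)
      }
    }
  }
  if (!length(fracs)) return(NA_real_)
  mean(fracs)
}

#' Per-gene structural summary table
#'
#' @param gms A `gene_model_set`.
#' @param hexamers Optional ESE hexamer set (adds an `ese_density` column).
#' @param optimal_codons Optional optimal codon set (adds a `fop` column).
#' @param path Optional path; when given the table is also written as TSV.
#' @return data.frame with one row per gene: identifiers, exon_count,
#'   cds_len_nt, reliable_last_exon, cds_in_last_exon, utr3_len, flags.
#' @export
structural_table <- function(gms, hexamers = NULL, optimal_codons = NULL,
                             path = NULL) {
  rows <- lapply(gms$models, function(tm) {
    data.frame(
      gene_id = tm$gene_id,
      transcript_id = tm$transcript_id,
      exon_count = tm$n_exons,
      cds_len_nt = 3L * length(tm$cds_codons),
      reliable_last_exon = if (tm$n_exons > 1L) is_reliable_last_exon(tm)
        else NA,
      cds_in_last_exon = cds_in_last_exon(tm),
      utr3_len = tm$utr3_len,
      ese_density = if (!is.null(hexamers))
        ese_density(paste(tm$cds_codons, collapse = ""), hexamers)
        else NA_real_,
      fop = if (!is.null(optimal_codons))
        fop(tm$cds_codons, optimal_codons) else NA_real_,
      flags = paste(tm$flags, collapse = ","),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
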