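#' Construct a codon sequence
#'
#' A light wrapper around a character vector of codons (3-letter strings over
#' A/C/G/T/N). The terminal stop codon is expected to have been stripped
#' upstream (see [load_annotation()]); internal stop codons are legal input
#' but flag the sequence, since they indicate a problematic annotation.
#'
#' @param codons Character vector of 3-letter codons, or a single nucleotide
#'   string whose length is a multiple of 3.
#' @param label Identifier of the gene/exon/window the codons come from.
#' @return Object of class `"codon_sequence"`: the codon vector with
#'   attributes `label` and `has_internal_stop`.
#' @export
#' @examples
#' codon_sequence("TCATCTGGG", label = "toy")
codon_sequence <- function(codons, label = NA_character_) {
  if (length(codons) == 1L && nchar(codons) > 3L) {
    if (nchar(codons) %% 3L != 0L) {
      stop("nucleotide string length not a multiple of 3", call. = FALSE)
    }
    codons <- substring(codons, seq(1L, nchar(codons), 3L),
                        seq(3L, nchar(codons), 3L))
  }
  codons <- toupper(as.character(codons))
  if (length(codons) && any(nchar(codons) != 3L)) {
    stop("all codons must have length 3", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", codons)
  if (any(bad)) {
    stop("invalid characters in codons: ", paste(unique(codons[bad]),
         collapse = ", "), call. = FALSE)
  }
  structure(codons,
            label = label,
            has_internal_stop = any(codons %in% stop_codons()),
            class = "codon_sequence")
}

.metric_value <- function(metric, per_group, n_used, n_skipped,
                          label = NA_character_) {
  defined <- per_group$denominator > 0
  value <- if (any(defined)) {
    mean(per_group$numerator[defined] / per_group$denominator[defined])
  } else {
    NA_real_
  }
  structure(list(metric = metric, value = value, defined = any(defined),
                 per_group = per_group, n_used = n_used,
                 n_skipped = n_skipped, label = label),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("%s%s = %s  (n_used = %d, n_skipped = %d)\n",
              x$metric,
              if (is.na(x$label)) "" else paste0("[", x$label, "]"),
              if (x$defined) format(x$value) else "UNDEFINED",
              x$n_used, x$n_skipped))
  invisible(x)
}

#' Extract the numeric value of a metric
#'
#' @param x A `"metric_value"`.
#' @return The value, or `NA_real_` when the metric is undefined for the
#'   sequence (all group denominators zero).
#' @export
metric_value <- function(x) {
  stopifnot(inherits(x, "metric_value"))
  if (x$defined) x$value else NA_real_
}

.as_codons <- function(seq) {
  if (inherits(seq, "codon_sequence")) as.character(seq)
  else as.character(codon_sequence(seq))
}

#' Fragile codon usage (FCU)
#'
#' The fraction of a sequence's sense codons that are fragile (convertible to
#' a stop codon by one point mutation). Codons containing N, and any stop
#' codons present, are excluded from numerator and denominator and tallied in
#' `n_skipped`. A sequence with no countable codon yields an UNDEFINED value
#' rather than an error.
#'
#' @param seq A [codon_sequence()] (or codon vector / nucleotide string).
#' @return A `"metric_value"` with per-group bookkeeping (a single pooled
#'   group for FCU).
#' @export
#' @examples
#' metric_value(fcu(c("TCA", "TCT", "GGG", "TGG")))  # 0.5
fcu <- function(seq) {
  codons <- .as_codons(seq)
  skip <- grepl("N", codons, fixed = TRUE) | codons %in% stop_codons()
  counted <- codons[!skip]
  num <- sum(counted %in% fragile_codons())
  per_group <- data.frame(group_id = "all_sense", numerator = num,
                          denominator = length(counted),
                          stringsAsFactors = FALSE)
  .metric_value("FCU", per_group, length(counted), sum(skip),
                attr(seq, "label") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.group_counts <- function(items, groups) {
  # per-group numerator/denominator counts of fragile vs all members
  data.frame(
    group_id = vapply(groups, `[[`, "", "group_id"),
    numerator = vapply(groups, function(g)
      sum(items %in% g$fragile_members), 0L),
    denominator = vapply(groups, function(g)
      sum(items %in% g$members), 0L),
    stringsAsFactors = FALSE)
}

#' Normalized fragile codon usage (NFCU)
#'
#' For each synonymous, GC-matched codon group (see [nfcu_groups()]) the
#' fragile fraction (occurrences of fragile members / occurrences of any
#' member) is computed; NFCU is the unweighted mean over all groups with a
#' non-zero denominator. If no group member occurs the value is UNDEFINED.
#' Because comparisons happen within synonymous families of fixed GC content,
#' NFCU is insensitive to amino-acid composition and background GC.
#'
#' @param seq A [codon_sequence()] (or codon vector / nucleotide string).
#' @param groups Groups from [nfcu_groups()]; canonical by default.
#' @return A `"metric_value"`.
#' @export
#' @examples
#' metric_value(nfcu(c("TCA", "TCT", "CGA", "GGT")))  # mean(1/2, 1, 0) = 0.5
nfcu <- function(seq, groups = nfcu_groups()) {
  codons <- .as_codons(seq)
  skip <- grepl("N", codons, fixed = TRUE) | codons %in% stop_codons()
  counted <- codons[!skip]
  per_group <- .group_counts(counted, groups)
  .metric_value("NFCU", per_group, sum(per_group$denominator), sum(skip),
                attr(seq, "label") %||% NA_character_)
}

.as_residues <- function(peptide) {
  if (length(peptide) == 1L && nchar(peptide) != 1L) {
    peptide <- strsplit(peptide, "")[[1]]
  }
  toupper(peptide)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fragile amino-acid usage (FAU)
#'
#' The fraction of a peptide's residues that are fragile amino acids
#' (C, Q, E, K, W, Y — those encoded exclusively by fragile codons). All
#' standard residues count, including the initial methionine; `X` and other
#' non-standard letters are skipped and tallied.
#'
#' @param peptide Amino-acid string (or character vector of residues).
#' @param label Optional identifier.
#' @return A `"metric_value"`.
#' @export
#' @examples
#' metric_value(fau("CQEKWY"))  # 1
fau <- function(peptide, label = NA_character_) {
  res <- .as_residues(peptide)
  keep <- res %in% AA20
  counted <- res[keep]
  num <- sum(counted %in% fragile_amino_acids())
  per_group <- data.frame(group_id = "all_residues", numerator = num,
                          denominator = length(counted),
                          stringsAsFactors = FALSE)
  .metric_value("FAU", per_group, length(counted), sum(!keep), label)
}

#' Normalized fragile amino-acid usage (NFAU)
#'
#' The unweighted mean, over the two GC-matched amino-acid groups (see
#' [nfau_groups()]), of the fraction of group residues that are fragile.
#' Serine, though facultative at the codon level, belongs to group 2 and is
#' counted as non-fragile. UNDEFINED when neither group is represented.
#'
#' @param peptide Amino-acid string (or character vector of residues).
#' @param groups Groups from [nfau_groups()].
#' @param label Optional identifier.
#' @return A `"metric_value"`.
#' @export
#' @examples
#' metric_value(nfau("YKNF"))  # 0.5
nfau <- function(peptide, groups = nfau_groups(), label = NA_character_) {
  res <- .as_residues(peptide)
  res <- res[res %in% AA20]
  per_group <- .group_counts(res, groups)
  .metric_value("NFAU", per_group, sum(per_group$denominator),
                length(.as_residues(peptide)) - length(res), label)
}

# ---- fast numeric paths used by the pipeline over thousands of records ----

.nfcu_value <- function(codons, groups = nfcu_groups()) {
  num <- den <- numeric(length(groups))
  for (i in seq_along(groups)) {
    den[i] <- sum(codons %in% groups[[i]]$members)
    num[i] <- sum(codons %in% groups[[i]]$fragile_members)
  }
  if (!any(den > 0)) return(NA_real_)
  mean(num[den > 0] / den[den > 0])
}

.fcu_value <- function(codons) {
  counted <- codons[!grepl("N", codons, fixed = TRUE) &
                      !(codons %in% stop_codons())]
  if (!length(counted)) return(NA_real_)
  sum(counted %in% fragile_codons()) / length(counted)
}

.fau_value <- function(res) {
  res <- res[res %in% AA20]
  if (!length(res)) return(NA_real_)
  sum(res %in% fragile_amino_acids()) / length(res)
}

.nfau_value <- function(res, groups = nfau_groups()) {
  num <- den <- numeric(length(groups))
  for (i in seq_along(groups)) {
    den[i] <- sum(res %in% groups[[i]]$members)
    num[i] <- sum(res %in% groups[[i]]$fragile_members)
  }
  if (!any(den > 0)) return(NA_real_)
  mean(num[den > 0] / den[den > 0])
}

#' Write metric values as TSV
#'
#' One row per record: label, metric, value (empty for UNDEFINED), n_used,
#' n_skipped, and per-group numerator/denominator bookkeeping collapsed as
#' `group:num/den` pairs.
#'
#' @param metrics A list of `"metric_value"` objects.
#' @param path Output file path.
#' @return Invisibly, the data.frame written.
#' @export
write_metrics_tsv <- function(metrics, path) {
  rows <- lapply(metrics, function(m) {
    data.frame(
      label = m$label,
      metric = m$metric,
      value = if (m$defined) format(m$value, digits = 15) else "",
      n_used = m$n_used,
      n_skipped = m$n_skipped,
      groups = paste(sprintf("%s:%d/%d", m$per_group$group_id,
                             m$per_group$numerator, m$per_group$denominator),
                     collapse = ";"),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
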