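# End-to-end drivers mirroring the published analyses: intergenic
# (single- vs multi-exon), intragenic (last vs upstream exons), boundary
# windows, covariate-binned comparisons, and the constraint-binned
# NFCU-NFAU correlation. All drivers report exclusion bookkeeping so cohort
# accounting stays auditable.

# fatal flags exclude a gene from all codon-level analyses
.FATAL_FLAGS <- c("internal_stop", "length_not_multiple_of_3",
                  "cds_outside_exon")

#' Per-gene metric table
#'
#' Computes FCU, NFCU, FAU and NFAU for the representative transcript of
#' every gene, along with structural fields used downstream. Genes with
#' fatal annotation flags (internal stop codons, CDS length not a multiple
#' of three) are marked unusable and excluded by the drivers; genes lacking
#' a terminal stop are retained for gene-level (intergenic) analyses but
#' flagged.
#'
#' @param gms A `gene_model_set` from [load_annotation()].
#' @param group_mode NFCU group mode (`"canonical"` or `"derived"`).
#' @return data.frame, one row per gene: identifiers, `exon_count`,
#'   `cds_len` (codons), `fcu`, `nfcu`, `fau`, `nfau`, `utr3_len`,
#'   `reliable_last_exon`, `cds_in_last_exon`, `flags`, `usable`.
#' @export
gene_metrics_table <- function(gms, group_mode = "canonical") {
  groups <- nfcu_groups(group_mode)
  agroups <- nfau_groups()
  rows <- lapply(gms$models, function(tm) {
    pep <- strsplit(tm$peptide, "")[[1]]
    data.frame(
      gene_id = tm$gene_id,
      transcript_id = tm$transcript_id,
      exon_count = tm$n_exons,
      cds_len = length(tm$cds_codons),
      fcu = .fcu_value(tm$cds_codons),
      nfcu = .nfcu_value(tm$cds_codons, groups),
      fau = .fau_value(pep),
      nfau = .nfau_value(pep, agroups),
      utr3_len = tm$utr3_len,
      reliable_last_exon = if (tm$n_exons > 1L) is_reliable_last_exon(tm)
        else NA,
      cds_in_last_exon = cds_in_last_exon(tm),
      flags = paste(tm$flags, collapse = ","),
      usable = !any(tm$flags %in% .FATAL_FLAGS),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Assign intergenic comparison classes
#'
#' Genes are `"multi_exon"` (exon count > 1, the reference class) or
#' `"single_exon"`; when a histone gene-id list is supplied, single-exon
#' genes are subdivided into `"single_exon_histone"` and
#' `"single_exon_nonhistone"` for the PABP-pathway contrast.
#'
#' @param metrics Output of [gene_metrics_table()].
#' @param histone_ids Optional character vector (or path to a one-id-per-line
#'   file) of histone-like gene ids.
#' @return The metrics data.frame with added `class` and `subclass` columns.
#' @export
assign_gene_classes <- function(metrics, histone_ids = NULL) {
  if (is.character(histone_ids) && length(histone_ids) == 1L &&
      file.exists(histone_ids)) {
    histone_ids <- readLines(histone_ids)
  }
  metrics$class <- ifelse(metrics$exon_count > 1L, "multi_exon",
                          "single_exon")
  metrics$subclass <- metrics$class
  if (!is.null(histone_ids)) {
    single <- metrics$class == "single_exon"
    metrics$subclass[single] <- ifelse(
      metrics$gene_id[single] %in% histone_ids,
      "single_exon_histone", "single_exon_nonhistone")
  }
  metrics
}

.one_intergenic_table <- function(values, metrics) {
  ref <- values[metrics$class == "multi_exon"]
  ref <- ref[!is.na(ref)]
  groups_to_report <- list(multi_exon = metrics$class == "multi_exon",
                           single_exon = metrics$class == "single_exon")
  if (any(metrics$subclass == "single_exon_histone")) {
    groups_to_report$single_exon_nonhistone <-
      metrics$subclass == "single_exon_nonhistone"
    groups_to_report$single_exon_histone <-
      metrics$subclass == "single_exon_histone"
  }
  rows <- lapply(names(groups_to_report), function(g) {
    v_all <- values[groups_to_report[[g]]]
    v <- v_all[!is.na(v_all)]
    if (!length(v)) return(NULL)
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = qs[2], q1 = qs[1],
               q3 = qs[3],
               p_value = if (g == "multi_exon") NA_real_ else
                 rank_sum_test(v, ref),
               ratio = qs[2] / stats::median(ref),
               n_undefined_dropped = sum(is.na(v_all)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intergenic comparison of fragile codon and amino-acid usage
#'
#' Compares single-exon genes (and, when a histone list is given, the
#' histone/non-histone subclasses) against the multi-exon reference for each
#' of FCU, NFCU, FAU and NFAU: n, median, quartiles, two-sided rank-sum p
#' versus multi-exon genes, and the ratio of medians.
#'
#' @param gms A `gene_model_set`, or a precomputed [gene_metrics_table()].
#' @param histone_ids Optional histone gene-id vector or file path.
#' @param group_mode NFCU group mode.
#' @param out_dir Optional directory for TSV/JSON reports.
#' @return A list with one comparison data.frame per metric plus
#'   `exclusions` (named counts).
#' @export
run_intergenic <- function(gms, histone_ids = NULL,
                           group_mode = "canonical", out_dir = NULL) {
  metrics <- if (is.data.frame(gms)) gms else
    gene_metrics_table(gms, group_mode)
  n_input <- nrow(metrics)
  metrics <- assign_gene_classes(metrics, histone_ids)
  usable <- metrics[metrics$usable, , drop = FALSE]
  if (!any(usable$class == "multi_exon")) {
    stop("reference class (multi-exon genes) is absent", call. = FALSE)
  }
  tabs <- list(FCU = .one_intergenic_table(usable$fcu, usable),
               NFCU = .one_intergenic_table(usable$nfcu, usable),
               FAU = .one_intergenic_table(usable$fau, usable),
               NFAU = .one_intergenic_table(usable$nfau, usable))
  res <- c(tabs, list(exclusions = c(input = n_input,
                                     unusable = n_input - nrow(usable),
                                     analyzed = nrow(usable))))
  if (!is.null(out_dir)) .write_report(res, out_dir, "intergenic", tabs)
  res
}

# eligible transcripts for exon-based analyses, with per-reason counts
.exon_eligible <- function(gms) {
  reasons <- character(0)
  keep <- list()
  for (tm in gms$models) {
    if (any(tm$flags %in% .FATAL_FLAGS)) {
      reasons <- c(reasons, "fatal_flags")
    } else if (tm$n_exons < 2L) {
      reasons <- c(reasons, "single_exon")
    } else if (!is_reliable_last_exon(tm)) {
      reasons <- c(reasons, "unreliable_last_exon")
    } else if (!any(tm$cds_exon_index < tm$n_exons)) {
      reasons <- c(reasons, "no_upstream_coding_exon")
    } else {
      keep[[tm$transcript_id]] <- tm
      reasons <- c(reasons, "eligible")
    }
  }
  list(models = keep, reasons = table(reasons))
}

#' Intragenic comparison: last exons versus upstream exons
#'
#' For multi-exon genes with a reliably annotated last exon and at least one
#' upstream coding exon: (a) pooled exon-level comparison of NFCU between
#' the set of last exons and the set of upstream exons (one value per exon,
#' using only codons completely encoded by the exon); (b) per-gene paired
#' comparison of last-exon NFCU against the NFCU of the pooled upstream
#' codons of the same gene — an exact two-sided sign (binomial) test on the
#' genes where the two values differ plus a signed-rank test on all defined
#' pairs; (c) gene-level comparison of multi-exon genes whose entire CDS
#' lies in the last exon against those with two or more coding exons.
#'
#' @param gms A `gene_model_set`.
#' @param group_mode NFCU group mode.
#' @param out_dir Optional report directory.
#' @return A list: `pooled` (comparison data.frame, reference
#'   `upstream_exons`), `paired` (list with `n_pairs`, `n_lower`,
#'   `n_higher`, `sign_p`, `signed_rank_p`), `cds_last` (comparison
#'   data.frame or NULL), `eligibility` (reason counts).
#' @export
run_intragenic <- function(gms, group_mode = "canonical", out_dir = NULL) {
  groups <- nfcu_groups(group_mode)
  el <- .exon_eligible(gms)
  if (!length(el$models)) {
    warning("no eligible genes for the intragenic analysis", call. = FALSE)
    return(list(pooled = NULL, paired = NULL, cds_last = NULL,
                eligibility = el$reasons))
  }
  last_vals <- numeric(0)
  up_vals <- numeric(0)
  n_undef_last <- n_undef_up <- 0L
  paired_last <- paired_up <- numeric(0)
  for (tm in el$models) {
    ex <- tm$exon_of_codon
    lastv <- .nfcu_value(tm$cds_codons[!is.na(ex) & ex == tm$n_exons],
                         groups)
    upv_pooled <- .nfcu_value(tm$cds_codons[!is.na(ex) & ex < tm$n_exons],
                              groups)
    if (is.na(lastv)) n_undef_last <- n_undef_last + 1L else
      last_vals <- c(last_vals, lastv)
    # upstream exons contribute one value each to the pooled comparison
    for (e in seq_len(tm$n_exons - 1L)) {
      v <- .nfcu_value(tm$cds_codons[!is.na(ex) & ex == e], groups)
      if (is.na(v)) n_undef_up <- n_undef_up + 1L else
        up_vals <- c(up_vals, v)
    }
    if (!is.na(lastv) && !is.na(upv_pooled)) {
      paired_last <- c(paired_last, lastv)
      paired_up <- c(paired_up, upv_pooled)
    }
  }
  pooled <- summarize_groups(
    c(up_vals, last_vals),
    c(rep("upstream_exons", length(up_vals)),
      rep("last_exons", length(last_vals))),
    reference = "upstream_exons")
  pooled$n_undefined_dropped <- c(n_undef_up, n_undef_last)

  d <- paired_last - paired_up
  paired <- list(n_pairs = length(d),
                 n_differing = sum(d != 0),
                 n_lower = sum(d < 0),
                 n_higher = sum(d > 0),
                 sign_p = sign_test(d),
                 signed_rank_p = signed_rank_test(d),
                 median_last = stats::median(paired_last),
                 median_upstream = stats::median(paired_up),
                 # per-gene pairing uses the whole upstream sequence, whose
                 # NFCU is free of the small-count lattice that exon-level
                 # medians snap to, so this ratio is the preferred estimate
                 # of region-level depletion
                 ratio = stats::median(paired_last) /
                   stats::median(paired_up),
                 rank_sum_p = rank_sum_test(paired_last, paired_up))

  # (c) CDS entirely in the last exon vs >= 2 coding exons (gene level)
  metrics <- gene_metrics_table(gms, group_mode)
  metrics <- metrics[metrics$usable & metrics$exon_count > 1L, , drop = FALSE]
  cil <- metrics$cds_in_last_exon
  cds_last <- NULL
  if (any(cil, na.rm = TRUE) && any(!cil, na.rm = TRUE)) {
    cds_last <- summarize_groups(
      metrics$nfcu,
      ifelse(cil, "cds_in_last_exon", "multi_coding_exon"),
      reference = "multi_coding_exon")
  }
  res <- list(pooled = pooled, paired = paired, cds_last = cds_last,
              eligibility = el$reasons)
  if (!is.null(out_dir)) {
    .write_report(res, out_dir, "intragenic",
                  list(pooled = pooled, cds_last = cds_last))
  }
  res
}

#' Boundary-window comparison around the last exon-exon junction
#'
#' Extracts the 5' (NMD-competent) and 3' (NMD-compromised) windows from
#' every window-eligible gene (see [extract_boundary_windows()]), compares
#' their NFCU distributions (reference: 5' windows), and optionally reruns
#' the comparison after partitioning window codons into those overlapping
#' exonic splicing enhancers and those external to them.
#'
#' @param gms A `gene_model_set`.
#' @param window_size,buffer_nt,min_last_exon_codons Window geometry, see
#'   [extract_boundary_windows()].
#' @param hexamers Optional ESE hexamer set for the partitioned rerun.
#' @param group_mode NFCU group mode.
#' @param out_dir Optional report directory.
#' @return A list: `comparison` (data.frame, reference `five_prime`),
#'   `n_eligible`, `reasons` (ineligibility counts), and when hexamers are
#'   given `ese_overlapping` / `ese_external` comparison data.frames.
#' @export
run_windows <- function(gms, window_size = 50L, buffer_nt = 50L,
                        min_last_exon_codons = 100L, hexamers = NULL,
                        group_mode = "canonical", out_dir = NULL) {
  groups <- nfcu_groups(group_mode)
  five <- three <- numeric(0)
  five_ov <- three_ov <- five_ex <- three_ex <- numeric(0)
  reasons <- character(0)
  n_eligible <- 0L
  for (tm in gms$models) {
    if (any(tm$flags %in% .FATAL_FLAGS)) {
      reasons <- c(reasons, "fatal_flags")
      next
    }
    w <- extract_boundary_windows(tm, window_size, buffer_nt,
                                  min_last_exon_codons)
    if (!w$eligible) {
      reasons <- c(reasons, w$reason)
      next
    }
    n_eligible <- n_eligible + 1L
    five <- c(five, .nfcu_value(unclass(w$five_prime_window), groups))
    three <- c(three, .nfcu_value(unclass(w$three_prime_window), groups))
    if (!is.null(hexamers)) {
      cds_nt <- paste(tm$cds_codons, collapse = "")
      for (side in c("five", "three")) {
        win <- if (side == "five") w$five_prime_window else
          w$three_prime_window
        start_idx <- if (side == "five") w$five_start_codon else
          w$three_start_codon
        part <- partition_codons_by_ese(
          win, hexamers, context = cds_nt,
          offset_nt = 3L * (start_idx - 1L))
        ov <- .nfcu_value(unclass(part$overlapping), groups)
        exv <- .nfcu_value(unclass(part$external), groups)
        if (side == "five") {
          five_ov <- c(five_ov, ov)
          five_ex <- c(five_ex, exv)
        } else {
          three_ov <- c(three_ov, ov)
          three_ex <- c(three_ex, exv)
        }
      }
    }
  }
  cmp <- function(f, t) {
    f_def <- f[!is.na(f)]
    t_def <- t[!is.na(t)]
    if (!length(f_def) || !length(t_def)) return(NULL)
    out <- summarize_groups(
      c(f_def, t_def),
      c(rep("five_prime", length(f_def)), rep("three_prime", length(t_def))),
      reference = "five_prime")
    out$n_undefined_dropped <-
      c(five_prime = sum(is.na(f)),
        three_prime = sum(is.na(t)))[out$group]
    out
  }
  res <- list(
    comparison = if (n_eligible > 0L) cmp(five, three) else NULL,
    n_eligible = n_eligible,
    reasons = table(reasons))
  if (n_eligible == 0L) {
    warning("no window-eligible genes", call. = FALSE)
  }
  if (!is.null(hexamers) && n_eligible > 0L) {
    res$ese_overlapping <- cmp(five_ov, three_ov)
    res$ese_external <- cmp(five_ex, three_ex)
  }
  if (!is.null(out_dir)) {
    .write_report(res, out_dir, "windows",
                  Filter(is.data.frame, res))
  }
  res
}

#' Binned intergenic comparison
#'
#' Re-runs the single- versus multi-exon NFCU comparison within quartile
#' bins of a pooled covariate (CDS length, ESE density or Fop), removing
#' that covariate as a confounder: within each bin the classes are compared
#' with a rank-sum test and a ratio of medians.
#'
#' @param gms A `gene_model_set`, or a [gene_metrics_table()] (for
#'   `cds_length` binning only).
#' @param bin_variable `"cds_length"`, `"ese_density"` or `"fop"`.
#' @param hexamers ESE hexamer set (required for `ese_density`).
#' @param optimal_codons Optimal codon set (required for `fop`).
#' @param fop_mode `"raw"` or `"gc_controlled"`.
#' @param k Number of bins (default 4).
#' @param group_mode NFCU group mode.
#' @param out_dir Optional report directory.
#' @return data.frame with one row per (bin, class): `bin`, `group`, `n`,
#'   `median`, `q1`, `q3`, `p_value` (vs multi-exon within the bin),
#'   `ratio`.
#' @export
run_binned <- function(gms, bin_variable = c("cds_length", "ese_density",
                                             "fop"),
                       hexamers = NULL, optimal_codons = NULL,
                       fop_mode = "raw", k = 4L,
                       group_mode = "canonical", out_dir = NULL) {
  bin_variable <- match.arg(bin_variable)
  metrics <- if (is.data.frame(gms)) gms else
    gene_metrics_table(gms, group_mode)
  metrics <- assign_gene_classes(metrics)
  metrics <- metrics[metrics$usable, , drop = FALSE]
  var <- switch(bin_variable,
    cds_length = metrics$cds_len,
    ese_density = {
      if (is.null(hexamers)) stop("hexamers required", call. = FALSE)
      if (is.data.frame(gms)) stop("need gene models for ESE density",
                                   call. = FALSE)
      vapply(gms$models[metrics$gene_id], function(tm)
        ese_density(paste(tm$cds_codons, collapse = ""), hexamers), 0)
    },
    fop = {
      if (is.null(optimal_codons)) stop("optimal_codons required",
                                        call. = FALSE)
      if (is.data.frame(gms)) stop("need gene models for Fop",
                                   call. = FALSE)
      vapply(gms$models[metrics$gene_id], function(tm)
        fop(tm$cds_codons, optimal_codons, fop_mode), 0)
    })
  ok <- is.finite(var)
  metrics <- metrics[ok, , drop = FALSE]
  var <- var[ok]
  bins <- quartile_bin(var, k)
  rows <- list()
  for (b in levels(bins)) {
    sub <- metrics[bins == b, , drop = FALSE]
    if (!any(sub$class == "multi_exon") || !any(sub$class == "single_exon")) {
      next
    }
    tab <- .one_intergenic_table(sub$nfcu, sub)
    tab <- cbind(bin = b, tab, stringsAsFactors = FALSE)
    rows[[b]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) .write_report(out, out_dir, "binned", list(binned = out))
  out
}

#' NFCU-NFAU correlation binned by selective constraint
#'
#' Computes the overall Spearman correlation between per-gene NFCU and NFAU
#' and the correlation (with a 95 percent Fisher-z confidence interval)
#' within each Ka/Ks quartile, mirroring the constraint-dependence analysis:
#' under strong constraint only codon choice is free to respond, so the two
#' robustness channels decouple.
#'
#' @param metrics A [gene_metrics_table()] (or `gene_model_set`).
#' @param kaks data.frame with `gene_id` and `ratio` (e.g. from
#'   [read_kaks_table()] or built from [ng86()]).
#' @param k Number of constraint bins (default 4).
#' @param min_bin Minimum genes per bin; smaller bins are skipped with a
#'   warning (default 4).
#' @param out_dir Optional report directory.
#' @return A list: `overall` (a `"correlation_by_bin"`), `by_bin` (list of
#'   them, `Q1` lowest Ka/Ks to `Qk` highest), `mean_kaks` (named per-bin
#'   means), `n_genes`.
#' @export
run_constraint_correlation <- function(metrics, kaks, k = 4L, min_bin = 4L,
                                       out_dir = NULL) {
  if (!is.data.frame(metrics)) metrics <- gene_metrics_table(metrics)
  df <- merge(metrics[metrics$usable, c("gene_id", "nfcu", "nfau")],
              kaks[, c("gene_id", "ratio")], by = "gene_id")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < min_bin) stop("too few genes with Ka/Ks", call. = FALSE)
  overall <- spearman_ci(df$nfcu, df$nfau, bin_label = "overall")
  bins <- quartile_bin(df$ratio, k)
  by_bin <- list()
  mean_kaks <- numeric(0)
  for (b in levels(bins)) {
    sub <- df[bins == b, , drop = FALSE]
    if (nrow(sub) < min_bin) {
      warning("bin ", b, " has fewer than ", min_bin, " genes; skipped",
              call. = FALSE)
      next
    }
    by_bin[[b]] <- spearman_ci(sub$nfcu, sub$nfau, bin_label = b)
    mean_kaks[b] <- mean(sub$ratio)
  }
  res <- list(overall = overall, by_bin = by_bin, mean_kaks = mean_kaks,
              n_genes = nrow(df))
  if (!is.null(out_dir)) {
    tab <- do.call(rbind, lapply(c(list(overall), by_bin), function(s)
      data.frame(bin = s$bin_label, n = s$n, rho = s$rho, ci_low = s$ci_low,
                 ci_high = s$ci_high, p_value = s$p_value,
                 stringsAsFactors = FALSE)))
    .write_report(res, out_dir, "correlation", list(correlation = tab))
  }
  res
}

# write TSV tables plus one machine-readable JSON summary per analysis;
# p-values are serialized in full precision, never truncated to "<1e-15"
.write_report <- function(res, out_dir, name, tables) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    utils::write.table(tables[[nm]],
                       file.path(out_dir, sprintf("%s_%s.tsv", name, nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  strip <- function(x) {
    if (inherits(x, "table")) return(as.list(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(res), file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(NULL)
}
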