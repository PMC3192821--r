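# Nei-Gojobori (1986) pairwise Ka/Ks with equal pathway weighting and
# Jukes-Cantor correction. Used where a maximum-likelihood or
# transition/transversion-aware estimator (yn00) would otherwise be run:
# downstream analyses consume only quartile ranks of Ka/Ks, which are robust
# to estimator choice at moderate divergence.

# synonymous/nonsynonymous site counts of one codon; a change producing a
# stop codon counts as nonsynonymous, so syn + nonsyn = 3 per codon
.ng86_sites <- function(codon) {
  key <- paste0("sites_", codon)
  if (!is.null(.cf_env[[key]])) return(.cf_env[[key]])
  code <- standard_genetic_code()
  aa <- code[[codon]]
  nts <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(NUCS, nts[pos])) {
      mut <- nts
      mut[pos] <- alt
      mut <- paste(mut, collapse = "")
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  res <- c(syn = s, nonsyn = 3 - s)
  .cf_env[[key]] <- res
  res
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; pathways through stop codons are excluded unless all are blocked
.ng86_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("diff_", c1, "_", c2)
  if (!is.null(.cf_env[[key]])) return(.cf_env[[key]])
  code <- standard_genetic_code()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  perms <- switch(as.character(length(pos)),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  path_counts <- function(order, allow_stop) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      cur_c <- paste(cur, collapse = "")
      nxt_c <- paste(nxt, collapse = "")
      if (!allow_stop && code[[nxt_c]] == "*" && nxt_c != c2) return(NULL)
      if (code[[cur_c]] != "*" && code[[cur_c]] == code[[nxt_c]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  counts <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stop = FALSE))
  if (!length(counts)) {
    counts <- lapply(perms, path_counts, allow_stop = TRUE)
  }
  m <- do.call(rbind, counts)
  res <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  .cf_env[[key]] <- res
  res
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for one codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the two
#' sequences; a change to a stop codon counts as nonsynonymous so that
#' syn + nonsyn sites equal three per codon), counts differences with equal
#' weighting over substitution pathways (pathways through stop codons are
#' excluded unless every pathway is blocked), and applies the Jukes-Cantor
#' multiple-hit correction d = -3/4 log(1 - 4p/3) to the proportions. The
#' estimate is symmetric in its arguments.
#'
#' @param seq_a,seq_b Equal-length gapless codon vectors (or nucleotide
#'   strings with length a multiple of 3) containing no stop codons or
#'   ambiguity codes.
#' @param pair_id Optional label.
#' @return Object of class `"rate_pair"`: list with `ka`, `ks`, `ratio`
#'   (`NA` when `ks` is 0 or a proportion is saturated), site and difference
#'   counts, and `flags` (`"saturated_syn"`, `"saturated_nonsyn"`,
#'   `"ks_zero"`).
#' @export
#' @examples
#' a <- c("ATG", "GCT", "AAA")
#' ng86(a, a)$ka  # 0
ng86 <- function(seq_a, seq_b, pair_id = NA_character_) {
  a <- .as_codons(seq_a)
  b <- .as_codons(seq_b)
  if (length(a) != length(b)) {
    stop("sequences differ in codon count", call. = FALSE)
  }
  if (length(a) < 1L) stop("empty alignment", call. = FALSE)
  if (any(c(a, b) %in% stop_codons())) {
    stop("stop codons in alignment", call. = FALSE)
  }
  if (any(grepl("N", c(a, b), fixed = TRUE))) {
    stop("ambiguity codes in alignment", call. = FALSE)
  }
  sites_a <- vapply(a, .ng86_sites, c(syn = 0, nonsyn = 0))
  sites_b <- vapply(b, .ng86_sites, c(syn = 0, nonsyn = 0))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- mapply(.ng86_diff, a, b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- .jc_correct(ps)
  ka <- .jc_correct(pn)
  flags <- character(0)
  if (!is.na(ps) && ps >= 0.75) flags <- c(flags, "saturated_syn")
  if (!is.na(pn) && pn >= 0.75) flags <- c(flags, "saturated_nonsyn")
  ratio <- NA_real_
  if (!is.na(ks) && !is.na(ka)) {
    if (ks == 0) flags <- c(flags, "ks_zero") else ratio <- ka / ks
  }
  structure(list(pair_id = pair_id, ka = ka, ks = ks, ratio = ratio,
                 sites_syn = S, sites_nonsyn = N, sd = Sd, nd = Nd,
                 ps = ps, pn = pn, flags = flags),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("Ka = %s, Ks = %s, Ka/Ks = %s%s\n",
              format(x$ka), format(x$ks),
              if (is.na(x$ratio)) "UNDEFINED" else format(x$ratio),
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Pairwise synonymous divergence (Ks) matrix
#'
#' Computes NG86 Ks for every pair of pre-aligned, equal-length sequences.
#' Used for redundancy filtering of paralogous gene sets: sequences whose
#' pairwise Ks all fall below a threshold collapse into one cluster
#' (single linkage).
#'
#' @param seqs Named list of equal-length codon vectors or nucleotide
#'   strings.
#' @return Symmetric numeric matrix of Ks values with zero diagonal; cells
#'   are `NA` where estimation failed (e.g. saturation).
#' @export
pairwise_ks_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- tryCatch(ng86(seqs[[i]], seqs[[j]])$ks, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- ks
    }
  }
  m
}

#' Single-linkage clusters under a Ks threshold
#'
#' @param ks_matrix Output of [pairwise_ks_matrix()].
#' @param threshold Ks below which two sequences are linked.
#' @return Integer vector of cluster memberships (named as the matrix).
#' @export
ks_clusters <- function(ks_matrix, threshold) {
  n <- nrow(ks_matrix)
  cl <- seq_len(n)
  link <- !is.na(ks_matrix) & ks_matrix < threshold
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && link[i, j]) {
        old <- cl[j]
        cl[cl == old] <- cl[i]
      }
    }
  }
  stats::setNames(match(cl, unique(cl)), rownames(ks_matrix))
}

#' Read a precomputed Ka/Ks table
#'
#' Accepts an external TSV (columns `gene_id` or `pair_id`, `ka`, `ks`,
#' optionally `ratio`) and bypasses the built-in estimator entirely.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `ka`, `ks`, `ratio`.
#' @export
read_kaks_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  id_col <- intersect(c("gene_id", "pair_id"), names(df))[1]
  if (is.na(id_col)) stop("no gene_id/pair_id column", call. = FALSE)
  out <- data.frame(gene_id = df[[id_col]], ka = df$ka, ks = df$ks,
                    stringsAsFactors = FALSE)
  out$ratio <- if ("ratio" %in% names(df)) df$ratio else
    ifelse(df$ks > 0, df$ka / df$ks, NA_real_)
  out
}

#' Write Ka/Ks estimates as TSV
#'
#' @param pairs List of `"rate_pair"` objects.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_kaks_tsv <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair_id = p$pair_id, ka = p$ka, ks = p$ks, ratio = p$ratio,
               flags = paste(p$flags, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
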