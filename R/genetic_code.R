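#' @importFrom Biostrings GENETIC_CODE DNAString DNAStringSet
#' @importFrom stats median quantile setNames
NULL

# package-level cache for derived tables (filled lazily, derivation is cheap)
.cf_env <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' The standard (nuclear) genetic code
#'
#' Returns the standard genetic code as a named character vector mapping the
#' 64 DNA codons to one-letter amino-acid codes, with `"*"` marking the three
#' stop codons (TAA, TAG, TGA). The DNA alphabet (T, not U) is used
#' throughout the package and codons are always uppercase.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]  # "M"
standard_genetic_code <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code
}

#' Sense and stop codons of the standard code
#'
#' @return `sense_codons()`: character vector of the 61 codons encoding an
#'   amino acid; `stop_codons()`: the 3 stop codons. Both sorted
#'   lexicographically.
#' @export
sense_codons <- function() {
  code <- standard_genetic_code()
  sort(names(code)[code != "*"])
}

#' @rdname sense_codons
#' @export
stop_codons <- function() {
  code <- standard_genetic_code()
  sort(names(code)[code == "*"])
}

.check_sense_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon) ||
      nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in% NUCS)) {
    stop("not a valid codon over {A,C,G,T}: ", deparse(codon), call. = FALSE)
  }
  if (standard_genetic_code()[[codon]] == "*") {
    stop("stop codon supplied where a sense codon is required: ", codon,
         call. = FALSE)
  }
  invisible(codon)
}

#' Stop codons reachable by a single point mutation
#'
#' Enumerates all nine single-nucleotide substitutions of a sense codon and
#' returns those that produce a stop codon. A sense codon with at least one
#' stop neighbor is "fragile": a single transcriptional error can convert it
#' into a premature termination codon.
#'
#' @param codon A single sense codon (uppercase DNA, e.g. `"TGG"`).
#' @return Character vector (possibly empty) of stop codons, sorted
#'   lexicographically.
#' @export
#' @examples
#' stop_neighbors("TGG")  # c("TAG", "TGA")
#' stop_neighbors("GGG")  # character(0)
stop_neighbors <- function(codon) {
  .check_sense_codon(codon)
  stops <- stop_codons()
  nts <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(NUCS, nts[pos])) {
      mut <- nts
      mut[pos] <- alt
      mut <- paste(mut, collapse = "")
      if (mut %in% stops) out <- c(out, mut)
    }
  }
  sort(unique(out))
}

#' Classify a sense codon as fragile or robust
#'
#' @param codon A single sense codon.
#' @return A list of class `"codon_classification"` with elements `codon`,
#'   `status` (`"fragile"` or `"robust"`) and `stop_neighbors`.
#' @export
#' @examples
#' classify_codon("TCA")$status  # "fragile"
#' classify_codon("TCT")$status  # "robust"
classify_codon <- function(codon) {
  nb <- stop_neighbors(codon)
  structure(
    list(codon = codon,
         status = if (length(nb) > 0L) "fragile" else "robust",
         stop_neighbors = nb),
    class = "codon_classification")
}

#' Fragile/robust classification table for all 61 sense codons
#'
#' Derived by enumeration of single-nucleotide neighbors (never from a
#' hard-coded list). Under the standard code there are 18 fragile and 43
#' robust sense codons.
#'
#' @return data.frame with columns `codon`, `amino_acid`, `status`,
#'   `stop_neighbors` (comma-separated), one row per sense codon.
#' @export
codon_classification_table <- function() {
  if (!is.null(.cf_env$codon_table)) return(.cf_env$codon_table)
  code <- standard_genetic_code()
  codons <- sense_codons()
  nb <- lapply(codons, stop_neighbors)
  tab <- data.frame(
    codon = codons,
    amino_acid = unname(code[codons]),
    status = ifelse(lengths(nb) > 0L, "fragile", "robust"),
    stop_neighbors = vapply(nb, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  .cf_env$codon_table <- tab
  tab
}

#' The fragile sense codons
#'
#' @return Character vector of the 18 fragile codons, sorted.
#' @export
fragile_codons <- function() {
  tab <- codon_classification_table()
  tab$codon[tab$status == "fragile"]
}

#' Classify an amino acid as fragile, robust or facultative
#'
#' An amino acid is fragile if every codon encoding it is fragile, robust if
#' every codon is robust, and facultative if its codon family mixes both.
#' Under the standard code there are 6 fragile (C, Q, E, K, W, Y), 10 robust
#' and 4 facultative (S, L, R, G) amino acids.
#'
#' @param aa A single one-letter amino-acid code.
#' @return A list of class `"aa_classification"` with elements `amino_acid`
#'   and `status` (`"fragile"`, `"robust"` or `"facultative"`).
#' @export
#' @examples
#' classify_amino_acid("W")$status  # "fragile"
#' classify_amino_acid("S")$status  # "facultative"
classify_amino_acid <- function(aa) {
  tab <- amino_acid_classification_table()
  i <- match(aa, tab$amino_acid)
  if (length(aa) != 1L || is.na(i)) {
    stop("not a standard amino acid one-letter code: ", deparse(aa),
         call. = FALSE)
  }
  structure(list(amino_acid = aa, status = tab$status[i]),
            class = "aa_classification")
}

#' @rdname classify_amino_acid
#' @return `amino_acid_classification_table()`: data.frame with columns
#'   `amino_acid`, `status`, `n_codons`, `n_fragile_codons`.
#' @export
amino_acid_classification_table <- function() {
  if (!is.null(.cf_env$aa_table)) return(.cf_env$aa_table)
  ct <- codon_classification_table()
  aas <- sort(unique(ct$amino_acid))
  n_cod <- vapply(aas, function(a) sum(ct$amino_acid == a), 0L)
  n_frag <- vapply(aas, function(a)
    sum(ct$amino_acid == a & ct$status == "fragile"), 0L)
  status <- ifelse(n_frag == n_cod, "fragile",
                   ifelse(n_frag == 0L, "robust", "facultative"))
  tab <- data.frame(amino_acid = aas, status = status, n_codons = n_cod,
                    n_fragile_codons = n_frag, stringsAsFactors = FALSE,
                    row.names = NULL)
  .cf_env$aa_table <- tab
  tab
}

#' @rdname classify_amino_acid
#' @export
fragile_amino_acids <- function() {
  tab <- amino_acid_classification_table()
  tab$amino_acid[tab$status == "fragile"]
}

.codon_gc <- function(codon) {
  vapply(strsplit(codon, ""), function(x) sum(x %in% c("G", "C")), 0L)
}

#' Synonymous GC-matched codon groups underlying NFCU
#'
#' NFCU (normalized fragile codon usage) is computed within groups of codons
#' that are synonymous, share the same G+C count, and mix fragile with robust
#' members, so that the fragile fraction in each group is insensitive to both
#' amino-acid composition and background base composition.
#'
#' Two modes are provided. `"canonical"` (the default) returns the five
#' groups as classically listed: \{TCA,TCT\} and \{TCG,TCC\} (Ser),
#' \{CGA,CGT\} (Arg), \{GGA,GGT\} (Gly) and the three-membered Leu group
#' \{TTG,CTT,CTA\}. Note that the original description labels the fifth group
#' "Lysine", but the listed codons TTG/CTT/CTA encode leucine (both lysine
#' codons are fragile, so no such lysine group can exist); the group is
#' treated as leucine here. The canonical lists also leave out the AGN
#' synonyms (AGT/AGC for Ser, AGG for Arg) without stated rationale.
#' `"derived"` rebuilds the partition from first principles: the codons of
#' each facultative amino acid are split by G+C count and every mixed
#' (fragile + robust) part is kept, which yields the same five groups with
#' AGT, AGC and AGG included. TTA (Leu, fragile, GC = 0) has no GC-matched
#' robust synonym and belongs to no group in either mode.
#'
#' @param mode `"canonical"` or `"derived"`.
#' @return A list of groups; each group is a list with `group_id`,
#'   `amino_acid`, `members`, `fragile_members` and `gc_count`.
#' @export
#' @examples
#' g <- nfcu_groups()
#' g[[1]]$members  # "TCA" "TCT"
nfcu_groups <- function(mode = c("canonical", "derived")) {
  mode <- match.arg(mode)
  key <- paste0("nfcu_", mode)
  if (!is.null(.cf_env[[key]])) return(.cf_env[[key]])
  ct <- codon_classification_table()
  mk <- function(aa, members) {
    members <- sort(members)
    st <- ct$status[match(members, ct$codon)]
    gc <- unique(.codon_gc(members))
    stopifnot(length(gc) == 1L)
    list(group_id = sprintf("%s-GC%d", aa, gc),
         amino_acid = aa,
         members = members,
         fragile_members = members[st == "fragile"],
         gc_count = gc)
  }
  if (mode == "canonical") {
    groups <- list(
      mk("S", c("TCA", "TCT")),
      mk("S", c("TCG", "TCC")),
      mk("R", c("CGA", "CGT")),
      mk("G", c("GGA", "GGT")),
      mk("L", c("TTG", "CTT", "CTA")))
  } else {
    at <- amino_acid_classification_table()
    fac <- at$amino_acid[at$status == "facultative"]
    groups <- list()
    for (aa in sort(fac)) {
      cods <- ct$codon[ct$amino_acid == aa]
      for (gc in sort(unique(.codon_gc(cods)))) {
        members <- cods[.codon_gc(cods) == gc]
        st <- ct$status[match(members, ct$codon)]
        if (any(st == "fragile") && any(st == "robust")) {
          groups <- c(groups, list(mk(aa, members)))
        }
      }
    }
  }
  # disambiguate the two Ser groups
  ids <- vapply(groups, `[[`, "", "group_id")
  stopifnot(!anyDuplicated(ids))
  .cf_env[[key]] <- groups
  groups
}

#' GC-matched amino-acid groups underlying NFAU
#'
#' NFAU (normalized fragile amino-acid usage) averages the fragile fraction
#' within two groups of amino acids whose full synonymous codon families have
#' equal G+C fraction. Group 1 (1/6 of family nucleotides G or C): Tyr and
#' Lys (fragile), Asn and Phe (robust). Group 2 (1/2 G or C): Gln, Glu and
#' Cys (fragile), Ser (facultative, counted as non-fragile), His, Thr, Val
#' and Asp (robust). The memberships are re-derivable from the family GC
#' fractions of the two-codon families plus Ser.
#'
#' @return A list of two groups, each a list with `group_id`, `members`,
#'   `fragile_members` and `family_gc_fraction`.
#' @export
nfau_groups <- function() {
  if (!is.null(.cf_env$nfau)) return(.cf_env$nfau)
  groups <- list(
    list(group_id = "AA-GC1of6",
         members = c("Y", "K", "N", "F"),
         fragile_members = c("Y", "K"),
         family_gc_fraction = 1 / 6),
    list(group_id = "AA-GC1of2",
         members = c("Q", "E", "C", "S", "H", "T", "V", "D"),
         fragile_members = c("Q", "E", "C"),
         family_gc_fraction = 1 / 2))
  .cf_env$nfau <- groups
  groups
}

#' Family GC fraction of an amino acid's full codon family
#'
#' Fraction of G+C nucleotides across all codons encoding the amino acid;
#' used to derive the NFAU group memberships independently of the canonical
#' lists.
#'
#' @param aa One-letter amino-acid code(s).
#' @return Numeric vector of GC fractions.
#' @export
family_gc_fraction <- function(aa) {
  ct <- codon_classification_table()
  vapply(aa, function(a) {
    cods <- ct$codon[ct$amino_acid == a]
    sum(.codon_gc(cods)) / (3 * length(cods))
  }, 0)
}

#' Export the codon classification as TSV
#'
#' Writes one row per sense codon with columns codon, amino_acid, status and
#' stop_neighbors (comma-separated).
#'
#' @param path Output file path.
#' @return Invisibly, the table written.
#' @export
export_codon_table <- function(path) {
  tab <- codon_classification_table()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @export
print.codon_classification <- function(x, ...) {
  cat(sprintf("codon %s: %s", x$codon, x$status))
  if (length(x$stop_neighbors)) {
    cat(" (stop neighbors: ", paste(x$stop_neighbors, collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.aa_classification <- function(x, ...) {
  cat(sprintf("amino acid %s: %s\n", x$amino_acid, x$status))
  invisible(x)
}
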