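#' Haplotype sets
#'
#' A haplotype set is a tibble with one row per MHC haplotype: a `haplotype`
#' label column and an optional `sequence` column holding the concatenated
#' amino-acid sequence across the class IIa loci (aligned, equal lengths, gaps
#' as `-`). Divergence is always computed on the alignment supplied by the
#' user; no alignment is performed internally.
#'
#' @param names Character vector of unique haplotype labels.
#' @param sequences Optional character vector of aligned amino-acid sequences,
#'   one per label (named or positional).
#' @return A `haplotype_set` tibble.
#' @export
haplotype_set <- function(names, sequences = NULL) {
  names <- as.character(names)
  if (length(names) == 0 || any(is.na(names) | names == "")) {
    abort("Haplotype labels must be non-empty.")
  }
  if (anyDuplicated(names)) {
    abort(paste0("Duplicate haplotype label(s): ",
                 paste(unique(names[duplicated(names)]), collapse = ", ")))
  }
  tbl <- tibble::tibble(haplotype = names)
  if (!is.null(sequences)) {
    if (!is.null(base::names(sequences))) {
      missing <- setdiff(names, base::names(sequences))
      if (length(missing) > 0) {
        abort(paste0("No sequence for haplotype(s): ", paste(missing, collapse = ", ")))
      }
      sequences <- sequences[names]
    }
    if (length(sequences) != length(names)) {
      abort("Need exactly one sequence per haplotype label.")
    }
    sequences <- toupper(as.character(sequences))
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1) {
      abort(sprintf("Aligned sequences must have equal length (found %s).",
                    paste(sort(unique(lens)), collapse = ", ")))
    }
    tbl$sequence <- unname(sequences)
  }
  class(tbl) <- unique(c("haplotype_set", class(tbl)))
  tbl
}

#' Read a haplotype set from an aligned amino-acid FASTA
#'
#' One record per haplotype; the record id is the haplotype label. All
#' sequences must have the same (aligned) length.
#'
#' @param path Path to a FASTA file.
#' @return A `haplotype_set` tibble with sequences.
#' @export
read_haplotype_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("No FASTA records found in ", path))
  labels <- sub("\\s.*$", "", names(seqs))
  haplotype_set(labels, setNames(as.character(seqs), labels))
}

#' Write a haplotype set as FASTA
#'
#' @param hs A `haplotype_set` carrying sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(hs, path) {
  if (!"sequence" %in% names(hs)) abort("Haplotype set carries no sequences.")
  writeLines(paste0(">", hs$haplotype, "\n", hs$sequence), path)
  invisible(path)
}

#' Read a diplotype table
#'
#' Tab-separated with header columns `ID`, `HAP1`, `HAP2` (case-insensitive).
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `id`, `hap1`, `hap2`.
#' @export
read_diplotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(c("id", "hap1", "hap2"), names(df))
  if (length(missing) > 0) {
    abort(paste0("Diplotype table is missing column(s): ",
                 paste(toupper(missing), collapse = ", ")))
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate diplotype row(s) for: ", paste(dup, collapse = ", ")))
  }
  dplyr::select(df, "id", "hap1", "hap2")
}

#' Write a diplotype table
#'
#' @param diplotypes Tibble with columns `id`, `hap1`, `hap2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diplotypes <- function(diplotypes, path) {
  out <- tibble::tibble(ID = diplotypes$id, HAP1 = diplotypes$hap1,
                        HAP2 = diplotypes$hap2)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Proportion of differing amino-acid positions (p-distance)
#'
#' Computes the proportion of compared alignment positions at which two
#' equal-length amino-acid sequences differ. Positions where either sequence
#' carries a gap (`-`) are excluded (pairwise deletion). Comparison is
#' case-insensitive; `X` is an ordinary (mismatching) symbol.
#'
#' @param seq_a,seq_b Amino-acid strings of equal length.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' p_distance("AAAA", "AAAT") # 0.25
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    abort(sprintf("Sequence lengths differ (%d vs %d).", length(a), length(b)))
  }
  keep <- a != "-" & b != "-"
  if (!any(keep)) abort("No comparable (gap-free) positions between the sequences.")
  mean(a[keep] != b[keep])
}

#' Divergence between the two haplotypes of a diplotype
#'
#' The p-distance between the amino-acid sequences of an individual's two
#' haplotypes; 0 for homozygotes. Vectorised over `hap1`/`hap2`.
#'
#' @param hap1,hap2 Haplotype labels (recycled to common length).
#' @param hs A `haplotype_set` carrying sequences for all labels used.
#' @return Numeric vector of divergences.
#' @export
diplotype_divergence <- function(hap1, hap2, hs) {
  if (!"sequence" %in% names(hs)) abort("Haplotype set carries no sequences.")
  n <- max(length(hap1), length(hap2))
  hap1 <- rep_len(as.character(hap1), n)
  hap2 <- rep_len(as.character(hap2), n)
  missing <- setdiff(unique(c(hap1, hap2)), hs$haplotype)
  if (length(missing) > 0) {
    abort(paste0("No sequence for haplotype label(s): ", paste(missing, collapse = ", ")))
  }
  seqs <- setNames(hs$sequence, hs$haplotype)
  # Distances depend only on the unordered label pair; compute each pair once.
  key <- paste(pmin(hap1, hap2), pmax(hap1, hap2), sep = "\r")
  uk <- unique(key)
  vals <- vapply(uk, function(k) {
    pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (pair[1] == pair[2]) 0 else p_distance(seqs[[pair[1]]], seqs[[pair[2]]])
  }, numeric(1))
  unname(vals[match(key, uk)])
}

#' MHC heterozygosity of a diplotype
#'
#' @param hap1,hap2 Haplotype labels (recycled to common length).
#' @return Integer vector: 1 if the two labels differ, else 0.
#' @export
heterozygosity <- function(hap1, hap2) {
  as.integer(as.character(hap1) != as.character(hap2))
}

#' Per-individual MHC diversity table
#'
#' Convenience wrapper combining [heterozygosity()] and
#' [diplotype_divergence()] over a diplotype table.
#'
#' @param diplotypes Tibble with columns `id`, `hap1`, `hap2`.
#' @param hs A `haplotype_set`; sequences are required only if `divergence`
#'   is to be computed (`hs` carrying sequences).
#' @return Tibble `id`, `hap1`, `hap2`, `heterozygosity` and, when sequences
#'   are available, `divergence`.
#' @export
mhc_diversity <- function(diplotypes, hs) {
  out <- tibble::tibble(
    id = diplotypes$id, hap1 = diplotypes$hap1, hap2 = diplotypes$hap2,
    heterozygosity = heterozygosity(diplotypes$hap1, diplotypes$hap2)
  )
  if ("sequence" %in% names(hs)) {
    out$divergence <- diplotype_divergence(out$hap1, out$hap2, hs)
  }
  out
}

#' Haplotype dosage coding
#'
#' Codes each individual's diplotype as the number of copies (0, 1 or 2) of
#' every haplotype in the set; each row sums to exactly 2.
#'
#' @param diplotypes Tibble with columns `id`, `hap1`, `hap2`.
#' @param hs A `haplotype_set` (or character vector of labels).
#' @return Tibble with column `id` followed by one integer dosage column per
#'   haplotype label.
#' @export
dosage_matrix <- function(diplotypes, hs) {
  labels <- if (is.character(hs)) hs else hs$haplotype
  unknown <- setdiff(unique(c(diplotypes$hap1, diplotypes$hap2)), labels)
  if (length(unknown) > 0) {
    abort(paste0("Unknown haplotype label(s): ", paste(unknown, collapse = ", ")))
  }
  m <- matrix(0L, nrow = nrow(diplotypes), ncol = length(labels),
              dimnames = list(NULL, labels))
  i1 <- cbind(seq_len(nrow(diplotypes)), match(diplotypes$hap1, labels))
  i2 <- cbind(seq_len(nrow(diplotypes)), match(diplotypes$hap2, labels))
  m[i1] <- m[i1] + 1L
  m[i2] <- m[i2] + 1L
  dplyr::bind_cols(tibble::tibble(id = diplotypes$id), tibble::as_tibble(m))
}
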