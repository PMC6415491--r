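.lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

.lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Detect a target site duplication from an occupied/empty allele pair
#'
#' A TE insertion creates a short direct repeat (target site duplication,
#' TSD) of host sequence on both sides of the element. Given the occupied
#' allele (with the insertion) and the empty allele (without), the TSD is
#' recovered from the overlap of the longest common prefix and suffix of
#' the two sequences: with prefix length p and suffix length s (s capped
#' so p + s does not exceed the occupied length), the TSD length is
#' t = p + s - length(empty). If t <= 0 the insertion created no
#' duplication and `NULL` is returned. A TSD longer than `max_tsd` is
#' flagged `ambiguous` (it usually signals coincidental identity between
#' element ends and flanking sequence) but still reported.
#'
#' The reassembly identity holds for every detected record:
#' prefix + tsd + inserted + tsd + suffix equals the occupied allele,
#' where prefix = empty\[0, p - t) and suffix = empty\[p, end).
#'
#' @param occupied,empty Nucleotide strings over A, C, G, T, N; the
#'   occupied allele must be the longer one.
#' @param max_tsd Longest TSD considered unambiguous.
#' @param insertion_id Optional identifier carried into the record.
#' @return A list of class `tsd_record` with `insertion_id`,
#'   `tsd_sequence`, `tsd_length`, `insertion_point` (0-based offset of
#'   the end of the first TSD copy in the empty allele),
#'   `inserted_sequence` (the inserted element without the duplicated
#'   copy) and `ambiguous`; or `NULL` when no duplication is present.
#' @export
detect_tsd <- function(occupied, empty, max_tsd = 20, insertion_id = NA_character_) {
  occupied <- toupper(occupied)
  empty <- toupper(empty)
  if (nchar(occupied) <= nchar(empty)) stop("no insertion present")
  p <- .lcp_len(occupied, empty)
  s <- .lcs_len(occupied, empty)
  if (p + s > nchar(occupied)) s <- nchar(occupied) - p
  t <- p + s - nchar(empty)
  if (t <= 0) return(NULL)
  tsd <- substr(empty, p - t + 1L, p)
  inserted <- substr(occupied, p + 1L, nchar(occupied) - s)
  structure(list(
    insertion_id = insertion_id,
    tsd_sequence = tsd,
    tsd_length = t,
    insertion_point = p,
    inserted_sequence = inserted,
    ambiguous = t > max_tsd
  ), class = "tsd_record")
}

#' Reassemble the occupied allele from a TSD record
#'
#' @param record A `tsd_record` from [detect_tsd()].
#' @param empty The empty allele the record was derived from.
#' @return The reconstructed occupied allele string.
#' @export
reassemble_occupied <- function(record, empty) {
  empty <- toupper(empty)
  p <- record$insertion_point
  t <- record$tsd_length
  paste0(substr(empty, 1L, p - t), record$tsd_sequence,
         record$inserted_sequence, record$tsd_sequence,
         substr(empty, p + 1L, nchar(empty)))
}

#' Detect TSDs for paired FASTA files of occupied and empty alleles
#'
#' Records are paired by sequence name; every name in `occupied_fasta`
#' must also appear in `empty_fasta`.
#'
#' @param occupied_fasta,empty_fasta Paths to FASTA files.
#' @param max_tsd Passed to [detect_tsd()].
#' @return A data frame with one row per pair: `insertion_id`,
#'   `tsd_sequence`, `tsd_length`, `insertion_point`, `ambiguous`
#'   (`tsd_length` 0 and `tsd_sequence` `NA` when no duplication found).
#' @export
detect_tsd_pairs <- function(occupied_fasta, empty_fasta, max_tsd = 20) {
  occ <- Biostrings::readDNAStringSet(occupied_fasta)
  emp <- Biostrings::readDNAStringSet(empty_fasta)
  if (!all(names(occ) %in% names(emp))) {
    stop("occupied records without an empty-allele partner: ",
         paste(setdiff(names(occ), names(emp)), collapse = ", "))
  }
  rows <- lapply(names(occ), function(id) {
    rec <- detect_tsd(as.character(occ[[id]]), as.character(emp[[id]]),
                      max_tsd = max_tsd, insertion_id = id)
    if (is.null(rec)) {
      data.frame(insertion_id = id, tsd_sequence = NA_character_,
                 tsd_length = 0L, insertion_point = NA_integer_,
                 ambiguous = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(insertion_id = id, tsd_sequence = rec$tsd_sequence,
                 tsd_length = rec$tsd_length,
                 insertion_point = rec$insertion_point,
                 ambiguous = rec$ambiguous, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Consensus matrix and information content of a sequence set
#'
#' Builds a per-column base-count/base-frequency matrix from equal-length
#' sequences and the per-column information content in bits,
#' IC_j = 2 + sum_b f_bj log2 f_bj (4-letter alphabet, no small-sample
#' correction; the matrix carries n so users can correct downstream).
#' Under the default `"modal-length-only"` policy, sequences whose length
#' differs from the modal length are dropped before counting — the usual
#' treatment when a few detected duplications are shorter than the rest.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param length_policy `"modal-length-only"` (drop off-modal lengths) or
#'   `"strict"` (error unless all lengths equal).
#' @return A list of class `consensus_matrix` with `counts` (4 x L),
#'   `frequencies`, `information_content` (bits per column), `consensus`
#'   (majority base per column), `n_sequences`, `n_dropped`,
#'   `column_count`.
#' @export
consensus_profile <- function(sequences,
                              length_policy = c("modal-length-only", "strict")) {
  length_policy <- match.arg(length_policy)
  sequences <- toupper(sequences)
  if (length(sequences) == 0) stop("no sequences supplied")
  len <- nchar(sequences)
  if (length_policy == "strict") {
    if (length(unique(len)) > 1) stop("sequences differ in length")
    keep <- rep(TRUE, length(sequences))
  } else {
    tab <- table(len)
    modal <- max(as.integer(names(tab)[tab == max(tab)]))  # ties -> longest
    keep <- len == modal
  }
  kept <- sequences[keep]
  if (length(kept) == 0) stop("no sequences left after length filtering")
  L <- nchar(kept[1])
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(kept),
                                     baseOnly = TRUE)
  counts <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  colsum <- colSums(counts)
  if (any(colsum == 0)) stop("column with no unambiguous base")
  freqs <- sweep(counts, 2, colsum, "/")
  ic <- apply(freqs, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(
    counts = counts,
    frequencies = freqs,
    information_content = unname(ic),
    consensus = rownames(freqs)[apply(freqs, 2, which.max)],
    n_sequences = length(kept),
    n_dropped = sum(!keep),
    column_count = L
  ), class = "consensus_matrix")
}

#' Scan a sequence for an IUPAC motif
#'
#' Finds every occurrence of a degenerate (IUPAC-coded) motif on the
#' given strand of a nucleotide sequence; used to check conservation of
#' transcription factor binding sites, core promoter motifs and matrix
#' attachment regions in element copies.
#'
#' @param sequence Nucleotide string.
#' @param iupac_pattern Motif over the IUPAC nucleotide alphabet
#'   (e.g. `"TATAWA"`).
#' @return A data frame with 0-based `position` and `match` columns, one
#'   row per hit (zero rows when the pattern is absent or longer than the
#'   sequence).
#' @export
scan_motif <- function(sequence, iupac_pattern) {
  pat <- toupper(iupac_pattern)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pat)) {
    stop("invalid IUPAC code in pattern: ", iupac_pattern)
  }
  empty <- data.frame(position = integer(), match = character(),
                      stringsAsFactors = FALSE)
  if (nchar(pat) > nchar(sequence)) return(empty)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pat), Biostrings::DNAString(toupper(sequence)),
    fixed = "subject"
  )
  if (length(hits) == 0) return(empty)
  data.frame(position = BiocGenerics::start(hits) - 1L,
             match = as.character(hits), stringsAsFactors = FALSE)
}

#' Group identical element copies as transposition-burst candidates
#'
#' Element copies with byte-identical sequences (after uppercasing) are
#' grouped; groups of two or more are candidate products of a
#' transposition burst. Also returns one representative per distinct
#' sequence, the set conventionally kept for downstream tree building.
#'
#' @param named_sequences Named character vector (or `DNAStringSet`) of
#'   element sequences.
#' @return A list with `groups` (list of character vectors of member ids,
#'   size >= 2, ordered by decreasing size then first member),
#'   `singletons` (ids with unique sequences) and `representatives`
#'   (first member of each group plus all singletons).
#' @export
group_identical <- function(named_sequences) {
  if (methods::is(named_sequences, "DNAStringSet")) {
    named_sequences <- setNames(as.character(named_sequences),
                                names(named_sequences))
  }
  if (is.null(names(named_sequences)) && length(named_sequences) > 0) {
    stop("sequences must be named")
  }
  seqs <- toupper(named_sequences)
  parts <- split(names(seqs), unname(seqs))
  sizes <- lengths(parts)
  groups <- parts[sizes >= 2]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, `[`, character(1), 1))]
  singletons <- unlist(parts[sizes == 1], use.names = FALSE)
  list(
    groups = unname(groups),
    singletons = sort(singletons),
    representatives = sort(c(vapply(groups, `[`, character(1), 1), singletons))
  )
}

#' Count substitutions between two aligned sequences
#'
#' Columns where either sequence has a gap (`-`) are excluded; the count
#' is the number of remaining columns where the two residues differ.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequence strings.
#' @return Integer substitution count.
#' @export
pairwise_substitutions <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  sum(a != "-" & b != "-" & a != b)
}
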