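ORIENTATIONS <- c("sense", "antisense", "unknown")
ELEMENT_CLASSES <- c("solo-LTR", "full-length", "unknown")
CALL_SOURCES <- c("reference-annotation", "de-novo-caller")
GENOTYPE_STATES <- c("absent", "heterozygous", "homozygous", "failed")
CLIMATE_CLASSES <- c("cold", "temperate", "arid")

## strand symbol used on disk <-> orientation vocabulary used in memory
.strand_to_orientation <- function(x) {
  out <- rep("unknown", length(x))
  out[x == "+"] <- "sense"
  out[x == "-"] <- "antisense"
  bad <- !(x %in% c("+", "-", ".", NA))
  if (any(bad)) {
    stop("unknown orientation symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

.orientation_to_strand <- function(x) {
  c(sense = "+", antisense = "-", unknown = ".")[x]
}

#' Construct a table of TE insertion calls
#'
#' An insertion call is one observation of a transposable element insertion
#' in one strain: a genomic interval (the caller's coordinate range, or a
#' point interval for an exactly placed insertion), the TE family, the
#' insertion orientation and the structural class of the element. All
#' coordinates are 0-based half-open.
#'
#' @param chrom Chromosome arm name.
#' @param start,end Integer 0-based half-open interval; `0 <= start < end`.
#' @param call_id Identifier of the individual observation; autogenerated
#'   when missing.
#' @param strain_id Strain in which the call was made.
#' @param family TE family name (e.g. `"roo"`).
#' @param orientation One of `"sense"` (5'-3'), `"antisense"` (3'-5'),
#'   `"unknown"`.
#' @param element_class One of `"solo-LTR"`, `"full-length"`, `"unknown"`.
#' @param source One of `"reference-annotation"`, `"de-novo-caller"`.
#' @return A `data.frame` of class `insertion_calls`, one row per call.
#' @export
insertion_calls <- function(chrom, start, end,
                            call_id = NULL,
                            strain_id = "unknown",
                            family = "unknown",
                            orientation = "unknown",
                            element_class = "unknown",
                            source = "de-novo-caller") {
  n <- length(chrom)
  if (is.null(call_id)) call_id <- sprintf("call%06d", seq_len(n))
  df <- data.frame(
    call_id = as.character(call_id),
    strain_id = rep_len(as.character(strain_id), n),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    family = rep_len(as.character(family), n),
    orientation = rep_len(as.character(orientation), n),
    element_class = rep_len(as.character(element_class), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("insertion_calls", "data.frame")
  validate_insertion_calls(df)
}

#' @rdname insertion_calls
#' @param x An `insertion_calls` data frame to validate.
#' @export
validate_insertion_calls <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(x)
  if (any(x$start < 0) || any(x$start >= x$end)) {
    bad <- which(x$start < 0 | x$start >= x$end)[1]
    stop("invalid interval at row ", bad, ": need 0 <= start < end")
  }
  if (!all(x$orientation %in% ORIENTATIONS)) {
    stop("orientation must be one of: ", paste(ORIENTATIONS, collapse = ", "))
  }
  if (!all(x$element_class %in% ELEMENT_CLASSES)) {
    stop("element_class must be one of: ", paste(ELEMENT_CLASSES, collapse = ", "))
  }
  x
}

#' Read TE insertion calls from a BED-like TSV file
#'
#' Supports two coordinate dialects: `"bed0"` (0-based half-open, BED
#' native) and `"tidal-range-1-based"` (1-based inclusive coordinate
#' ranges as produced by TE callers that report a range of candidate
#' insertion positions). All coordinates are normalised to 0-based
#' half-open on input: a 1-based inclusive range (s, e) becomes
#' (s - 1, e).
#'
#' Columns (tab-separated, no header): chrom, start, end, then optionally
#' call_id, strain_id, family, strand (`+`/`-`/`.`), element_class,
#' source. Missing optional columns get defaults.
#'
#' @param path Path to the TSV/BED file.
#' @param dialect Coordinate convention of the file.
#' @return An `insertion_calls` data frame.
#' @export
read_insertion_calls <- function(path, dialect = c("bed0", "tidal-range-1-based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(insertion_calls(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3)) {
    stop("malformed row at line ", which(nfield < 3)[1], ": fewer than 3 columns")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed row at line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates")
  }
  if (dialect == "tidal-range-1-based") start <- start - 1L
  bad <- start < 0L | end <= start
  if (any(bad)) {
    stop("malformed row at line ", which(bad)[1],
         ": empty or negative interval after normalization")
  }
  n <- length(lines)
  insertion_calls(
    chrom = get(1, NA),
    start = start,
    end = end,
    call_id = if (any(nfield >= 4)) get(4, "") else NULL,
    strain_id = get(5, "unknown"),
    family = get(6, "unknown"),
    orientation = .strand_to_orientation(get(7, ".")),
    element_class = get(8, "unknown"),
    source = get(9, "de-novo-caller")
  )
}

#' Write TE insertion calls to a BED-like TSV file
#'
#' Inverse of [read_insertion_calls()]; the chosen dialect controls the
#' coordinate convention written.
#'
#' @param calls An `insertion_calls` data frame.
#' @param path Output path.
#' @param dialect Coordinate convention to write.
#' @return `path`, invisibly.
#' @export
write_insertion_calls <- function(calls, path,
                                  dialect = c("bed0", "tidal-range-1-based")) {
  dialect <- match.arg(dialect)
  start <- calls$start
  if (dialect == "tidal-range-1-based") start <- start + 1L
  out <- data.frame(
    calls$chrom, start, calls$end, calls$call_id, calls$strain_id,
    calls$family, unname(.orientation_to_strand(calls$orientation)),
    calls$element_class, calls$source
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` and `five_prime_UTR` features. GFF3 coordinates are
#' 1-based inclusive and are converted to 0-based half-open. The
#' transcription start site (TSS) is derived from the strand: body start
#' on `+`, body end - 1 on `-`.
#'
#' @param path Path to a GFF3 file.
#' @return A list of class `gene_models` with elements `genes` (data frame
#'   with `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`) and `utr5`
#'   (data frame with `gene_id`, `chrom`, `start`, `end`), all 0-based
#'   half-open.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  u <- gr[type == "five_prime_UTR"]
  strand <- as.character(BiocGenerics::strand(g))
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand symbol for gene(s): ",
         paste(g$ID[!(strand %in% c("+", "-"))], collapse = ", "))
  }
  start0 <- BiocGenerics::start(g) - 1L
  end0 <- BiocGenerics::end(g)
  genes <- data.frame(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = strand,
    start = start0,
    end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE
  )
  utr5 <- data.frame(
    gene_id = character(), chrom = character(),
    start = integer(), end = integer(), stringsAsFactors = FALSE
  )
  if (length(u) > 0) {
    parent <- vapply(u$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    utr5 <- data.frame(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(u)),
      start = BiocGenerics::start(u) - 1L,
      end = BiocGenerics::end(u),
      stringsAsFactors = FALSE
    )
    i <- match(utr5$gene_id, genes$gene_id)
    if (anyNA(i)) {
      stop("five_prime_UTR with unknown Parent gene: ",
           paste(unique(utr5$gene_id[is.na(i)]), collapse = ", "))
    }
    outside <- utr5$start < genes$start[i] | utr5$end > genes$end[i]
    if (any(outside)) {
      stop("five_prime_UTR outside gene body for gene(s): ",
           paste(unique(utr5$gene_id[outside]), collapse = ", "))
    }
  }
  structure(list(genes = genes, utr5 = utr5), class = "gene_models")
}

#' Read a strain-by-insertion genotype table
#'
#' The table records, for every (strain, insertion) pair screened, the
#' diploid genotype call: `absent`, `heterozygous`, `homozygous` or
#' `failed`. Failed calls are retained in the table but excluded from all
#' frequency denominators downstream.
#'
#' @param path Path to a TSV with header columns `strain_id`,
#'   `population_id`, `insertion_id`, `state`.
#' @return A `data.frame` of class `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("strain_id", "population_id", "insertion_id", "state")
  if (!all(required %in% names(df))) {
    stop("genotype table must have columns: ", paste(required, collapse = ", "))
  }
  genotype_table(df)
}

#' @rdname read_genotype_table
#' @param df A data frame with the genotype-table columns.
#' @export
genotype_table <- function(df) {
  bad <- !(df$state %in% GENOTYPE_STATES)
  if (any(bad)) {
    stop("unknown genotype state(s): ", paste(unique(df$state[bad]), collapse = ", "))
  }
  key <- paste(df$strain_id, df$insertion_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop("duplicate (strain, insertion) pair: ", d$strain_id[1], " / ",
         d$insertion_id[1])
  }
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read population metadata
#'
#' @param path Path to a TSV with header columns `population_id`,
#'   `latitude` (degrees), `climate_class` (`cold`, `temperate`, `arid`)
#'   and `n_strains`.
#' @return A `data.frame` of class `population_meta`.
#' @export
read_population_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("population_id", "latitude", "climate_class", "n_strains")
  if (!all(required %in% names(df))) {
    stop("population metadata must have columns: ", paste(required, collapse = ", "))
  }
  if (!all(df$climate_class %in% CLIMATE_CLASSES)) {
    stop("climate_class must be one of: ", paste(CLIMATE_CLASSES, collapse = ", "))
  }
  if (any(df$n_strains < 1)) stop("n_strains must be >= 1")
  class(df) <- c("population_meta", "data.frame")
  df
}
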