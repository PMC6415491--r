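#' Midpoint of an insertion call interval
#'
#' TE callers that work from discordant read pairs report a coordinate
#' range rather than an exact insertion point; the canonical insertion
#' site is taken as the midpoint of that range. For a 0-based half-open
#' interval \[start, end) this is the floor of the median of the inclusive
#' span start..end-1, i.e. `floor((start + end - 1) / 2)`.
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @return Integer vector of midpoint positions (0-based).
#' @export
compute_midpoint <- function(start, end) {
  stopifnot(all(start < end))
  as.integer((as.numeric(start) + as.numeric(end) - 1) %/% 2)
}

#' Collapse insertion calls into canonical merged sites
#'
#' Calls whose midpoints fall within `tolerance_bp` of each other are
#' treated as observations of the same insertion site. Merging is
#' transitive (chain merging): per chromosome arm, midpoints are sorted
#' and consecutive midpoints with gap <= `tolerance_bp` join the same
#' site, so a run 10, 15, 20 at tolerance 5 is a single site. The site
#' position is the floor of the median of member midpoints.
#'
#' @param calls An `insertion_calls` data frame.
#' @param tolerance_bp Maximum midpoint gap (bp) merged into one site.
#' @return A `data.frame` of class `merged_sites` with columns `site_id`,
#'   `chrom`, `position`, `n_calls`, `n_strains`, and list columns
#'   `member_call_ids`, `strains`, `orientations`.
#' @export
collapse_sites <- function(calls, tolerance_bp = 5) {
  if (tolerance_bp < 0) stop("tolerance_bp must be >= 0")
  mid <- if (nrow(calls)) compute_midpoint(calls$start, calls$end) else integer()
  ord <- order(calls$chrom, mid)
  calls <- calls[ord, , drop = FALSE]
  mid <- mid[ord]
  if (nrow(calls) == 0) {
    out <- data.frame(site_id = character(), chrom = character(),
                      position = integer(), n_calls = integer(),
                      n_strains = integer(), stringsAsFactors = FALSE)
    out$member_call_ids <- list()
    out$strains <- list()
    out$orientations <- list()
    class(out) <- c("merged_sites", "data.frame")
    return(out)
  }
  new_chrom <- c(TRUE, calls$chrom[-1] != calls$chrom[-nrow(calls)])
  gap_break <- c(TRUE, diff(mid) > tolerance_bp)
  grp <- cumsum(new_chrom | gap_break)
  idx <- split(seq_len(nrow(calls)), grp)
  out <- data.frame(
    site_id = sprintf("site%05d", seq_along(idx)),
    chrom = vapply(idx, function(i) calls$chrom[i[1]], character(1)),
    position = vapply(idx, function(i) as.integer(floor(median(mid[i]))),
                      integer(1)),
    n_calls = lengths(idx),
    n_strains = vapply(idx, function(i) length(unique(calls$strain_id[i])),
                       integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$member_call_ids <- lapply(idx, function(i) calls$call_id[i])
  out$strains <- lapply(idx, function(i) unique(calls$strain_id[i]))
  out$orientations <- lapply(idx, function(i) table(calls$orientation[i]))
  class(out) <- c("merged_sites", "data.frame")
  out
}

#' Count merged sites in fixed genomic windows
#'
#' Windows are non-overlapping tiles of `width` bp anchored at coordinate
#' 0 on each chromosome arm. Windows containing no site are omitted.
#'
#' @param sites A `merged_sites` data frame.
#' @param width Window width in bp.
#' @return A data frame with columns `chrom`, `window_start`, `count`,
#'   ordered by (chrom, window_start).
#' @export
count_windows <- function(sites, width = 1000) {
  stopifnot(width > 0)
  if (nrow(sites) == 0) {
    return(data.frame(chrom = character(), window_start = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  ws <- as.integer((sites$position %/% width) * width)
  agg <- stats::aggregate(list(count = ws),
                          by = list(chrom = sites$chrom, window_start = ws),
                          FUN = length)
  agg <- agg[order(agg$chrom, agg$window_start), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Maximum sliding-window site count
#'
#' Sensitivity check for the fixed-tile scan: for each chromosome arm,
#' the largest number of merged sites covered by any sliding window of
#' `width` bp (every site position considered as a window start).
#'
#' @inheritParams count_windows
#' @return A data frame with columns `chrom`, `max_count`.
#' @export
sliding_max_count <- function(sites, width = 1000) {
  stopifnot(width > 0)
  res <- lapply(split(sites$position, sites$chrom), function(p) {
    p <- sort(p)
    max(vapply(p, function(s) sum(p >= s & p < s + width), integer(1)))
  })
  data.frame(chrom = names(res), max_count = unlist(res, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Call insertional cluster windows
#'
#' A cluster is a window holding at least `min_count` distinct merged
#' sites. Output is ordered by (chrom, window_start) so ties in count are
#' broken deterministically.
#'
#' @param windows Output of [count_windows()].
#' @param min_count Minimum number of sites for a window to be called.
#' @param promoters Optional `promoter_regions` data frame; when given,
#'   each cluster is annotated with the gene ids of promoters overlapping
#'   the window.
#' @param width Window width used to build `windows`.
#' @return A data frame with columns `chrom`, `window_start`,
#'   `window_end`, `count` and, when `promoters` is supplied, a list
#'   column `overlapping_promoters`.
#' @export
call_clusters <- function(windows, min_count = 7, promoters = NULL,
                          width = 1000) {
  stopifnot(min_count >= 1)
  hit <- windows[windows$count >= min_count, , drop = FALSE]
  hit <- hit[order(hit$chrom, hit$window_start), , drop = FALSE]
  rownames(hit) <- NULL
  hit$window_end <- hit$window_start + as.integer(width)
  hit <- hit[, c("chrom", "window_start", "window_end", "count")]
  if (!is.null(promoters) && nrow(hit) > 0) {
    wgr <- GenomicRanges::GRanges(
      hit$chrom, IRanges::IRanges(hit$window_start + 1L, hit$window_end))
    pgr <- GenomicRanges::GRanges(
      promoters$chrom, IRanges::IRanges(promoters$start + 1L, promoters$end))
    ov <- GenomicRanges::findOverlaps(wgr, pgr)
    hit$overlapping_promoters <- lapply(seq_len(nrow(hit)), function(i) {
      unique(promoters$gene_id[S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == i]])
    })
  } else if (!is.null(promoters)) {
    hit$overlapping_promoters <- list()
  }
  hit
}

#' Build strand-aware promoter regions
#'
#' The promoter region of a gene is defined as the `upstream_bp` window
#' immediately upstream of its TSS, unioned with all of its 5'UTR
#' intervals. On the `+` strand the upstream window is
#' \[tss - upstream_bp, tss); on the `-` strand it is
#' \[tss + 1, tss + 1 + upstream_bp). Windows are clipped at position 0
#' and, when `contig_lengths` is supplied, at the contig end. Overlapping
#' pieces are merged per gene.
#'
#' @param genes A `gene_models` object from [read_gene_models()] (or a
#'   list with the same `genes`/`utr5` structure).
#' @param upstream_bp Upstream window size in bp.
#' @param contig_lengths Optional named integer vector of contig lengths
#'   used to clip windows.
#' @return A `data.frame` of class `promoter_regions` with columns
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open; possibly
#'   several rows per gene).
#' @export
build_promoters <- function(genes, upstream_bp = 1000, contig_lengths = NULL) {
  stopifnot(upstream_bp >= 0)
  g <- genes$genes
  up_start <- ifelse(g$strand == "+", g$tss - upstream_bp, g$tss + 1L)
  up_end <- ifelse(g$strand == "+", g$tss, g$tss + 1L + upstream_bp)
  up_start <- pmax(up_start, 0L)
  if (!is.null(contig_lengths)) {
    lim <- unname(contig_lengths[g$chrom])
    up_end <- ifelse(is.na(lim), up_end, pmin(up_end, lim))
  }
  pieces <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = as.integer(up_start), end = as.integer(up_end),
    stringsAsFactors = FALSE
  )
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
  if (nrow(genes$utr5) > 0) {
    pieces <- rbind(pieces, genes$utr5[, c("gene_id", "chrom", "start", "end")])
  }
  merged <- lapply(split(pieces, pieces$gene_id), function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(gene_id = p$gene_id[1], chrom = p$chrom[1],
               start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_regions", "data.frame")
  out
}

#' Assign merged sites to the promoter regions containing them
#'
#' A site belongs to every promoter region whose intervals contain its
#' position. Also reports the overall proportion of sites falling in at
#' least one promoter/5'UTR region (the "5' insertion preference"
#' proportion).
#'
#' @param sites A `merged_sites` data frame.
#' @param promoters A `promoter_regions` data frame.
#' @return A list with `assignments` (named list: site_id -> character
#'   vector of gene ids, empty when the site is in no promoter),
#'   `n_in_promoter` and `proportion_in_promoter`.
#' @export
classify_sites <- function(sites, promoters) {
  assignments <- setNames(rep(list(character()), nrow(sites)), sites$site_id)
  if (nrow(sites) > 0 && nrow(promoters) > 0) {
    sgr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$position + 1L, sites$position + 1L))
    pgr <- GenomicRanges::GRanges(
      promoters$chrom, IRanges::IRanges(promoters$start + 1L, promoters$end))
    ov <- GenomicRanges::findOverlaps(sgr, pgr)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
      assignments[[i]] <- unique(promoters$gene_id[sh[qh == i]])
    }
  }
  n_in <- sum(lengths(assignments) > 0)
  list(
    assignments = assignments,
    n_in_promoter = n_in,
    proportion_in_promoter = if (nrow(sites)) n_in / nrow(sites) else NA_real_
  )
}

#' Promoter recurrence of insertions across strains
#'
#' For each promoter region, counts the strains carrying at least one
#' insertion call inside it and the number of distinct insertion sites
#' (after midpoint collapse at `tolerance_bp`), keeping promoters hit in
#' at least `min_strains` strains. Promoters with two or more distinct
#' sites are flagged as multi-insertion (cluster) candidates. Results are
#' ordered by decreasing strain support, ties broken by (chrom, start).
#'
#' @param calls An `insertion_calls` data frame (all strains pooled; the
#'   `strain_id` column identifies the strain of each call).
#' @param promoters A `promoter_regions` data frame.
#' @param min_strains Minimum number of supporting strains.
#' @param tolerance_bp Midpoint collapse tolerance within the promoter.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `n_strains`, `n_sites`, `multi_insertion` and a list column
#'   `site_orientations` (per distinct site, the orientation tally).
#' @export
promoter_recurrence <- function(calls, promoters, min_strains = 3,
                                tolerance_bp = 5) {
  mid <- if (nrow(calls)) compute_midpoint(calls$start, calls$end) else integer()
  genes <- unique(promoters$gene_id)
  rows <- lapply(genes, function(gid) {
    p <- promoters[promoters$gene_id == gid, , drop = FALSE]
    inside <- rep(FALSE, nrow(calls))
    for (j in seq_len(nrow(p))) {
      inside <- inside | (calls$chrom == p$chrom[j] & mid >= p$start[j] &
                            mid < p$end[j])
    }
    if (!any(inside)) return(NULL)
    sub <- calls[inside, , drop = FALSE]
    sites <- collapse_sites(sub, tolerance_bp = tolerance_bp)
    data.frame(
      gene_id = gid, chrom = p$chrom[1], start = min(p$start),
      n_strains = length(unique(sub$strain_id)),
      n_sites = nrow(sites),
      multi_insertion = nrow(sites) >= 2,
      site_orientations = I(list(sites$orientations)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), n_strains = integer(),
                      n_sites = integer(), multi_insertion = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[out$n_strains >= min_strains, , drop = FALSE]
  out <- out[order(-out$n_strains, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
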