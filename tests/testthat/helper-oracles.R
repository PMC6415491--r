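## Independent brute-force oracles. These deliberately avoid the package's
## own algorithms: collapse via all-pairs union-find, windows via per-site
## binning, TSD via exhaustive decomposition, Fisher via hypergeometric
## enumeration, subsample expectation via full subset enumeration.

## all-pairs union-find collapse of midpoints (per chromosome)
oracle_collapse <- function(chrom, mid, tolerance) {
  n <- length(mid)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && abs(mid[i] - mid[j]) <= tolerance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  data.frame(
    chrom = vapply(groups, function(g) chrom[g[1]], character(1)),
    position = vapply(groups, function(g) as.integer(floor(median(mid[g]))),
                      integer(1)),
    n_calls = lengths(groups),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## per-site bin assignment
oracle_bin <- function(chrom, pos, width) {
  ws <- as.integer((pos %/% width) * width)
  key <- paste(chrom, ws)
  counts <- table(key)
  parts <- strsplit(names(counts), " ")
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    window_start = as.integer(vapply(parts, `[`, character(1), 2)),
    count = as.integer(counts),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## exhaustive TSD decomposition: the largest t such that for some prefix
## cut a, occupied = empty[1..a+t] + anything + empty[(a+1)..end]
## with tsd = empty[(a+1)..(a+t)]
oracle_tsd <- function(occupied, empty) {
  ne <- nchar(empty)
  best <- NULL
  for (a in 0:ne) {
    for (t in 0:(ne - a)) {
      pre_tsd <- substr(empty, 1, a + t)
      tsd_suf <- substr(empty, a + 1, ne)
      if (startsWith(occupied, pre_tsd) && endsWith(occupied, tsd_suf) &&
          nchar(occupied) >= (a + t) + (ne - a)) {
        if (is.null(best) || t > best$t) {
          best <- list(t = t, tsd = substr(empty, a + 1, a + t),
                       insertion_point = a + t)
        }
      }
    }
  }
  if (is.null(best) || best$t == 0) NULL else best
}

## two-sided Fisher p by hypergeometric enumeration (fisher.test's rule:
## sum all tables with point probability <= observed, within relative
## tolerance)
oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

## expected distinct insertions by full enumeration of subsets
oracle_expected_distinct <- function(cm, n) {
  N <- length(cm$universe)
  subsets <- utils::combn(cm$universe, n, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    sum(vapply(cm$carriers, function(carr) any(carr %in% s), logical(1)))
  }, numeric(1)))
}

## direct per-column base counting
oracle_counts <- function(seqs) {
  L <- nchar(seqs[1])
  mat <- matrix(0L, nrow = 4, ncol = L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    ch <- strsplit(toupper(s), "")[[1]]
    for (j in seq_len(L)) {
      if (ch[j] %in% rownames(mat)) mat[ch[j], j] <- mat[ch[j], j] + 1L
    }
  }
  mat
}

## random valid insertion-call set on a couple of arms
random_calls <- function(n, max_pos = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(60, n, replace = TRUE)
  insertion_calls(
    chrom = sample(c("chr2L", "chr2R"), n, replace = TRUE),
    start = start, end = start + len,
    strain_id = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
    orientation = sample(c("sense", "antisense", "unknown"), n, replace = TRUE)
  )
}
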