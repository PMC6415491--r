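test_that("the midpoint is the floor-median of the inclusive span", {
  expect_equal(compute_midpoint(100L, 201L), 150L)
  expect_equal(compute_midpoint(100L, 101L), 100L)
  ## enumerate the inclusive span 3..9: floor of its median is 6
  expect_equal(compute_midpoint(3L, 10L), 6L)
  expect_equal(compute_midpoint(3L, 10L),
               as.integer(floor(median(3:9))))
})

make_point_calls <- function(mid, chrom = "chr2L", strain = "s1") {
  insertion_calls(chrom = rep(chrom, length(mid)), start = mid,
                  end = mid + 1L, strain_id = strain)
}

test_that("collapse merges within tolerance, transitively", {
  s <- collapse_sites(make_point_calls(c(100L, 103L, 250L)), tolerance_bp = 5)
  expect_equal(nrow(s), 2L)
  expect_setequal(s$position, c(101L, 250L))

  chain <- collapse_sites(make_point_calls(c(10L, 15L, 20L)), tolerance_bp = 5)
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$position, 15L)

  empty <- collapse_sites(make_point_calls(integer()))
  expect_equal(nrow(empty), 0L)
  expect_error(collapse_sites(make_point_calls(1L), tolerance_bp = -1),
               ">= 0")
})

test_that("collapse agrees with a union-find oracle on random call sets", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(1:40, 1)
    tol <- sample(0:8, 1)
    calls <- random_calls(n)
    got <- collapse_sites(calls, tolerance_bp = tol)
    exp <- oracle_collapse(calls$chrom,
                           compute_midpoint(calls$start, calls$end), tol)
    got_key <- sort(paste(got$chrom, got$position, got$n_calls))
    exp_key <- sort(paste(exp$chrom, exp$position, exp$n_calls))
    expect_identical(got_key, exp_key)
  }
})

test_that("collapse is idempotent and monotone in tolerance", {
  set.seed(7)
  for (rep in 1:20) {
    calls <- random_calls(30)
    s1 <- collapse_sites(calls, tolerance_bp = 5)
    s2 <- collapse_sites(make_point_calls(s1$position, chrom = s1$chrom),
                         tolerance_bp = 5)
    ## re-collapsing one call per site at the site position changes nothing
    expect_equal(s2$position, s1$position)
    expect_equal(s2$chrom, s1$chrom)
    counts <- vapply(c(0, 2, 5, 10, 50), function(tol)
      nrow(collapse_sites(calls, tolerance_bp = tol)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("window counts equal brute-force binning and sum to site count", {
  sites <- collapse_sites(make_point_calls(c(100L, 900L, 1500L)))
  w <- count_windows(sites, width = 1000)
  expect_equal(w$window_start, c(0L, 1000L))
  expect_equal(w$count, c(2L, 1L))

  expect_equal(nrow(count_windows(collapse_sites(make_point_calls(integer())))),
               0L)

  set.seed(5)
  calls <- random_calls(200, max_pos = 20000)
  sites <- collapse_sites(calls, tolerance_bp = 0)
  w <- count_windows(sites, width = 1000)
  o <- oracle_bin(sites$chrom, sites$position, 1000)
  o <- o[order(o$chrom, o$window_start), ]
  expect_equal(w$count, o$count)
  expect_equal(w$window_start, o$window_start)
  expect_equal(sum(w$count), nrow(sites))
})

test_that("cluster calling thresholds window counts deterministically", {
  w <- data.frame(chrom = c("chr2L", "chr2L"), window_start = c(0L, 1000L),
                  count = c(8L, 3L))
  cc <- call_clusters(w, min_count = 7)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$window_start, 0L)
  expect_equal(nrow(call_clusters(w, min_count = 9)), 0L)
})

test_that("promoters are strand-aware upstream windows plus the 5'UTR", {
  gm <- structure(list(
    genes = data.frame(
      gene_id = c("gp", "gm", "gc"), chrom = "chr2L",
      strand = c("+", "-", "+"),
      start = c(5000L, 4000L, 300L), end = c(7000L, 5200L, 2300L),
      tss = c(5000L, 5199L, 300L), stringsAsFactors = FALSE),
    utr5 = data.frame(gene_id = "gp", chrom = "chr2L",
                      start = 5000L, end = 5200L, stringsAsFactors = FALSE)
  ), class = "gene_models")
  pr <- build_promoters(gm, upstream_bp = 1000)
  gp <- pr[pr$gene_id == "gp", ]
  ## upstream [4000,5000) unions with the adjacent UTR [5000,5200)
  expect_equal(gp$start, 4000L)
  expect_equal(gp$end, 5200L)
  gmn <- pr[pr$gene_id == "gm", ]
  expect_equal(gmn$start, 5200L)
  expect_equal(gmn$end, 6200L)
  gc <- pr[pr$gene_id == "gc", ]
  expect_equal(gc$start, 0L)  # clipped at the contig origin
  expect_equal(gc$end, 300L)
})

test_that("site classification equals the all-pairs containment check", {
  prom <- structure(data.frame(
    gene_id = c("g1", "g2"), chrom = c("chr2L", "chr2L"),
    start = c(4000L, 4100L), end = c(5200L, 4600L), stringsAsFactors = FALSE
  ), class = c("promoter_regions", "data.frame"))
  sites <- collapse_sites(make_point_calls(c(4500L, 9999L)))
  cl <- classify_sites(sites, prom)
  expect_setequal(cl$assignments[[1]], c("g1", "g2"))
  expect_length(cl$assignments[[2]], 0)
  expect_equal(cl$proportion_in_promoter, 0.5)

  set.seed(21)
  pos <- sample.int(10000, 50)
  sites <- collapse_sites(make_point_calls(pos), tolerance_bp = 0)
  starts <- sample.int(9000, 20)
  prom <- structure(data.frame(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr2L",
    start = starts, end = starts + sample.int(1500, 20),
    stringsAsFactors = FALSE), class = c("promoter_regions", "data.frame"))
  cl <- classify_sites(sites, prom)
  for (i in seq_len(nrow(sites))) {
    hit <- prom$gene_id[sites$position[i] >= prom$start &
                          sites$position[i] < prom$end]
    expect_setequal(cl$assignments[[i]], hit)
  }
})

test_that("promoter recurrence counts strains and distinct sites", {
  prom <- structure(data.frame(
    gene_id = "g1", chrom = "chr2L", start = 4000L, end = 5200L,
    stringsAsFactors = FALSE), class = c("promoter_regions", "data.frame"))
  one <- insertion_calls("chr2L", 4500L, 4501L, strain_id = "s1")
  expect_equal(nrow(promoter_recurrence(one, prom, min_strains = 3)), 0L)
  r1 <- promoter_recurrence(one, prom, min_strains = 1)
  expect_equal(r1$n_strains, 1L)
  expect_equal(r1$n_sites, 1L)
  expect_false(r1$multi_insertion)

  ## same position, opposite orientations, two strains -> one site with a
  ## mixed orientation tally
  two <- insertion_calls(c("chr2L", "chr2L"), c(4500L, 4500L),
                         c(4501L, 4501L), strain_id = c("s1", "s2"),
                         orientation = c("sense", "antisense"))
  r2 <- promoter_recurrence(two, prom, min_strains = 2)
  expect_equal(r2$n_sites, 1L)
  tally <- r2$site_orientations[[1]][[1]]
  expect_equal(as.integer(tally[c("sense", "antisense")]), c(1L, 1L))
})
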