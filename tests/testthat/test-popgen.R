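make_genotypes <- function(states, pop = "p1", insertion = "i1") {
  genotype_table(data.frame(
    strain_id = sprintf("s%03d", seq_along(states)),
    population_id = pop, insertion_id = insertion, state = states,
    stringsAsFactors = FALSE
  ))
}

test_that("allele frequency uses diploid counting and drops failed strains", {
  g <- make_genotypes(c("homozygous", "homozygous", "heterozygous", "absent"))
  expect_equal(allele_frequency(g, "i1")$frequency, 5 / 8)
  expect_equal(allele_frequency(make_genotypes(rep("absent", 5)), "i1")$frequency, 0)

  g2 <- make_genotypes(c("homozygous", "failed", "failed", "heterozygous"))
  r <- allele_frequency(g2, "i1")
  expect_equal(r$n_strains_used, 2L)
  expect_equal(r$frequency, 3 / 4)
  expect_error(allele_frequency(make_genotypes(rep("failed", 3)), "i1"),
               "no genotyped strains")
})

test_that("allele frequency matches a direct recount on random tables", {
  set.seed(31)
  for (rep in 1:25) {
    states <- sample(c("absent", "heterozygous", "homozygous", "failed"),
                     40, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    g <- make_genotypes(states)
    if (all(states == "failed")) next
    r <- allele_frequency(g, "i1")
    n_alleles <- 0; n_strains <- 0
    for (s in states) {
      if (s == "failed") next
      n_strains <- n_strains + 1
      if (s == "homozygous") n_alleles <- n_alleles + 2
      if (s == "heterozygous") n_alleles <- n_alleles + 1
    }
    expect_equal(r$frequency, n_alleles / (2 * n_strains))
  }
})

test_that("global allele frequency is the strain-weighted population mix", {
  g <- genotype_table(data.frame(
    strain_id = sprintf("s%02d", 1:10),
    population_id = rep(c("p1", "p2"), c(6, 4)),
    insertion_id = "i1",
    state = c(rep("homozygous", 2), rep("absent", 4),
              rep("heterozygous", 3), "absent"),
    stringsAsFactors = FALSE
  ))
  f1 <- allele_frequency(g, "i1", "p1")
  f2 <- allele_frequency(g, "i1", "p2")
  glob <- allele_frequency(g, "i1")
  weighted <- (f1$frequency * f1$n_strains_used +
                 f2$frequency * f2$n_strains_used) /
    (f1$n_strains_used + f2$n_strains_used)
  expect_equal(glob$frequency, weighted)
})

test_that("occupancy, private and distinct agree with membership scans", {
  single <- list(p1 = c("a", "b"))
  expect_true(all(occupancy(single) == 1L))
  expect_equal(distinct_insertions(list()), 0L)
  expect_length(private_insertions(list(p1 = "a", p2 = "a")), 0)

  set.seed(41)
  for (rep in 1:20) {
    catalog <- lapply(1:6, function(i)
      sample(letters[1:10], sample(1:6, 1)))
    names(catalog) <- paste0("p", 1:6)
    occ <- occupancy(catalog)
    for (id in names(occ)) {
      expect_equal(occ[[id]],
                   sum(vapply(catalog, function(s) id %in% s, logical(1))))
    }
    expect_setequal(private_insertions(catalog), names(occ)[occ == 1])
    expect_equal(distinct_insertions(catalog),
                 length(unique(unlist(catalog))))
  }
})

test_that("expected co-occurrence follows the product rule, with 2ab option", {
  expect_equal(expected_cooccurrence(0.165, 0.063)$expected_fraction,
               0.165 * 0.063)
  expect_equal(round(expected_cooccurrence(0.165, 0.063)$expected_fraction, 4),
               0.0104)
  expect_equal(expected_cooccurrence(0, 0.5)$expected_fraction, 0)
  expect_equal(expected_cooccurrence(0.1, 0.2, mode = "hwe")$expected_fraction,
               0.04)
  ## symmetry, monotonicity, and the fixed 2x relationship
  expect_equal(expected_cooccurrence(0.3, 0.7)$expected_fraction,
               expected_cooccurrence(0.7, 0.3)$expected_fraction)
  expect_lt(expected_cooccurrence(0.2, 0.5)$expected_fraction,
            expected_cooccurrence(0.3, 0.5)$expected_fraction)
  expect_equal(expected_cooccurrence(0.2, 0.5, mode = "hwe")$expected_fraction,
               2 * expected_cooccurrence(0.2, 0.5)$expected_fraction)
  expect_error(expected_cooccurrence(1.2, 0.5), "\\[0, 1\\]")
})

test_that("latitude correlation matches the textbook formula", {
  lat <- c(40, 45, 50, 55, 60)
  expect_equal(latitude_correlation(lat, 2 * lat + 1)$r_squared, 1)
  expect_error(latitude_correlation(lat, rep(3, 5)), "zero variance")
  expect_error(latitude_correlation(lat[1:2], c(1, 2)), "at least 3")

  set.seed(51)
  x <- rnorm(14, 50, 8); y <- rnorm(14, 5, 2)
  res <- latitude_correlation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((14 - 2) / (1 - r^2))
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 12), tolerance = 1e-12)
})

test_that("climate association equals hypergeometric enumeration", {
  res <- climate_association(c(arid = 10, other = 0),
                             c(arid = 0, other = 10), "arid")
  expect_equal(res$p_value, oracle_fisher2x2(res$table), tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  balanced <- climate_association(c(arid = 5, other = 5),
                                  c(arid = 5, other = 5), "arid")
  expect_equal(balanced$p_value, 1)

  set.seed(61)
  for (rep in 1:30) {
    tabv <- sample(0:12, 4, replace = TRUE)
    if (sum(tabv) == 0) next
    carr <- c(a = tabv[1], b = tabv[3])
    nonc <- c(a = tabv[2], b = tabv[4])
    if (sum(carr) == 0 || sum(nonc) == 0) next
    res <- climate_association(carr, nonc, "a")
    expect_equal(res$p_value, oracle_fisher2x2(res$table), tolerance = 1e-9)
  }
})

test_that("climate scan adjusts p-values only when asked", {
  counts <- data.frame(
    insertion_id = rep(c("i1", "i2"), each = 2),
    climate_class = rep(c("arid", "other"), 2),
    carriers = c(8, 1, 2, 3),
    noncarriers = c(2, 9, 8, 7)
  )
  plain <- climate_association_scan(counts, "arid")
  expect_false("p_adjusted" %in% names(plain))
  adj <- climate_association_scan(counts, "arid", adjust = "BH")
  expect_equal(adj$p_adjusted, p.adjust(adj$p_value, "BH"))
})
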