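#' Allele frequency of an insertion from diploid genotype calls
#'
#' Standard diploid counting: a homozygous strain contributes two
#' insertion alleles, a heterozygous strain one, an absent strain none.
#' Strains whose genotyping failed are excluded from the denominator.
#'
#' @param genotypes A `genotype_table` data frame.
#' @param insertion_id Insertion to summarise.
#' @param population Optional population id; default summarises all
#'   populations together (`"global"`).
#' @return A list with `insertion_id`, `population_id`, `n_strains_used`,
#'   `n_hom`, `n_het` and `frequency` = (2 hom + het) / (2 n_used).
#' @export
allele_frequency <- function(genotypes, insertion_id, population = NULL) {
  rows <- genotypes[genotypes$insertion_id == insertion_id, , drop = FALSE]
  if (!is.null(population)) {
    rows <- rows[rows$population_id == population, , drop = FALSE]
  }
  rows <- rows[rows$state != "failed", , drop = FALSE]
  if (nrow(rows) == 0) stop("no genotyped strains in scope for ", insertion_id)
  n_hom <- sum(rows$state == "homozygous")
  n_het <- sum(rows$state == "heterozygous")
  list(
    insertion_id = insertion_id,
    population_id = if (is.null(population)) "global" else population,
    n_strains_used = nrow(rows),
    n_hom = n_hom, n_het = n_het,
    frequency = (2 * n_hom + n_het) / (2 * nrow(rows))
  )
}

#' Allele frequencies for all insertions, per population and global
#'
#' @param genotypes A `genotype_table` data frame.
#' @return A data frame with one row per (insertion, population) pair
#'   plus one `"global"` row per insertion; columns as in
#'   [allele_frequency()].
#' @export
allele_frequency_table <- function(genotypes) {
  ins <- unique(genotypes$insertion_id)
  rows <- list()
  for (id in ins) {
    pops <- unique(genotypes$population_id[genotypes$insertion_id == id])
    for (p in pops) {
      r <- tryCatch(allele_frequency(genotypes, id, p), error = function(e) NULL)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
    rows[[length(rows) + 1L]] <- allele_frequency(genotypes, id)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Population occupancy of each insertion
#'
#' @param catalog Named list mapping population ids to character vectors
#'   of insertion ids present there (orientation-suffixed variants are
#'   distinct insertions).
#' @return Named integer vector: for each insertion, the number of
#'   populations in which it occurs.
#' @export
occupancy <- function(catalog) {
  stopifnot(length(catalog) > 0)
  ids <- unlist(lapply(catalog, unique), use.names = FALSE)
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Insertions private to a single population
#'
#' @inheritParams occupancy
#' @return Character vector of insertion ids with occupancy exactly 1.
#' @export
private_insertions <- function(catalog) {
  occ <- occupancy(catalog)
  names(occ)[occ == 1L]
}

#' Number of distinct insertions in a catalogue
#'
#' @inheritParams occupancy
#' @return Integer count of distinct insertion ids across populations.
#' @export
distinct_insertions <- function(catalog) {
  if (length(catalog) == 0) return(0L)
  length(unique(unlist(catalog, use.names = FALSE)))
}

#' Expected frequency of strains carrying two insertions
#'
#' For two insertions on different haplotypes, the expected fraction of
#' flies carrying both. The default `"product"` mode multiplies the two
#' observed allele frequencies, the rule used in the source screen; the
#' `"hwe"` mode returns the Hardy-Weinberg trans-heterozygote frequency
#' 2ab for comparison (exactly twice the product value).
#'
#' @param freq_a,freq_b Observed allele frequencies in \[0, 1\].
#' @param mode `"product"` or `"hwe"`.
#' @return A list with `mode` and `expected_fraction`.
#' @export
expected_cooccurrence <- function(freq_a, freq_b, mode = c("product", "hwe")) {
  mode <- match.arg(mode)
  if (freq_a < 0 || freq_a > 1 || freq_b < 0 || freq_b > 1) {
    stop("frequencies must be in [0, 1]")
  }
  val <- freq_a * freq_b
  if (mode == "hwe") val <- 2 * val
  list(mode = mode, expected_fraction = val)
}

#' Pearson correlation of a population summary with latitude
#'
#' @param latitude Numeric vector of population latitudes (degrees).
#' @param response Numeric response per population (e.g. number of
#'   distinct insertions, or number of strains with an insertion).
#' @return A list with `r`, `r_squared`, `p_value` (two-sided, t
#'   distribution with n - 2 df) and `n`.
#' @export
latitude_correlation <- function(latitude, response) {
  stopifnot(length(latitude) == length(response))
  if (length(latitude) < 3) stop("need at least 3 populations")
  if (stats::sd(latitude) == 0 || stats::sd(response) == 0) {
    stop("zero variance in latitude or response")
  }
  ct <- stats::cor.test(latitude, response, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(latitude))
}

#' Climate association of an insertion by Fisher's exact test
#'
#' Tests whether carriers of an insertion are over-represented in a focal
#' climate class, using a two-sided Fisher's exact test on the 2x2 table
#' (focal class vs pooled other classes) x (carrier vs non-carrier
#' strains).
#'
#' @param carriers Named integer vector: strains carrying the insertion
#'   per climate class.
#' @param noncarriers Named integer vector: strains without the insertion
#'   per climate class (same names).
#' @param focal_class The climate class tested for enrichment.
#' @return A list with `focal_class`, `odds_ratio`, `p_value`, `n` and
#'   the 2x2 `table`.
#' @export
climate_association <- function(carriers, noncarriers, focal_class) {
  stopifnot(identical(sort(names(carriers)), sort(names(noncarriers))))
  if (length(carriers) < 2) stop("need at least 2 climate classes")
  if (!focal_class %in% names(carriers)) stop("unknown focal class")
  if (any(carriers < 0) || any(noncarriers < 0)) stop("counts must be >= 0")
  if (sum(carriers) + sum(noncarriers) == 0) stop("all-zero table")
  others <- setdiff(names(carriers), focal_class)
  tab <- matrix(c(carriers[[focal_class]], noncarriers[[focal_class]],
                  sum(carriers[others]), sum(noncarriers[others])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("focal", "other"),
                                c("carrier", "noncarrier")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(focal_class = focal_class, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, n = sum(tab), table = tab)
}

#' Climate association scan over many insertions
#'
#' Runs [climate_association()] for each insertion and optionally adjusts
#' p-values for multiple testing (Benjamini-Hochberg). No adjustment is
#' the default.
#'
#' @param counts A data frame with columns `insertion_id`,
#'   `climate_class`, `carriers`, `noncarriers`.
#' @param focal_class Climate class tested for enrichment.
#' @param adjust `"none"` or `"BH"`.
#' @return A data frame with `insertion_id`, `odds_ratio`, `p_value` and,
#'   when adjusted, `p_adjusted`.
#' @export
climate_association_scan <- function(counts, focal_class,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ids <- unique(counts$insertion_id)
  res <- lapply(ids, function(id) {
    sub <- counts[counts$insertion_id == id, , drop = FALSE]
    a <- climate_association(
      setNames(sub$carriers, sub$climate_class),
      setNames(sub$noncarriers, sub$climate_class),
      focal_class
    )
    data.frame(insertion_id = id, odds_ratio = a$odds_ratio,
               p_value = a$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
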