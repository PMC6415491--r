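#' Build a carrier map from a genotype table
#'
#' The carrier map records, for each insertion, which strains carry it
#' (heterozygous or homozygous — a presence/absence screen calls
#' presence, not dosage), together with the universe of successfully
#' screened strains. Strains whose genotyping failed for every insertion
#' are excluded from the universe.
#'
#' @param genotypes A `genotype_table` data frame.
#' @return A list of class `carrier_map` with `carriers` (named list:
#'   insertion_id -> character vector of strain ids) and `universe`
#'   (character vector of screened strain ids).
#' @export
carrier_map <- function(genotypes) {
  ok <- genotypes[genotypes$state != "failed", , drop = FALSE]
  carr <- ok[ok$state %in% c("heterozygous", "homozygous"), , drop = FALSE]
  carriers <- lapply(split(carr$strain_id, carr$insertion_id), unique)
  structure(list(
    carriers = carriers,
    universe = sort(unique(ok$strain_id))
  ), class = "carrier_map")
}

#' @rdname carrier_map
#' @param carriers Named list: insertion_id -> strain ids.
#' @param universe Character vector of all screened strains.
#' @export
new_carrier_map <- function(carriers, universe) {
  if (!all(unlist(carriers, use.names = FALSE) %in% universe)) {
    stop("carrier strain outside the screened universe")
  }
  structure(list(carriers = lapply(carriers, unique),
                 universe = unique(universe)),
            class = "carrier_map")
}

#' Exact expected number of distinct insertions in a random subsample
#'
#' Closed form for the expectation of the number of distinct insertions
#' detected when n strains are drawn uniformly without replacement from N
#' screened strains: each insertion with c carriers is detected unless
#' all n draws avoid its carriers, so
#' E = sum_i \[1 - C(N - c_i, n) / C(N, n)\], with terms where
#' N - c_i < n contributing 1.
#'
#' @param carriers A `carrier_map`.
#' @param n Subsample size; must not exceed the universe size.
#' @return The exact expectation (numeric scalar).
#' @export
exact_expected_distinct <- function(carriers, n) {
  N <- length(carriers$universe)
  if (n > N) stop("subsample size exceeds number of screened strains")
  if (n < 1) stop("subsample size must be >= 1")
  cs <- lengths(carriers$carriers)
  sum(ifelse(N - cs < n, 1,
             1 - exp(lchoose(N - cs, n) - lchoose(N, n))))
}

#' Monte-Carlo estimate of distinct insertions detected by a small screen
#'
#' Repeatedly draws n strains uniformly without replacement from the
#' screened universe and counts the distinct insertions carried by at
#' least one sampled strain — the simulation used to judge whether a
#' small PCR screen (e.g. 10 strains) suffices to reveal an insertion
#' cluster. The closed-form expectation is attached for comparison.
#' Identical inputs and seed give identical output.
#'
#' @param carriers A `carrier_map`.
#' @param n Subsample size.
#' @param trials Number of Monte-Carlo trials.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return A list of class `power_estimate` with `n_subsample`, `trials`,
#'   `seed`, `mean_distinct`, `sd_distinct`, `exact_expectation` and the
#'   per-trial `counts`.
#' @export
mean_distinct_subsample <- function(carriers, n = 10, trials = 1000, seed) {
  if (missing(seed)) stop("a seed is required")
  if (trials < 1) stop("trials must be >= 1")
  N <- length(carriers$universe)
  if (n > N) stop("subsample size exceeds number of screened strains")
  ## carrier incidence matrix: insertions x strains
  M <- vapply(carriers$carriers,
              function(s) carriers$universe %in% s,
              logical(N))
  M <- matrix(M, nrow = N)  # strains x insertions
  counts <- integer(trials)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (i in seq_len(trials)) {
    idx <- sample.int(N, n)
    counts[i] <- sum(colSums(M[idx, , drop = FALSE]) > 0)
  }
  structure(list(
    n_subsample = n,
    trials = trials,
    seed = seed,
    mean_distinct = mean(counts),
    sd_distinct = stats::sd(counts),
    exact_expectation = exact_expected_distinct(carriers, n),
    counts = counts
  ), class = "power_estimate")
}
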