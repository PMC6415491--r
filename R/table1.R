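#' Packaged multi-population PCR screen summary
#'
#' A literal transcription of the published per-population PCR screen of
#' the CG18446 promoter region: for each of the 15 natural populations,
#' the number of strains analysed (including, in parentheses in the
#' original, strains screened in the earlier study and folded into
#' `n_analyzed` here), the numbers of strains homozygous and heterozygous
#' for the presence of a roo insertion, and the identifiers of the roo
#' insertions found. Insertions observed in the reverse (3'-5')
#' orientation at a site carry the suffix `_rev` and are distinct
#' identifiers, matching the published treatment of opposite-orientation
#' insertions at one position.
#'
#' @return A list of class `table1_fixture` with elements
#'   \describe{
#'     \item{populations}{data frame: `population_id`, `n_analyzed`,
#'       `n_hom`, `n_het`.}
#'     \item{insertions}{named list mapping `population_id` to the
#'       character vector of insertion identifiers found there.}
#'     \item{totals}{list with `n_analyzed`, `n_hom`, `n_het`,
#'       `n_insertions` as printed in the source table's TOTAL row.}
#'   }
#' @export
load_table1_fixture <- function() {
  populations <- data.frame(
    population_id = c(
      "Akka_FI", "Stockholm_SE", "Lund_SE", "Karensminde_DK", "Munich_DE",
      "MarketHarborough_UK", "Gotheron_FR", "Bari_IT", "Gimenells_ES",
      "Tomelloso_ES", "CortesDeBaza_ES", "Guadix_ES", "SanCristobal_ES",
      "Raleigh_US", "Siavonga_ZI"
    ),
    n_analyzed = c(13L, 23L, 6L, 12L, 14L, 20L, 13L, 12L, 14L, 15L, 13L,
                   14L, 12L, 49L, 27L),
    n_hom = c(3L, 9L, 3L, 5L, 6L, 5L, 3L, 3L, 3L, 3L, 0L, 0L, 6L, 36L, 2L),
    n_het = c(4L, 6L, 1L, 2L, 5L, 7L, 2L, 4L, 9L, 10L, 9L, 11L, 2L, 0L, 10L),
    stringsAsFactors = FALSE
  )
  insertions <- list(
    Akka_FI = c("roo-90", "roo-64", "roo-291"),
    Stockholm_SE = c("roo-44", "roo-68", "roo-90", "roo-393", "roo-64",
                     "roo-42", "FBti0019985_rev"),
    Lund_SE = c("roo-68", "roo-64"),
    Karensminde_DK = c("FBti0019985", "roo-19", "roo-68", "roo-64",
                       "roo-90_rev"),
    Munich_DE = c("roo+175", "roo-68", "roo-90", "roo-378"),
    MarketHarborough_UK = c("FBti0019985", "roo+37", "roo-68", "roo-90",
                            "roo-291", "roo-42", "roo-90_rev"),
    Gotheron_FR = c("roo-68", "roo-90", "roo-378", "roo-64"),
    Bari_IT = c("FBti0019985", "roo+175", "roo-19", "roo-28", "roo-68",
                "roo-90"),
    Gimenells_ES = c("FBti0019985", "roo+175", "roo-44", "roo-90"),
    Tomelloso_ES = c("roo-44", "roo-90", "roo-291"),
    CortesDeBaza_ES = c("roo-44", "roo-90", "roo-90_rev"),
    Guadix_ES = c("roo-68", "roo-90", "roo-64", "FBti0019985_rev"),
    SanCristobal_ES = c("FBti0019985", "roo-90", "roo-291"),
    Raleigh_US = c("FBti0019985", "roo+7", "roo+278", "roo-28", "roo-44",
                   "roo-68", "roo-90", "FBti0019985_rev"),
    Siavonga_ZI = c("roo-90", "roo+7_rev", "roo-56", "roo+192")
  )
  structure(
    list(
      populations = populations,
      insertions = insertions,
      totals = list(n_analyzed = 257L, n_hom = 87L, n_het = 82L,
                    n_insertions = 20L)
    ),
    class = "table1_fixture"
  )
}

#' Convert the packaged screen summary into a population catalogue
#'
#' @param fixture A `table1_fixture`, as returned by
#'   [load_table1_fixture()].
#' @return A named list mapping population identifiers to character
#'   vectors of insertion identifiers, the input expected by
#'   [occupancy()], [private_insertions()] and [distinct_insertions()].
#' @export
table1_to_catalog <- function(fixture = load_table1_fixture()) {
  stopifnot(inherits(fixture, "table1_fixture"))
  fixture$insertions
}
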