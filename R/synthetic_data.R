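#' Default multi-population study design for the simulator
#'
#' Fifteen populations whose strain counts follow the packaged PCR-screen
#' summary ([load_table1_fixture()]), with representative latitudes and
#' climate classes for a European transect plus one North American and
#' one sub-Saharan population.
#'
#' @return A `population_meta`-style data frame.
#' @export
default_populations <- function() {
  fx <- load_table1_fixture()$populations
  meta <- data.frame(
    population_id = fx$population_id,
    latitude = c(65.0, 59.3, 55.7, 55.4, 48.1, 52.5, 45.0, 41.1, 41.7,
                 39.2, 37.7, 37.3, 28.5, 35.8, -16.5),
    climate_class = c("cold", "cold", "cold", "cold", "temperate",
                      "temperate", "temperate", "temperate", "temperate",
                      "arid", "arid", "arid", "temperate", "temperate",
                      "arid"),
    n_strains = fx$n_analyzed,
    stringsAsFactors = FALSE
  )
  class(meta) <- c("population_meta", "data.frame")
  meta
}

#' Simulation configuration for a multi-strain TE insertion screen
#'
#' Defines the study conditions the generator emulates: the population
#' structure (sizes, latitudes, climates), a scaled-down genome of a few
#' contigs, gene models with 5'UTRs, a background rate of scattered
#' de novo insertions, and one or more planted promoter clusters of
#' recurrent insertions with configured per-site allele frequencies,
#' 5-bp TSDs and a 428-bp solo-LTR-sized element.
#'
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the config including the seed.
#' @param populations Data frame with `population_id`, `latitude`,
#'   `climate_class`, `n_strains`.
#' @param contigs Named integer vector of contig lengths (bp).
#' @param n_genes Number of genes, spread across contigs.
#' @param upstream_bp Promoter upstream window size.
#' @param background_rate Expected background insertions per kb per
#'   strain (Poisson). The default matches the genome-wide density of
#'   de novo roo calls in large strain panels (roughly one call per
#'   2,000 kb per strain).
#' @param planted_clusters List of cluster specs; each a list with
#'   `gene_index` (which gene hosts the cluster), `frequencies` (per-site
#'   population allele frequency, one per distinct site), `span_bp`
#'   (stretch of the upstream window holding the sites),
#'   `sense_fraction` (orientation mix).
#' @param tsd_length TSD length planted in allele pairs.
#' @param element_length Inserted element length (bp).
#' @param flank_length Flank length on either side of allele pairs.
#' @param failed_rate Per (strain, insertion) probability that the
#'   genotyping reaction fails.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              populations = default_populations(),
                              contigs = c(chr2L = 150000L, chr2R = 150000L,
                                          chr3L = 150000L),
                              n_genes = 30,
                              upstream_bp = 1000,
                              background_rate = 0.0005,
                              planted_clusters = list(list(
                                gene_index = 1,
                                frequencies = c(0.165, 0.063, 0.02, 0.02, 0.01),
                                span_bp = 600,
                                sense_fraction = 0.8
                              )),
                              tsd_length = 5,
                              element_length = 428,
                              flank_length = 150,
                              failed_rate = 0) {
  stopifnot(background_rate >= 0, failed_rate >= 0, failed_rate <= 1,
            tsd_length >= 1, element_length >= 1, n_genes >= 1)
  for (cl in planted_clusters) {
    if (any(cl$frequencies < 0 | cl$frequencies > 1)) {
      stop("planted allele frequencies must be in [0, 1]")
    }
    if (cl$span_bp > upstream_bp) {
      stop("planted site span exceeds the promoter upstream window")
    }
  }
  structure(list(
    seed = seed, populations = populations, contigs = contigs,
    n_genes = n_genes, upstream_bp = upstream_bp,
    background_rate = background_rate, planted_clusters = planted_clusters,
    tsd_length = tsd_length, element_length = element_length,
    flank_length = flank_length, failed_rate = failed_rate
  ), class = "simulation_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## deterministic gene placement: bodies of 2 kb every 6 kb from 5 kb in,
## round-robin over contigs; 200 bp 5'UTR at the 5' end of the body
.place_genes <- function(config) {
  contig <- rep(names(config$contigs), length.out = config$n_genes)
  per <- stats::setNames(rep(0L, length(config$contigs)), names(config$contigs))
  start <- integer(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    start[i] <- 5000L + per[[contig[i]]] * 6000L
    per[[contig[i]]] <- per[[contig[i]]] + 1L
    if (start[i] + 2000L > config$contigs[[contig[i]]]) {
      stop("contig ", contig[i], " too short for ", config$n_genes, " genes")
    }
  }
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(config$n_genes)),
    chrom = contig, strand = strand,
    start = start, end = start + 2000L,
    tss = ifelse(strand == "+", start, start + 2000L - 1L),
    stringsAsFactors = FALSE
  )
  utr5 <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(strand == "+", genes$start, genes$end - 200L),
    end = ifelse(strand == "+", genes$start + 200L, genes$end),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, utr5 = utr5), class = "gene_models")
}

#' Generate a complete ground-truthed synthetic insertion screen
#'
#' Emits every input the analysis modules consume — gene annotation,
#' pooled per-strain insertion calls (planted recurrent sites plus
#' Poisson background), a strain-by-insertion genotype table, population
#' metadata and occupied/empty allele FASTA pairs with known TSDs —
#' together with the generating truth. Planted genotypes are drawn per
#' strain under Hardy-Weinberg at the configured site frequency; carrier
#' strains receive a coordinate-range call whose midpoint jitters by at
#' most 2 bp around the true site, so 5-bp collapse reunites them.
#' Allele pairs are re-drawn until TSD detection recovers the planted
#' duplication exactly, guaranteeing repeat-free flanks.
#'
#' @param config A `simulation_config`.
#' @param out_dir Optional directory; when given, files are written
#'   (`genes.gff3`, `calls.bed`, `genotypes.tsv`, `populations.tsv`,
#'   `occupied.fa`, `empty.fa`, `truth.json`).
#' @return A list with `truth` (planted sites, genotype matrix,
#'   per-population realised frequencies, planted windows), `data`
#'   (in-memory `calls`, `genes`, `genotypes`, `populations`, `occupied`,
#'   `empty`) and `files` (paths, or `NULL`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  pops <- config$populations
  strain_pop <- rep(pops$population_id, pops$n_strains)
  strains <- sprintf("%s_s%02d", strain_pop,
                     unlist(lapply(pops$n_strains, seq_len)))
  genes <- .place_genes(config)

  ## --- planted cluster sites -------------------------------------------
  planted <- list()
  for (ci in seq_along(config$planted_clusters)) {
    cl <- config$planted_clusters[[ci]]
    g <- genes$genes[cl$gene_index, ]
    k <- length(cl$frequencies)
    ## distinct positions in the upstream window, >= 12 bp apart so they
    ## stay distinct under 5-bp collapse with +/-2 bp midpoint jitter
    if (g$strand == "+") {
      lo <- g$tss - cl$span_bp
      hi <- g$tss - 1L
    } else {
      lo <- g$tss + 1L
      hi <- g$tss + cl$span_bp
    }
    grid <- seq.int(lo, hi, by = 12L)
    if (length(grid) < k) stop("planted span too small for ", k, " sites")
    pos <- sort(sample(grid, k))
    orient <- ifelse(stats::runif(k) < cl$sense_fraction, "sense", "antisense")
    planted[[ci]] <- data.frame(
      insertion_id = sprintf("ins_c%d_%02d", ci, seq_len(k)),
      gene_id = g$gene_id, chrom = g$chrom, position = pos,
      frequency = cl$frequencies, orientation = orient,
      stringsAsFactors = FALSE
    )
  }
  planted <- do.call(rbind, planted)

  ## --- per-strain genotypes at planted sites (HWE) ---------------------
  geno_rows <- list()
  call_rows <- list()
  n_strains <- length(strains)
  for (i in seq_len(nrow(planted))) {
    f <- planted$frequency[i]
    u <- stats::runif(n_strains)
    state <- ifelse(u < f^2, "homozygous",
                    ifelse(u < f^2 + 2 * f * (1 - f), "heterozygous",
                           "absent"))
    failed <- stats::runif(n_strains) < config$failed_rate
    state[failed] <- "failed"
    geno_rows[[i]] <- data.frame(
      strain_id = strains, population_id = strain_pop,
      insertion_id = planted$insertion_id[i], state = state,
      stringsAsFactors = FALSE
    )
    carrier <- which(state %in% c("heterozygous", "homozygous"))
    if (length(carrier) > 0) {
      jitter <- sample(-2:2, length(carrier), replace = TRUE)
      half <- sample(0:30, length(carrier), replace = TRUE)
      mid <- planted$position[i] + jitter
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        chrom = planted$chrom[i],
        start = mid - half, end = mid + half + 1L,
        strain_id = strains[carrier], family = "roo",
        orientation = planted$orientation[i],
        element_class = "solo-LTR", source = "de-novo-caller",
        stringsAsFactors = FALSE
      )
    }
  }
  genotypes <- genotype_table(do.call(rbind, geno_rows))

  ## --- background insertions ------------------------------------------
  for (s in seq_len(n_strains)) {
    for (ct in names(config$contigs)) {
      len <- config$contigs[[ct]]
      k <- stats::rpois(1, config$background_rate * len / 1000)
      if (k == 0) next
      mid <- sort(sample.int(len - 200L, k) + 100L)
      half <- sample(0:30, k, replace = TRUE)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        chrom = ct, start = mid - half, end = mid + half + 1L,
        strain_id = strains[s], family = "roo",
        orientation = sample(c("sense", "antisense"), k, replace = TRUE),
        element_class = "unknown", source = "de-novo-caller",
        stringsAsFactors = FALSE
      )
    }
  }
  all_calls <- do.call(rbind, call_rows)
  calls <- insertion_calls(
    chrom = all_calls$chrom, start = all_calls$start, end = all_calls$end,
    strain_id = all_calls$strain_id, family = all_calls$family,
    orientation = all_calls$orientation,
    element_class = all_calls$element_class, source = all_calls$source
  )

  ## --- occupied/empty allele pairs with planted TSDs -------------------
  element <- .random_dna(config$element_length)
  occupied <- character(nrow(planted))
  empty <- character(nrow(planted))
  tsds <- character(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    for (try in 1:100) {
      tsd <- .random_dna(config$tsd_length)
      left <- .random_dna(config$flank_length)
      right <- .random_dna(config$flank_length)
      emp <- paste0(left, tsd, right)
      occ <- paste0(left, tsd, element, tsd, right)
      rec <- detect_tsd(occ, emp)
      if (!is.null(rec) && !rec$ambiguous &&
          rec$tsd_sequence == tsd &&
          rec$tsd_length == config$tsd_length &&
          identical(reassemble_occupied(rec, emp), occ)) {
        occupied[i] <- occ; empty[i] <- emp; tsds[i] <- tsd
        break
      }
      if (try == 100) stop("could not generate unambiguous TSD pair")
    }
  }
  names(occupied) <- names(empty) <- planted$insertion_id
  planted$tsd <- tsds

  ## --- realised per-population frequencies -----------------------------
  realized <- allele_frequency_table(genotypes)

  truth <- list(
    sites = planted,
    element_sequence = element,
    planted_windows = unique(data.frame(
      chrom = planted$chrom,
      window_start = as.integer((planted$position %/% 1000) * 1000),
      stringsAsFactors = FALSE
    )),
    realized_frequencies = realized
  )
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      genes = file.path(out_dir, "genes.gff3"),
      calls = file.path(out_dir, "calls.bed"),
      genotypes = file.path(out_dir, "genotypes.tsv"),
      populations = file.path(out_dir, "populations.tsv"),
      occupied = file.path(out_dir, "occupied.fa"),
      empty = file.path(out_dir, "empty.fa"),
      truth = file.path(out_dir, "truth.json")
    )
    .write_gene_models_gff3(genes, files$genes)
    write_insertion_calls(calls, files$calls, dialect = "bed0")
    utils::write.table(genotypes, files$genotypes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pops, files$populations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(occupied),
                                files$occupied)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(empty),
                                files$empty)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
  }
  list(
    truth = truth,
    data = list(calls = calls, genes = genes, genotypes = genotypes,
                populations = pops, occupied = occupied, empty = empty),
    files = files
  )
}

.write_gene_models_gff3 <- function(genes, path) {
  g <- genes$genes
  ggr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id
  )
  u <- genes$utr5
  if (nrow(u) > 0) {
    strand <- g$strand[match(u$gene_id, g$gene_id)]
    ugr <- GenomicRanges::GRanges(
      u$chrom, IRanges::IRanges(u$start + 1L, u$end), strand = strand,
      type = "five_prime_UTR", ID = paste0(u$gene_id, ".utr5"),
      Parent = u$gene_id
    )
    ggr <- c(ggr, ugr)
  }
  rtracklayer::export(ggr, path, format = "gff3")
  invisible(path)
}

#' Synthetic reconstruction of the DGRP-scale carrier map
#'
#' The detection-power simulation in the source study drew 10-strain
#' subsamples from the DGRP strains screened by PCR. The per-strain
#' genotype calls behind it are not redistributable, so this function
#' builds a synthetic stand-in at the scale the published summary table
#' prints for the North American (DGRP) population: 49 screened strains,
#' 36 of them homozygous carriers of exactly one of the 8 insertions
#' listed there, 13 non-carriers. Carrier counts per insertion follow a
#' geometric rank-abundance series (ratio 1/2, every listed insertion
#' present in at least one strain), the canonical shape for TE insertion
#' frequency spectra in which a couple of insertions are common and the
#' rest rare.
#'
#' @param n_strains Number of screened strains.
#' @param n_carriers Number of carrier strains (one insertion each).
#' @param insertion_ids Insertion identifiers to distribute carriers over.
#' @return A `carrier_map`.
#' @export
synthetic_dgrp_carrier_map <- function(n_strains = 49,
                                       n_carriers = 36,
                                       insertion_ids =
                                         load_table1_fixture()$insertions$Raleigh_US) {
  k <- length(insertion_ids)
  stopifnot(n_carriers >= k, n_carriers <= n_strains)
  w <- 0.5^(seq_len(k) - 1)
  counts <- pmax(1L, as.integer(floor(n_carriers * w / sum(w))))
  while (sum(counts) > n_carriers) {
    counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  }
  while (sum(counts) < n_carriers) {
    counts[which.max(counts)] <- counts[which.max(counts)] + 1L
  }
  strains <- sprintf("SYN_RAL_%03d", seq_len(n_strains))
  carrier_strains <- split(strains[seq_len(n_carriers)],
                           rep(seq_len(k), counts))
  new_carrier_map(stats::setNames(carrier_strains, insertion_ids), strains)
}
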