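#' Simulation configuration for the analytical-validation mixture
#'
#' The defaults mirror an equimolar pool of ten deeply genotyped reference
#' genomes carrying 1624 known variants (121 of them indels) with mixture
#' allele frequency at least 0.1, sequenced to a mean depth of 1000 over a
#' target space of 1,034,817 callable positions. Truth variants are placed
#' on `k` of the `2 * n_individuals` haplotypes, so the mixture AF spectrum
#' contains only multiples of `1/(2 * n_individuals)`; `k` is drawn by
#' genotype sampling at a population frequency `q ~ Uniform(af_q_range)`,
#' conditioned on `k >= 2`. The default `af_q_range = c(0.3, 0.7)` models
#' the truth set as well-genotyped common polymorphisms, whose mixture AFs
#' sit comfortably above the 0.1 calling cutoff (see the methods vignette);
#' the range is an exposed knob because the true spectrum of such a
#' validation specimen is design-dependent.
#'
#' @param seed Integer seed recorded in every output.
#' @param n_individuals Individuals in the mixture (default 10).
#' @param n_truth Truth-set size (default 1624).
#' @param indel_fraction Fraction of truth variants that are indels
#'   (default 121/1624).
#' @param target_space Callable positions in the target space
#'   (default 1,034,817).
#' @param mean_depth Mean read depth per position (default 1000).
#' @param error_rate Per-base substitution error rate (default 0.001),
#'   spread uniformly over the three non-reference bases.
#' @param depth_sigma Lognormal sigma of the per-position capture-efficiency
#'   multiplier (default 0.3).
#' @param af_q_range Population-frequency range for genotype sampling.
#' @return A list of class `pv_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_individuals = 10L, n_truth = 1624L,
                       indel_fraction = 121 / 1624,
                       target_space = 1034817L, mean_depth = 1000,
                       error_rate = 0.001, depth_sigma = 0.3,
                       af_q_range = c(0.3, 0.7)) {
  if (n_individuals < 2) abort("mixture requires at least 2 individuals")
  stopifnot(error_rate >= 0, error_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  structure(list(seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 n_truth = as.integer(n_truth),
                 indel_fraction = indel_fraction,
                 target_space = as.integer(target_space),
                 mean_depth = mean_depth, error_rate = error_rate,
                 depth_sigma = depth_sigma, af_q_range = af_q_range),
            class = "pv_sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate the pooled validation specimen
#'
#' Generates the pileup of an equimolar multi-genome mixture directly at the
#' position level (no read simulation: alignment is upstream of this
#' pipeline). Per-position depth is Poisson around a lognormal
#' capture-efficiency multiplier of the mean depth; at a truth locus with
#' mixture AF `f`, alternate reads are Binomial with success probability
#' `f(1-e) + (1-f)e/3`; elsewhere, error reads at rate `e` are split
#' uniformly over the three non-reference bases. The emitted truth set is
#' the ground truth for [benchmark_calls()].
#'
#' @param config A [sim_config()] object.
#' @return A list of class `pv_mixture` with elements `pileup` (long-format
#'   pileup tibble: `chrom`, `pos`, `ref`, `allele`, `count`), `truth`
#'   (tibble: `chrom`, `pos`, `ref`, `alt`, `type`, `k`, `af`) and `config`.
#' @export
simulate_mixture <- function(config = sim_config()) {
  set.seed(config$seed)
  n_pos <- config$target_space
  n_truth <- config$n_truth
  n_hap <- 2L * config$n_individuals

  truth_pos <- sort(sample.int(n_pos, n_truth))
  k <- integer(n_truth)
  todo <- seq_len(n_truth)
  while (length(todo) > 0) {
    q <- runif(length(todo), config$af_q_range[1], config$af_q_range[2])
    k[todo] <- rbinom(length(todo), n_hap, q)
    todo <- todo[k[todo] < 2L]
  }
  af <- k / n_hap

  n_indel <- round(n_truth * config$indel_fraction)
  is_indel <- seq_len(n_truth) %in% sample.int(n_truth, n_indel)

  ref <- sample(BASES, n_pos, replace = TRUE)
  truth_ref <- ref[truth_pos]
  truth_alt <- purrr::map_chr(truth_ref, function(r) {
    sample(setdiff(BASES, r), 1)
  })
  type <- rep("SNV", n_truth)
  if (n_indel > 0) {
    ins <- is_indel & runif(n_truth) < 0.5
    del <- is_indel & !ins
    type[ins] <- "insertion"; type[del] <- "deletion"
    truth_alt[ins] <- paste0(truth_ref[ins],
                             sample(BASES, sum(ins), replace = TRUE))
    truth_ref[del] <- paste0(truth_ref[del],
                             sample(BASES, sum(del), replace = TRUE))
    truth_alt[del] <- substr(truth_ref[del], 1, 1)
  }

  mult <- rlnorm(n_pos, meanlog = -config$depth_sigma^2 / 2,
                 sdlog = config$depth_sigma)
  depth <- rpois(n_pos, config$mean_depth * mult)

  e <- config$error_rate
  p_alt <- af * (1 - e) + (1 - af) * e / 3
  alt_count <- rbinom(n_truth, depth[truth_pos], p_alt)

  n_err <- rbinom(n_pos, depth, e)
  n_err[truth_pos] <- 0L  # error reads at truth loci are folded into p_alt
  e1 <- rbinom(n_pos, n_err, 1 / 3)
  e2 <- rbinom(n_pos, n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2

  ref_count <- depth - n_err
  ref_count[truth_pos] <- depth[truth_pos] - alt_count
  # truth loci carry the (possibly multi-base) truth reference spelling so
  # that the reference row stays a reference observation for deletions
  ref[truth_pos] <- truth_ref

  # error alleles: the three non-reference bases in fixed base order
  alt_base <- function(r, slot) {
    others <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(BASES, NULL))
    others[cbind(match(r, BASES), slot)]
  }
  err_rows <- function(counts, slot) {
    idx <- which(counts > 0)
    tibble(pos = idx, ref = ref[idx],
           allele = alt_base(ref[idx], slot), count = counts[idx])
  }

  pileup <- bind_rows(
    tibble(pos = seq_len(n_pos), ref = ref, allele = ref,
           count = ref_count),
    tibble(pos = truth_pos, ref = truth_ref, allele = truth_alt,
           count = alt_count),
    err_rows(e1, 1L), err_rows(e2, 2L), err_rows(e3, 3L)
  ) %>%
    filter(.data$count > 0) %>%
    mutate(chrom = "mixture", .before = 1) %>%
    arrange(.data$pos)

  truth <- tibble(chrom = "mixture", pos = truth_pos, ref = truth_ref,
                  alt = truth_alt, type = type, k = k, af = af)
  structure(list(pileup = pileup, truth = truth, config = config),
            class = "pv_mixture")
}

#' Simulate a patient sample with injected CNV events over a pooled cohort
#'
#' Builds a read-count matrix for one test sample plus a background pool on
#' a shared exon-sized target grid. Every sample shares per-target capture
#' efficiencies (lognormal) and has its own library-size factor; counts are
#' Poisson. Injected events scale the test sample's expected counts by
#' `cn / 2` (zero for a homozygous deletion). Heterozygous-SNP B-allele
#' fractions for the test sample are simulated per target:  0.5-centred
#' binomial under two copies, 1/3 or 2/3 under three, absent under loss.
#'
#' @param seed Integer seed.
#' @param genes Gene labels of the simulated panel (default 50 genes).
#' @param targets_per_gene Targets (exons) per gene (default 8).
#' @param n_background Background pool size (default 12).
#' @param mean_depth Mean per-target read count (default 400).
#' @param depth_sigma Lognormal sigma of target capture efficiency
#'   (default 0.3).
#' @param lib_sigma Lognormal sigma of per-sample library factors
#'   (default 0.1).
#' @param het_density Expected heterozygous SNPs per target (default 0.8).
#' @param events NULL, or a data frame with columns `gene`, `first_exon`,
#'   `last_exon` (1-based exon indices within the gene) and `cn`
#'   (0, 1 or 3).
#' @return A list of class `pv_sim_patient`: `counts` (long tibble with the
#'   test sample named "case"), `targets` (`target_id`, `gene`), `truth`
#'   (the injected events with target ids), `het_snps` (test-sample BAFs)
#'   and `seed`.
#' @export
simulate_patient <- function(seed = 1L, genes = sprintf("G%02d", 1:50),
                             targets_per_gene = 8L, n_background = 12L,
                             mean_depth = 400, depth_sigma = 0.3,
                             lib_sigma = 0.1, het_density = 0.8,
                             events = NULL) {
  set.seed(seed)
  targets <- tibble(
    gene = rep(genes, each = targets_per_gene),
    exon = rep(seq_len(targets_per_gene), times = length(genes))
  ) %>%
    mutate(target_id = paste0(.data$gene, "_e", .data$exon))
  n_t <- nrow(targets)

  cn <- rep(2, n_t)
  truth <- tibble(gene = character(), first_target = character(),
                  last_target = character(), n_targets = integer(),
                  cn = integer())
  if (!is.null(events)) {
    events <- as_tibble(events)
    touched <- logical(n_t)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      idx <- which(targets$gene == ev$gene &
                     targets$exon >= ev$first_exon &
                     targets$exon <= ev$last_exon)
      if (length(idx) == 0) abort("event outside simulated target space")
      if (any(touched[idx])) abort("overlapping contradictory events")
      touched[idx] <- TRUE
      cn[idx] <- ev$cn
      truth <- bind_rows(truth, tibble(
        gene = ev$gene, first_target = targets$target_id[idx[1]],
        last_target = targets$target_id[idx[length(idx)]],
        n_targets = length(idx), cn = as.integer(ev$cn)))
    }
  }

  eff <- rlnorm(n_t, meanlog = -depth_sigma^2 / 2, sdlog = depth_sigma)
  samples <- c("case", sprintf("bg%02d", seq_len(n_background)))
  lib <- rlnorm(length(samples), meanlog = -lib_sigma^2 / 2,
                sdlog = lib_sigma)
  counts <- purrr::map(seq_along(samples), function(s) {
    cns <- if (samples[s] == "case") cn else rep(2, n_t)
    tibble(target_id = targets$target_id, sample = samples[s],
           count = rpois(n_t, mean_depth * eff * lib[s] * cns / 2))
  }) %>% bind_rows()

  case_counts <- counts$count[counts$sample == "case"]
  n_het <- rpois(n_t, het_density)
  n_het[cn %in% c(0, 1)] <- 0L  # loss removes heterozygosity
  het_snps <- purrr::map(which(n_het > 0), function(t) {
    d <- pmax(case_counts[t], 1L)
    baf_p <- if (cn[t] == 3) sample(c(1 / 3, 2 / 3), n_het[t], replace = TRUE)
             else rep(0.5, n_het[t])
    tibble(target_id = targets$target_id[t], gene = targets$gene[t],
           depth = rep(as.integer(d), n_het[t]),
           baf = rbinom(n_het[t], d, baf_p) / d)
  }) %>% bind_rows()

  structure(list(counts = counts, targets = select(targets, "target_id", "gene"),
                 truth = truth, het_snps = het_snps, seed = as.integer(seed)),
            class = "pv_sim_patient")
}
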