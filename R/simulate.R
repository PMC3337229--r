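## Synthetic data with known ground truth, emulating the statistical
## structure of the modelled airway-epithelium study: 5 nonsmokers and
## 6 smokers, log-scale abundance spread, between-subject CV of 0.25,
## intergenic background reads, junction-spanning reads, and homologous
## sequence families.

#' Simulation configuration
#'
#' Defaults encode the study conditions this package models: 5 nonsmokers
#' vs 6 smokers, 43-nt single-end reads, between-subject coefficient of
#' variation 0.25, per-gene abundance `log10(RPKM) ~ N(0.5, 1)` truncated
#' to `[-2, 4.6]` (spanning the detection limit and the most abundant
#' secretoglobin-like transcripts), gene models of ~8 exons of ~250 nt,
#' and an intergenic background rate of 0.05 RPKM-equivalents (about 1/50
#' of a typical expressed exon's density).
#'
#' @param n_genes Number of genes.
#' @param n_nonsmokers,n_smokers Group sizes (defaults 5 and 6).
#' @param exon_count_mean Mean exons per gene (min 1).
#' @param exon_length_mean,exon_length_min Exon length distribution (nt).
#' @param intron_length_mean,intron_length_min Intron length distribution.
#' @param gene_gap_mean,gene_gap_min Intergenic gap distribution.
#' @param abundance_mu,abundance_sigma,abundance_range Parameters of the
#'   truncated normal law for `log10(RPKM)`.
#' @param cv Between-subject coefficient of variation of RPKM.
#' @param depth Sequencing depth (total mapped reads) per subject.
#' @param bg_rate Intron/intergenic background density (RPKM-equivalents).
#' @param responsive_fraction Fraction of genes given a smoking effect.
#' @param effect_range Fold-effect magnitudes, drawn log-uniformly.
#' @param read_length,min_overlap Read length and junction overlap (nt).
#' @param chrom Chromosome name for the synthetic genome.
#' @return A list of class `sae_config`.
#' @export
sae_config <- function(n_genes = 200, n_nonsmokers = 5, n_smokers = 6,
                       exon_count_mean = 8, exon_length_mean = 250,
                       exon_length_min = 50, intron_length_mean = 800,
                       intron_length_min = 100, gene_gap_mean = 8000,
                       gene_gap_min = 1000, abundance_mu = 0.5,
                       abundance_sigma = 1, abundance_range = c(-2, 4.6),
                       cv = 0.25, depth = 2e6, bg_rate = 0.05,
                       responsive_fraction = 0.1, effect_range = c(2, 8),
                       read_length = 43, min_overlap = 3, chrom = "chr1") {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_nonsmokers, cfg$n_smokers, cfg$depth,
              cfg$exon_count_mean, cfg$read_length)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (cfg$cv < 0) abort("cv must be non-negative")
  structure(cfg, class = "sae_config")
}

#' Generate a synthetic genome annotation
#'
#' Genes are laid end to end on one chromosome, separated by intergenic
#' gaps; exon and intron sizes are drawn from the configured
#' distributions. Deterministic under the seed.
#'
#' @param config An [sae_config()].
#' @param seed RNG seed.
#' @return A region tibble as from [build_annotation()].
#' @export
make_annotation <- function(config = sae_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  exons <- vector("list", cfg$n_genes)
  cursor <- cfg$gene_gap_min +
    rpois(1, cfg$gene_gap_mean - cfg$gene_gap_min)
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- 1L + rpois(1, cfg$exon_count_mean - 1)
    ex_len <- cfg$exon_length_min +
      rpois(n_ex, cfg$exon_length_mean - cfg$exon_length_min)
    in_len <- if (n_ex > 1)
      cfg$intron_length_min +
        rpois(n_ex - 1, cfg$intron_length_mean - cfg$intron_length_min)
    else integer(0)
    starts <- cursor + c(0, cumsum(ex_len[-n_ex] + in_len))
    exons[[g]] <- tibble(chrom = cfg$chrom, start = starts,
                         end = starts + ex_len,
                         strand = sample(c("+", "-"), 1),
                         gene = sprintf("G%04d", g))
    cursor <- starts[n_ex] + ex_len[n_ex] + cfg$gene_gap_min +
      rpois(1, cfg$gene_gap_mean - cfg$gene_gap_min)
  }
  build_annotation(bind_rows(exons))
}

#' Simulate ground-truth expression
#'
#' Per-gene base RPKM is drawn from the configured truncated log-normal
#' law; each subject's value is the base times multiplicative log-normal
#' noise calibrated so sd/mean equals the configured CV; smoking effects
#' multiply the smoker values of the responsive gene subset.
#'
#' @param config An [sae_config()].
#' @param annotation Annotation from [make_annotation()].
#' @param seed RNG seed.
#' @return A list of class `sae_truth`: `expr` (tibble `gene`, `subject`,
#'   `group`, `true_rpkm`), `responsive` (tibble `gene`, `effect`),
#'   `subjects`, `config`.
#' @export
simulate_expression <- function(config = sae_config(),
                                annotation = NULL, seed = 1) {
  set.seed(seed + 1L)
  cfg <- config
  genes <- if (is.null(annotation)) sprintf("G%04d", seq_len(cfg$n_genes))
           else sort(unique(annotation$gene[annotation$kind == "exon"]))
  base <- 10^pmin(pmax(rnorm(length(genes), cfg$abundance_mu,
                             cfg$abundance_sigma),
                       cfg$abundance_range[1]), cfg$abundance_range[2])
  subjects <- tibble(
    subject = c(sprintf("NS%02d", seq_len(cfg$n_nonsmokers)),
                sprintf("SM%02d", seq_len(cfg$n_smokers))),
    group = rep(the_groups, c(cfg$n_nonsmokers, cfg$n_smokers))
  )
  n_resp <- round(cfg$responsive_fraction * length(genes))
  resp_idx <- if (n_resp > 0) sort(sample(length(genes), n_resp)) else integer(0)
  fold <- 10^runif(n_resp, log10(cfg$effect_range[1]),
                   log10(cfg$effect_range[2]))
  dir <- sample(c(1, -1), n_resp, replace = TRUE)
  effect <- setNames(rep(1, length(genes)), genes)
  effect[resp_idx] <- fold^dir
  sdlog <- sqrt(log(1 + cfg$cv^2))
  expr <- tidyr::expand_grid(gene = genes, subject = subjects$subject) %>%
    left_join(subjects, by = "subject") %>%
    mutate(
      base = base[match(.data$gene, genes)],
      noise = if (cfg$cv > 0) rlnorm(n(), -sdlog^2 / 2, sdlog) else 1,
      true_rpkm = .data$base * .data$noise *
        if_else(.data$group == "smoker",
                effect[match(.data$gene, genes)], 1)
    ) %>%
    select("gene", "subject", "group", "true_rpkm")
  structure(list(expr = expr,
                 responsive = tibble(gene = genes[resp_idx],
                                     effect = effect[resp_idx]),
                 subjects = subjects, config = cfg),
            class = "sae_truth")
}

#' Simulate aligned reads from ground-truth expression
#'
#' Per gene and subject, the exon read count is Poisson with mean
#' `RPKM x exon_kb x depth_millions`, placed uniformly across the merged
#' exon model; introns and intergenic regions receive background reads at
#' `bg_rate` RPKM-equivalents. The per-million denominator is the nominal
#' depth: the remainder of a real library maps outside the simulated
#' features, so emitted records are a subset of `total_mapped`.
#'
#' @param truth An `sae_truth` from [simulate_expression()].
#' @param annotation The matching annotation.
#' @param depth Total mapped reads per subject (default from the config).
#' @param bg_rate Background density (default from the config).
#' @param seed RNG seed.
#' @return A named list of read sets (class `sae_reads`), one per subject.
#' @export
simulate_reads <- function(truth, annotation, depth = NULL, bg_rate = NULL,
                           seed = 1) {
  set.seed(seed + 2L)
  cfg <- truth$config
  depth <- depth %||% cfg$depth
  bg_rate <- bg_rate %||% cfg$bg_rate
  if (depth <= 0) abort("depth must be positive")
  rl <- cfg$read_length
  ann <- as_tibble(annotation)
  ex <- filter(ann, .data$kind == "exon") %>% arrange(.data$gene, .data$start)
  bg <- filter(ann, .data$kind != "exon")
  dM <- depth / 1e6
  ex_split <- split(ex, ex$gene)
  out <- lapply(truth$subjects$subject, function(s) {
    ev <- filter(truth$expr, .data$subject == s)
    reads <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      exg <- ex_split[[ev$gene[i]]]
      len <- exg$end - exg$start
      n <- rpois(1, ev$true_rpkm[i] * sum(len) / 1000 * dM)
      if (n == 0) return(NULL)
      j <- sample.int(nrow(exg), n, replace = TRUE, prob = len)
      start <- exg$start[j] +
        floor(runif(n) * len[j])
      tibble(chrom = exg$chrom[j], start = as.integer(start),
             end = as.integer(start + rl), strand = "+")
    })
    bg_n <- rpois(nrow(bg), bg_rate * (bg$end - bg$start) / 1000 * dM)
    if (sum(bg_n) > 0) {
      idx <- rep(seq_len(nrow(bg)), bg_n)
      start <- bg$start[idx] +
        floor(runif(length(idx)) * (bg$end[idx] - bg$start[idx]))
      reads <- bind_rows(reads,
                         tibble(chrom = bg$chrom[idx],
                                start = as.integer(start),
                                end = as.integer(start + rl), strand = "+"))
    }
    new_read_set(reads, subject_id = s, total_mapped = depth,
                 read_length = rl)
  })
  setNames(out, truth$subjects$subject)
}

#' Simulate junction-spanning reads
#'
#' For each annotated exon-exon boundary, spliced reads are drawn with
#' Poisson mean `usage x (L/1000) x (depth/1e6) x E`, where `E` is the
#' subject's true expression of the host gene, and placed at offsets valid
#' by construction (at least `min_overlap` nt on each exon).
#'
#' @param truth An `sae_truth`.
#' @param annotation The matching annotation.
#' @param usage Optional tibble (`junction`, `usage`) of baseline usage
#'   ratios (default 1 for every junction).
#' @param usage_effects Optional tibble (`junction`, `smoker_multiplier`)
#'   injecting differential splicing into the smoker group.
#' @param depth Total mapped reads per subject (default from the config).
#' @param seed RNG seed.
#' @return A list with `reads` (tibble `junction`, `gene`, `subject`,
#'   `offset`) and `junctions` (the junction database used).
#' @export
simulate_junction_reads <- function(truth, annotation, usage = NULL,
                                    usage_effects = NULL, depth = NULL,
                                    seed = 1) {
  set.seed(seed + 3L)
  cfg <- truth$config
  depth <- depth %||% cfg$depth
  jdb <- build_junction_db(annotation, read_length = cfg$read_length,
                           min_overlap = cfg$min_overlap)
  u <- jdb %>% select("junction", "gene", "effective_length")
  u$usage <- if (is.null(usage)) 1 else
    usage$usage[match(u$junction, usage$junction)]
  u$mult <- if (is.null(usage_effects)) 1 else
    dplyr::coalesce(usage_effects$smoker_multiplier[
      match(u$junction, usage_effects$junction)], 1)
  grid <- tidyr::expand_grid(u, subject = truth$subjects$subject) %>%
    left_join(truth$subjects, by = "subject") %>%
    left_join(truth$expr, by = c("gene", "subject", "group")) %>%
    mutate(lambda = .data$usage *
             if_else(.data$group == "smoker", .data$mult, 1) *
             (.data$effective_length / 1000) * (depth / 1e6) *
             .data$true_rpkm,
           n = rpois(n(), .data$lambda))
  grid <- filter(grid, .data$n > 0)
  idx <- rep(seq_len(nrow(grid)), grid$n)
  reads <- tibble(
    junction = grid$junction[idx],
    gene = grid$gene[idx],
    subject = grid$subject[idx],
    offset = unlist(purrr::map2(grid$effective_length, grid$n,
                                ~ sample.int(.x, .y, replace = TRUE)))
  )
  list(reads = reads, junctions = jdb)
}

#' Simulate homologous sequence families
#'
#' Each family descends from a random ancestor; the first member is the
#' ancestor and the others carry exactly `round((1 - target_identity/100)
#' * length)` substitutions at random positions, so seed-to-member
#' identity concentrates tightly at the target while unrelated sequences
#' share no long high-identity alignment.
#'
#' @param n_families Number of families (default 4).
#' @param members Members per family (default 3).
#' @param target_identity Within-family percent identity (default 92).
#' @param seq_length Sequence length in nt (default 600).
#' @param n_singletons Unrelated sequences added as negatives (default 3).
#' @param seed RNG seed.
#' @return A list with `sequences` (named character) and `truth`
#'   (tibble `gene`, `family`).
#' @export
simulate_family_sequences <- function(n_families = 4, members = 3,
                                      target_identity = 92,
                                      seq_length = 600, n_singletons = 3,
                                      seed = 1) {
  set.seed(seed + 4L)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  ## exact substitution count keeps realised identity tight at the target
  mutate_seq <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- sample(length(v), round(rate * length(v)))
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1), "")
    paste(v, collapse = "")
  }
  rate <- 1 - target_identity / 100
  seqs <- list(); truth <- list()
  for (f in seq_len(n_families)) {
    anc <- rand_seq(seq_length)
    for (m in seq_len(members)) {
      nm <- sprintf("FAM%d_M%d", f, m)
      seqs[[nm]] <- if (m == 1) anc else mutate_seq(anc, rate)
      truth[[nm]] <- tibble(gene = nm, family = sprintf("F%02d", f))
    }
  }
  for (k in seq_len(n_singletons)) {
    nm <- sprintf("SGL%d", k)
    seqs[[nm]] <- rand_seq(seq_length)
  }
  list(sequences = unlist(seqs), truth = bind_rows(truth))
}

#' Simulate exon and intergenic densities for threshold estimation
#'
#' Produces exon and size-matched intergenic RPKM samples from Poisson
#' read counts at a pooled (all-nonsmoker) depth, calibrated so the
#' FDR/FNR intersection falls near the 0.125 RPKM detection limit: a
#' fraction of exons is transcriptionally silent and every region sees a
#' weak uniform background.
#'
#' @param n_regions Exons (and matched intergenic regions) to simulate.
#' @param silent_fraction Fraction of exons with no true expression.
#' @param bg_rate Background density in RPKM-equivalents.
#' @param depth_millions Pooled depth in millions of mapped reads.
#' @param abundance_mu,abundance_sigma `log10 RPKM` law of expressed exons.
#' @param length_range Exon length range in nt.
#' @param seed RNG seed.
#' @return A list with `exon_rpkm`, `intergenic_rpkm` and `truth`
#'   (logical vector: exon truly expressed).
#' @export
simulate_threshold_data <- function(n_regions = 3000, silent_fraction = 0.3,
                                    bg_rate = 0.005, depth_millions = 100,
                                    abundance_mu = 0.5,
                                    abundance_sigma = 1,
                                    length_range = c(150, 350), seed = 1) {
  set.seed(seed + 5L)
  len_kb <- runif(n_regions, length_range[1], length_range[2]) / 1000
  expressed <- runif(n_regions) > silent_fraction
  true <- ifelse(expressed,
                 10^rnorm(n_regions, abundance_mu, abundance_sigma), 0)
  exon_rpkm <- rpois(n_regions, (true + bg_rate) * len_kb * depth_millions) /
    (len_kb * depth_millions)
  intergenic_rpkm <- rpois(n_regions, bg_rate * len_kb * depth_millions) /
    (len_kb * depth_millions)
  list(exon_rpkm = exon_rpkm, intergenic_rpkm = intergenic_rpkm,
       truth = expressed)
}
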