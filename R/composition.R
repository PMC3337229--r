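## Composition of the expressed transcriptome: abundance concentration by
## gene rank, ubiquitous / SAE-enriched partition, expression tiers,
## half-log histograms, cell-type cumulative distributions and microarray
## detection cross-tabulation.

abundance_bins <- c("1", "2-10", "11-100", "101-1000", ">1000")

#' Fraction of total mRNA by gene rank bin
#'
#' Genes are ranked by median RPKM (descending, ties broken by symbol) and
#' the fraction of total mRNA contributed by gene #1, genes #2-10, #11-100,
#' #101-1000 and #>1000 is computed. Fractions sum to one and are invariant
#' under uniform rescaling of all RPKM values.
#'
#' @param medians A tibble with `gene` and a median RPKM column
#'   (`nonsmoker_median` by default).
#' @param value Name of the median column to rank on.
#' @param label Optional tissue label attached to the profile.
#' @return A tibble with `bin`, `fraction` and `label`.
#' @export
abundance_profile <- function(medians, value = "nonsmoker_median",
                              label = "SAE") {
  v <- medians[[value]]
  if (length(v) == 0 || sum(v) <= 0) abort("no expressed genes to profile")
  o <- order(-v, medians$gene)
  v <- v[o]
  rank_bin <- as.character(cut(seq_along(v),
                               breaks = c(0, 1, 10, 100, 1000, Inf),
                               labels = abundance_bins))
  tibble(bin = factor(abundance_bins, levels = abundance_bins),
         fraction = vapply(abundance_bins,
                           function(b) sum(v[rank_bin == b]) / sum(v),
                           0, USE.NAMES = FALSE),
         label = label)
}

#' Compare two rank-abundance profiles by Fisher's exact test
#'
#' Each profile's fractions are expressed as integer counts of a common
#' pseudo-total (default 100, i.e. whole percentages) and the resulting
#' 2 x 5 table is submitted to Fisher's exact test.
#'
#' @param a,b Profiles from [abundance_profile()] with identical bins.
#' @param pseudo_total Common count total used to integerise the fractions.
#' @return The p value.
#' @export
compare_profiles <- function(a, b, pseudo_total = 100) {
  stopifnot(identical(as.character(a$bin), as.character(b$bin)))
  ca <- round(a$fraction * pseudo_total)
  cb <- round(b$fraction * pseudo_total)
  if (sum(ca) == 0 || sum(cb) == 0) abort("degenerate all-zero profile")
  stats::fisher.test(rbind(ca, cb), workspace = 2e7)$p.value
}

#' Partition expressed genes into ubiquitous and SAE-enriched
#'
#' Expressed genes found (case-insensitively) in the reference list of
#' genes expressed across at least 11 of 12 surveyed tissues are labelled
#' `ubiquitous`; the remainder are `enriched`. Expression tiers are
#' assigned from the median RPKM via [tier_assign()].
#'
#' @param medians A tibble of expressed genes with `gene` and
#'   `nonsmoker_median`.
#' @param reference Character vector of ubiquitously expressed gene symbols.
#' @return `medians` with `class` (`ubiquitous`/`enriched`) and `tier`
#'   columns; the ubiquitous share is reported via attributes `n_ubiquitous`
#'   and `pct_ubiquitous`.
#' @export
classify_ubiquitous <- function(medians, reference) {
  if (length(reference) == 0) abort("empty ubiquitous reference list")
  ub <- tolower(medians$gene) %in% tolower(reference)
  out <- medians %>%
    mutate(class = if_else(ub, "ubiquitous", "enriched"),
           tier = tier_assign(.data$nonsmoker_median))
  structure(out, n_ubiquitous = sum(ub),
            pct_ubiquitous = 100 * sum(ub) / nrow(medians))
}

#' Assign expression tiers from median RPKM
#'
#' Low: (0.125, 1]; medium: (1, 10]; high: (> 10). Values at or below the
#' 0.125 detection limit are not expressed and return `NA` (the expressed
#' call is a strict inequality).
#'
#' @param median_rpkm Numeric vector of median RPKM values.
#' @param threshold Detection threshold (default 0.125).
#' @return Factor with levels `low`, `medium`, `high` (`NA` below/at the
#'   threshold).
#' @export
tier_assign <- function(median_rpkm, threshold = 0.125) {
  cut(median_rpkm, breaks = c(threshold, 1, 10, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' Half-log10 histogram of expression values
#'
#' Bin `k` covers `[10^(start + k/2), 10^(start + (k+1)/2))`, anchored by
#' default at the detection limit (log10 0.125 = -0.9). All positive values
#' are binned (bins below the anchor get negative indices), so counts
#' conserve the total.
#'
#' @param values Positive expression values.
#' @param start log10 of the anchor (default -0.9).
#' @return A tibble with `bin` (index), `lower`, `upper` and `count`.
#' @export
halflog_histogram <- function(values, start = -0.9) {
  if (any(values <= 0)) abort("halflog_histogram: values must be positive")
  if (length(values) == 0)
    return(tibble(bin = integer(0), lower = numeric(0), upper = numeric(0),
                  count = integer(0)))
  k <- floor((log10(values) - start) / 0.5)
  rng <- seq(min(k), max(k))
  tibble(bin = as.integer(rng),
         lower = 10^(start + rng / 2),
         upper = 10^(start + (rng + 1) / 2),
         count = vapply(rng, function(b) sum(k == b), 0L))
}

#' Cumulative expression distribution of a gene set
#'
#' Cumulative frequency of a cell-type gene set's expression levels over
#' half-log bins; a non-decreasing curve from 0 to 1.
#'
#' @param medians Expressed-gene tibble with `gene` and `nonsmoker_median`.
#' @param gene_set Character vector of gene symbols.
#' @param start log10 anchor of the half-log bins (default -0.9).
#' @return A tibble with `level` (upper bin edge) and `cum_freq`.
#' @export
celltype_cumulative <- function(medians, gene_set, start = -0.9) {
  hit <- medians[tolower(medians$gene) %in% tolower(gene_set), ]
  if (nrow(hit) == 0)
    abort(paste0("no expressed genes in set; missing: ",
                 paste(head(gene_set, 10), collapse = ", ")))
  h <- halflog_histogram(hit$nonsmoker_median, start = start)
  tibble(level = h$upper, cum_freq = cumsum(h$count) / sum(h$count))
}

#' Per-category expression summary of the partitioned transcriptome
#'
#' For each functional category and partition class, reports the number of
#' genes, the percentage of the category and the median of the member
#' genes' median RPKM.
#'
#' @param partitioned Output of [classify_ubiquitous()].
#' @param category_map Tibble with `gene` and `category`.
#' @return A tibble (`category`, `class`, `n`, `pct_of_category`,
#'   `median_rpkm`).
#' @export
category_summary <- function(partitioned, category_map) {
  ## case-insensitive symbol match, no alias resolution
  joined <- as_tibble(partitioned) %>%
    mutate(gene_lc = tolower(.data$gene)) %>%
    inner_join(category_map %>% mutate(gene_lc = tolower(.data$gene)) %>%
                 select("gene_lc", "category"),
               by = "gene_lc", relationship = "many-to-many") %>%
    select(-"gene_lc")
  joined %>%
    group_by(.data$category, .data$class) %>%
    summarise(n = n(), median_rpkm = median(.data$nonsmoker_median),
              .groups = "drop_last") %>%
    mutate(pct_of_category = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select("category", "class", "n", "pct_of_category", "median_rpkm") %>%
    arrange(.data$category, .data$class)
}

#' Cross-tabulate RNA-Seq tiers against microarray present calls
#'
#' Per expression tier, the percentage of genes called present on more
#' than half the arrays, on half or fewer, or absent from the array
#' (no probe). The three classes are mutually exclusive and sum to 100%.
#'
#' @param partitioned Output of [classify_ubiquitous()].
#' @param pcalls Tibble with `gene` and `percent_present` (percentage of
#'   arrays with a present call); genes absent from the table have no probe.
#' @return A tibble (`class`, `tier`, `detection`, `n`, `pct`).
#' @export
detection_crosstab <- function(partitioned, pcalls) {
  as_tibble(partitioned) %>%
    mutate(gene_lc = tolower(.data$gene)) %>%
    left_join(pcalls %>% mutate(gene_lc = tolower(.data$gene)) %>%
                select("gene_lc", "percent_present"),
              by = "gene_lc") %>%
    mutate(detection = dplyr::case_when(
      is.na(.data$percent_present) ~ "no probe",
      .data$percent_present > 50 ~ "present >50%",
      TRUE ~ "present <50%"
    )) %>%
    group_by(.data$class, .data$tier, .data$detection) %>%
    summarise(n = n(), .groups = "drop_last") %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$class, .data$tier, .data$detection)
}
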