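## Splice-junction usage: database of annotated exon-exon boundaries,
## junction-spanning read counting with a minimum per-exon overlap,
## normalised usage, the three-rule filter cascade, and group tests with
## Q-Q calibration diagnostics.

#' Build the exon-exon junction database
#'
#' One junction per consecutive pair of merged exons per gene. A read of
#' length `R` must overlap each flanking exon by at least `min_overlap`
#' nucleotides, leaving `R - 2k + 1` admissible start positions: the
#' junction's effective length (38 nt for 43-nt reads and 3-nt overlap).
#'
#' @param annotation A region tibble from [build_annotation()].
#' @param read_length Read length `R` in nt (default 43).
#' @param min_overlap Minimum per-exon overlap `k` in nt (default 3).
#' @return A tibble (`junction`, `gene`, `donor_end`, `acceptor_start`,
#'   `effective_length`).
#' @export
build_junction_db <- function(annotation, read_length = 43L,
                              min_overlap = 3L) {
  if (read_length < 2 * min_overlap)
    abort("read length must be at least twice the minimum overlap")
  eff <- as.integer(read_length - 2L * min_overlap + 1L)
  filter(as_tibble(annotation), .data$kind == "exon") %>%
    group_by(.data$gene) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe({
      s <- .data$start; e <- .data$end
      g <- dplyr::cur_group()$gene
      if (length(s) < 2) {
        tibble(junction = character(0), donor_end = integer(0),
               acceptor_start = integer(0))
      } else {
        tibble(junction = sprintf("%s:j%02d", g, seq_len(length(s) - 1)),
               donor_end = e[-length(e)], acceptor_start = s[-1])
      }
    }) %>%
    mutate(effective_length = eff) %>%
    select("junction", "gene", "donor_end", "acceptor_start",
           "effective_length") %>%
    arrange(.data$junction)
}

#' Count junction-spanning reads
#'
#' Reads are given as placements on junction constructs (the spliced
#' aligner is external; [simulate_junction_reads()] produces such
#' placements). A placement at 1-based construct offset `o` — the
#' construct carries `R - k` nt of each flanking exon — spans the boundary
#' with `R - k - o + 1` nt on the donor side and `o + k - 1` nt on the
#' acceptor side; the read counts only when both are at least `k`.
#'
#' @param junction_reads Tibble with `junction`, `offset` and optionally
#'   `subject`.
#' @param junctions Junction database from [build_junction_db()].
#' @param read_length,min_overlap As in [build_junction_db()].
#' @return The junction table (crossed with subjects when present) with a
#'   `count` column of spliced reads.
#' @export
count_junction_reads <- function(junction_reads, junctions,
                                 read_length = 43L, min_overlap = 3L) {
  R <- read_length; k <- min_overlap
  jr <- as_tibble(junction_reads) %>%
    mutate(donor_nt = R - k - .data$offset + 1L,
           acceptor_nt = .data$offset + k - 1L) %>%
    filter(.data$donor_nt >= k, .data$acceptor_nt >= k,
           .data$junction %in% junctions$junction)
  if (!"subject" %in% names(jr)) jr$subject <- "s1"
  frame <- tidyr::expand_grid(junction = junctions$junction,
                              subject = unique(jr$subject))
  jr %>%
    count(.data$junction, .data$subject, name = "count") %>%
    dplyr::right_join(frame, by = c("junction", "subject")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    left_join(junctions, by = "junction") %>%
    arrange(.data$junction, .data$subject)
}

#' Normalised junction usage
#'
#' `U = count / ((L/1000) * (M/1e6) * E)` with `L` the effective junction
#' length in nt, `M` the subject's total mapped reads and `E` the
#' expression of the neighbouring exons (arithmetic mean RPKM of the two
#' flanking exons). Usage is flagged undefined (NA) when `E` is zero.
#'
#' @param count Spliced read count(s).
#' @param effective_length Effective junction length in nt (> 0).
#' @param total_mapped Subject library size (> 0).
#' @param neighbor_rpkm Flanking-exon expression `E`.
#' @return Normalised usage values.
#' @export
junction_usage <- function(count, effective_length, total_mapped,
                           neighbor_rpkm) {
  if (any(effective_length <= 0)) abort("effective length must be positive")
  if (any(total_mapped <= 0)) abort("total mapped reads must be positive")
  ifelse(neighbor_rpkm <= 0, NA_real_,
         count / ((effective_length / 1000) * (total_mapped / 1e6) *
                    neighbor_rpkm))
}

#' Apply the junction filter cascade
#'
#' Three independent exclusion rules, applied in order: (1) host-gene
#' expression below the 0.125 RPKM detection limit (`"gene-rpkm"`);
#' (2) fewer than 2 spliced reads in both the smoker and the nonsmoker
#' samples — no subject of either group reaches 2 spliced reads
#' (`"min-reads"`); (3) host-gene RPKM standard error across
#' all subjects above 0.5 (`"gene-se"`). Because the rules are independent
#' predicates the retained set does not depend on their order; the
#' recorded reason is the first failing rule in the quoted order.
#'
#' @param usage Tibble with `junction`, `gene`, `subject`, `group`,
#'   `count` and `usage` columns.
#' @param expr Long expression tibble used for the gene-level rules.
#' @param min_reads Spliced-read minimum a subject must reach for its
#'   group to pass (default 2).
#' @param max_se Gene RPKM standard-error ceiling (default 0.5).
#' @param threshold Detection limit applied to the host gene's median
#'   RPKM across all subjects (default 0.125).
#' @return The retained usage rows; excluded junctions and their reasons
#'   are in attribute `excluded` (tibble `junction`, `reason`).
#' @export
filter_junctions <- function(usage, expr, min_reads = 2, max_se = 0.5,
                             threshold = 0.125) {
  gene_stats <- expr %>%
    group_by(.data$gene) %>%
    summarise(gene_median = median(.data$rpkm),
              gene_se = sd(.data$rpkm) / sqrt(n()), .groups = "drop")
  reads_by_group <- usage %>%
    group_by(.data$junction, .data$group) %>%
    summarise(reads = max(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "reads",
                       values_fill = 0)
  status <- usage %>%
    distinct(.data$junction, .data$gene) %>%
    left_join(gene_stats, by = "gene") %>%
    left_join(reads_by_group, by = "junction") %>%
    mutate(
      fail_rpkm = .data$gene_median < threshold,
      fail_reads = .data$nonsmoker < min_reads & .data$smoker < min_reads,
      fail_se = .data$gene_se > max_se,
      reason = dplyr::case_when(
        .data$fail_rpkm ~ "gene-rpkm",
        .data$fail_reads ~ "min-reads",
        .data$fail_se ~ "gene-se",
        TRUE ~ NA_character_
      )
    )
  excluded <- status %>%
    filter(!is.na(.data$reason)) %>%
    select("junction", "reason")
  out <- usage %>%
    anti_join(excluded, by = "junction")
  attr(out, "excluded") <- excluded
  out
}

#' Test junction usage between groups, with Q-Q diagnostics
#'
#' Per retained junction, a two-sample t-test of normalised usage between
#' smokers and nonsmokers (pooled variance by default, matching
#' [smoking_test()]), with Benjamini-Hochberg q values reported alongside
#' the raw p values. Q-Q data compare sorted observed `-log10 p` with the
#' expected `-log10` uniform order statistics; the inflation factor is the
#' ratio of the median observed to median expected `-log10 p` and sits at
#' 1 when splicing does not differ between groups.
#'
#' @param usage Retained usage tibble (`junction`, `subject`, `group`,
#'   `usage`).
#' @param var_equal Pooled variance if `TRUE` (default).
#' @return An object of class `sae_junction_test`: list with `tests`
#'   (tibble `junction`, `p_value`, `q_value`), `qq` (tibble `expected`,
#'   `observed`), and `inflation`.
#' @export
junction_test <- function(usage, var_equal = TRUE) {
  per_group <- split(usage$group, usage$junction)[[1]]
  if (sum(per_group == "nonsmoker") < 2 || sum(per_group == "smoker") < 2)
    abort("both groups need at least 2 subjects")
  tests <- usage %>%
    filter(!is.na(.data$usage)) %>%
    group_by(.data$junction) %>%
    summarise(p_value = group_t_pvalue(
      .data$usage[.data$group == "nonsmoker"],
      .data$usage[.data$group == "smoker"],
      var_equal = var_equal), .groups = "drop") %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  qq <- qq_table(tests$p_value)
  structure(list(tests = tests, qq = qq,
                 inflation = inflation_factor(tests$p_value)),
            class = "sae_junction_test")
}

#' Q-Q table of p values against the uniform distribution
#'
#' @param p Raw p values.
#' @return A tibble with `expected` and `observed` `-log10 p`, sorted
#'   ascending.
#' @export
qq_table <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  tibble(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p)) %>%
    arrange(.data$expected)
}

#' Median-based p-value inflation factor
#'
#' Ratio of the median observed `-log10 p` to the uniform-null median
#' (`-log10 0.5`); 1 under a calibrated null.
#'
#' @param p Raw p values.
#' @return The inflation factor.
#' @export
inflation_factor <- function(p) {
  median(-log10(p), na.rm = TRUE) / (-log10(0.5))
}

#' @method glance sae_junction_test
#' @export
glance.sae_junction_test <- function(x, ...) {
  tibble(n_junctions = nrow(x$tests), inflation = x$inflation,
         n_q05 = sum(x$tests$q_value < 0.05, na.rm = TRUE))
}

#' @method tidy sae_junction_test
#' @export
tidy.sae_junction_test <- function(x, ...) x$tests

#' @export
print.sae_junction_test <- function(x, ...) {
  cat("Junction usage test: ", nrow(x$tests), " junctions, inflation ",
      round(x$inflation, 3), "\n", sep = "")
  invisible(x)
}
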