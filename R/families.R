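## Gene families by pairwise sequence identity: local alignment of mRNA
## sequences, links at >= 90% identity with >= 50% coverage of both
## sequences, families as connected components of the link graph.

## BLASTN-like local alignment scores; forward strand only (mRNA vs mRNA).
family_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                type = "local", substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

#' Percent identity and coverage of the best local alignment
#'
#' Aligns two mRNA sequences (forward strand, local alignment with affine
#' gaps: match +1, mismatch -2, gap open -5, gap extend -2). Identity is
#' matches over alignment columns; coverage is the aligned span on each
#' sequence over its length.
#'
#' @param seq_a,seq_b Nucleotide sequences (character), length >= 50 nt.
#' @return A one-row tibble (`identity`, `coverage_a`, `coverage_b`).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  for (s in list(seq_a, seq_b)) {
    if (nchar(s) == 0) abort("empty sequence")
    n_frac <- sum(strsplit(toupper(s), "")[[1]] == "N") / nchar(s)
    if (n_frac > 0.1) warn("sequence has >10% ambiguous bases")
  }
  aln <- family_align(seq_a, seq_b)
  tibble(
    identity = Biostrings::pid(aln, type = "PID1"),
    coverage_a = 100 * IRanges::width(Biostrings::pattern(aln)) / nchar(seq_a),
    coverage_b = 100 * IRanges::width(Biostrings::subject(aln)) / nchar(seq_b)
  )
}

#' Cluster sequences into homologous gene families
#'
#' All sequence pairs are aligned with [pairwise_identity()]; two genes are
#' linked when identity is at least `min_identity` and the alignment covers
#' at least `min_coverage` percent of both sequences. Families are the
#' connected components of the link graph (single-linkage) with at least
#' two members.
#'
#' @param sequences Named character vector of mRNA sequences, or a path to
#'   a FASTA file.
#' @param min_identity Identity threshold in percent (default 90).
#' @param min_coverage Dual coverage threshold in percent (default 50).
#' @return A tibble (`family`, `gene`) with one row per family member,
#'   members ordered alphabetically within families; the qualifying links
#'   (`gene_a`, `gene_b`, `identity`, `coverage_a`, `coverage_b`) are in
#'   attribute `links`.
#' @export
build_families <- function(sequences, min_identity = 90, min_coverage = 50) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- setNames(as.character(ss), names(ss))
  }
  if (length(sequences) < 2) abort("need at least 2 sequences")
  if (is.null(names(sequences))) abort("sequences must be named")
  nm <- names(sequences)
  pairs <- utils::combn(seq_along(sequences), 2)
  links <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pairwise_identity(sequences[[i1]], sequences[[i2]]) %>%
      mutate(gene_a = nm[i1], gene_b = nm[i2])
  }) %>%
    filter(.data$identity >= min_identity,
           pmin(.data$coverage_a, .data$coverage_b) >= min_coverage) %>%
    select("gene_a", "gene_b", "identity", "coverage_a", "coverage_b")
  if (nrow(links) == 0) {
    out <- tibble(family = character(0), gene = character(0))
    attr(out, "links") <- links
    return(out)
  }
  g <- igraph::graph_from_data_frame(links[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- tibble(gene = names(comp$membership),
                    comp = unname(comp$membership)) %>%
    group_by(.data$comp) %>%
    filter(n() >= 2) %>%
    arrange(.data$gene, .by_group = TRUE) %>%
    ungroup()
  ## deterministic family ids keyed to the alphabetically first member
  ids <- members %>%
    group_by(.data$comp) %>%
    summarise(seed = min(.data$gene), .groups = "drop") %>%
    arrange(.data$seed) %>%
    mutate(family = sprintf("F%02d", row_number()))
  out <- members %>%
    left_join(ids, by = "comp") %>%
    select("family", "gene") %>%
    arrange(.data$family, .data$gene)
  attr(out, "links") <- links
  out
}

#' Per-family expression table
#'
#' Joins family memberships with per-gene medians and orders members by
#' descending median RPKM within each family (the CYP2A-style ordering of
#' paralog expression).
#'
#' @param families A tibble from [build_families()].
#' @param medians A tibble with `gene` and `nonsmoker_median`.
#' @return A tibble (`family`, `gene`, `median_rpkm`, `rank_in_family`).
#' @export
family_expression <- function(families, medians) {
  as_tibble(families) %>%
    left_join(medians %>% select("gene", median_rpkm = "nonsmoker_median"),
              by = "gene") %>%
    group_by(.data$family) %>%
    arrange(desc(.data$median_rpkm), .data$gene, .by_group = TRUE) %>%
    mutate(rank_in_family = row_number()) %>%
    ungroup()
}
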