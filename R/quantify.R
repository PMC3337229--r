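## RPKM quantification over exons, introns, intergenic regions and gene
## models. A read contributes at most once to a given region; strand is
## ignored (the library protocol is not strand specific).

#' Reads per kilobase per million mapped reads
#'
#' `rpkm(count, length_nt, total_mapped)` = `count * 1e9 / (length_nt *
#' total_mapped)`. One RPKM corresponds to roughly one mRNA copy per cell,
#' so [rpkm_to_mrna_per_cell()] is the identity on that scale.
#'
#' @param count Raw read count(s) on the region.
#' @param length_nt Region length in nucleotides (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) abort("rpkm: region length must be positive")
  if (any(total_mapped <= 0)) abort("rpkm: total mapped reads must be positive")
  count * 1e9 / (length_nt * total_mapped)
}

#' mRNA copies per cell implied by an RPKM value
#'
#' @param rpkm RPKM value(s).
#' @return A tibble with `copies_per_cell` (= RPKM) and `cells_per_mrna`
#'   (its reciprocal): 0.125 RPKM is one mRNA per 8 cells.
#' @export
rpkm_to_mrna_per_cell <- function(rpkm) {
  tibble(rpkm = rpkm, copies_per_cell = rpkm, cells_per_mrna = 1 / rpkm)
}

#' Count reads overlapping each region
#'
#' Each read contributes at most 1 to a given region; any overlap of at
#' least one nucleotide counts. Coordinates are 0-based half-open on both
#' sides, so a read starting exactly at a region's `end` does not overlap.
#'
#' @param reads A read tibble (`chrom`, `start`, `end`).
#' @param regions A region tibble (`chrom`, `start`, `end`).
#' @return `regions` with a `count` column appended.
#' @export
count_reads <- function(reads, regions) {
  if (nrow(reads) == 0 || nrow(regions) == 0)
    return(mutate(as_tibble(regions), count = 0L))
  n <- GenomicRanges::countOverlaps(regions_to_granges(regions),
                                    regions_to_granges(reads),
                                    minoverlap = 1L, ignore.strand = TRUE)
  mutate(as_tibble(regions), count = as.integer(n))
}

#' Per-region read density with exclusive exon/intron assignment
#'
#' Assigns each read to feature classes for the exon / intron / intergenic
#' density comparison. A read overlapping both exon and intron of the same
#' gene is assigned to whichever class contains the larger overlap (ties to
#' the exon); a read overlapping several genes is assigned within each.
#' Intergenic overlaps are counted directly.
#'
#' @param reads A read tibble.
#' @param annotation A region tibble from [build_annotation()].
#' @param total_mapped Per-million denominator (defaults to the read set's
#'   [total_mapped()]).
#' @return The annotation tibble with `length`, `count` and `rpkm` columns.
#' @export
feature_density <- function(reads, annotation, total_mapped = NULL) {
  total_mapped <- total_mapped %||% total_mapped(reads)
  ann <- as_tibble(annotation)
  if (nrow(reads) == 0) {
    return(mutate(ann, length = .data$end - .data$start, count = 0L,
                  rpkm = 0))
  }
  gr_reads <- regions_to_granges(reads)
  gr_ann <- regions_to_granges(ann)
  hit <- GenomicRanges::findOverlaps(gr_reads, gr_ann, minoverlap = 1L,
                                     ignore.strand = TRUE)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_reads)[S4Vectors::queryHits(hit)],
    IRanges::ranges(gr_ann)[S4Vectors::subjectHits(hit)]
  ))
  hits <- tibble(
    read = S4Vectors::queryHits(hit),
    region = S4Vectors::subjectHits(hit),
    overlap = ov,
    kind = ann$kind[S4Vectors::subjectHits(hit)],
    gene = ann$gene[S4Vectors::subjectHits(hit)]
  )
  genic <- hits %>%
    filter(.data$kind != "intergenic") %>%
    group_by(.data$read, .data$gene) %>%
    ## larger-overlap class wins within a gene; ties go to the exon
    arrange(desc(.data$overlap), .data$kind, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  kept <- bind_rows(genic, filter(hits, .data$kind == "intergenic"))
  cnt <- kept %>% count(.data$region, name = "count")
  ann %>%
    mutate(region = row_number(), length = .data$end - .data$start) %>%
    left_join(cnt, by = "region") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           rpkm = rpkm(.data$count, .data$length, total_mapped)) %>%
    select(-"region")
}

#' Gene-level RPKM for one subject
#'
#' One value per gene symbol over the union exon model: reads overlapping
#' any merged exon of the gene count once for that gene (a read spanning
#' two genes counts for both), divided by the union exon length in kb and
#' the library size in millions.
#'
#' @inheritParams feature_density
#' @return A tibble with `gene`, `exon_length`, `count`, `rpkm`.
#' @export
gene_rpkm <- function(reads, annotation, total_mapped = NULL) {
  total_mapped <- total_mapped %||% total_mapped(reads)
  ex <- filter(as_tibble(annotation), .data$kind == "exon")
  lens <- ex %>%
    group_by(.data$gene) %>%
    summarise(exon_length = sum(.data$end - .data$start), .groups = "drop")
  zero <- lens$gene[lens$exon_length <= 0]
  if (length(zero) > 0) {
    warn(sprintf("excluding %d gene(s) with zero exon length", length(zero)))
    lens <- filter(lens, .data$exon_length > 0)
    ex <- filter(ex, !.data$gene %in% zero)
  }
  if (nrow(reads) == 0) {
    return(mutate(lens, count = 0L,
                  rpkm = rpkm(0, .data$exon_length, total_mapped)))
  }
  hit <- GenomicRanges::findOverlaps(regions_to_granges(reads),
                                     regions_to_granges(ex),
                                     minoverlap = 1L, ignore.strand = TRUE)
  cnt <- tibble(read = S4Vectors::queryHits(hit),
                gene = ex$gene[S4Vectors::subjectHits(hit)]) %>%
    distinct() %>%
    count(.data$gene, name = "count")
  lens %>%
    left_join(cnt, by = "gene") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           rpkm = rpkm(.data$count, .data$exon_length, total_mapped)) %>%
    arrange(.data$gene)
}

#' Build a gene-by-subject expression table
#'
#' @param alignments Named list of read sets (one per subject).
#' @param annotation A region tibble.
#' @param subjects A tibble with columns `subject` and `group`
#'   (`"nonsmoker"` or `"smoker"`).
#' @return A long tibble (`gene`, `subject`, `group`, `rpkm`), one row per
#'   gene and subject.
#' @export
expression_matrix <- function(alignments, annotation, subjects) {
  stopifnot(all(c("subject", "group") %in% names(subjects)))
  if (!all(subjects$group %in% the_groups))
    abort("subject groups must be 'nonsmoker' or 'smoker'")
  if (!all(subjects$subject %in% names(alignments)))
    abort("missing alignments for some subjects")
  purrr::map_dfr(subjects$subject, function(s) {
    gene_rpkm(alignments[[s]], annotation) %>%
      mutate(subject = s) %>%
      select("gene", "subject", "rpkm")
  }) %>%
    left_join(subjects[, c("subject", "group")], by = "subject") %>%
    select("gene", "subject", "group", "rpkm") %>%
    arrange(.data$gene, .data$subject)
}

#' Per-gene group medians of an expression table
#'
#' @param expr A long expression tibble (`gene`, `subject`, `group`, `rpkm`).
#' @return A tibble with `gene`, `nonsmoker_median`, `smoker_median`.
#' @export
expr_medians <- function(expr) {
  expr %>%
    group_by(.data$gene, .data$group) %>%
    summarise(m = median(.data$rpkm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "m",
                       values_fill = NA_real_) %>%
    rename(dplyr::any_of(c(nonsmoker_median = "nonsmoker",
                           smoker_median = "smoker"))) %>%
    arrange(.data$gene)
}

#' Sample candidate sub-intervals matching a template size distribution
#'
#' For each template region, one sub-interval of identical length is drawn
#' from the candidate regions without re-using genomic space, so the output
#' length multiset equals the template length multiset exactly. Used to
#' pick intergenic regions size-matched to the analysed exons.
#'
#' @param template_regions Region tibble whose lengths are to be matched.
#' @param candidate_regions Region tibble supplying genomic space.
#' @param seed Optional RNG seed.
#' @return A region tibble with one sampled interval per template row.
#' @export
matched_size_regions <- function(template_regions, candidate_regions,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sort(template_regions$end - template_regions$start,
               decreasing = TRUE)
  free <- as_tibble(candidate_regions)[, c("chrom", "start", "end")]
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    len <- lens[i]
    fit <- which(free$end - free$start >= len)
    if (length(fit) == 0)
      abort(sprintf(
        "insufficient candidate space: %d region(s) of length >= %d needed",
        sum(lens[i:length(lens)] >= len), len))
    ## weight by the number of admissible start positions
    w <- (free$end - free$start - len + 1)[fit]
    j <- fit[sample.int(length(fit), 1, prob = w)]
    s <- free$start[j] + sample.int(free$end[j] - free$start[j] - len + 1, 1) - 1L
    piece <- tibble(chrom = free$chrom[j], start = s, end = s + len)
    ## split the used block so space is not re-used
    left <- tibble(chrom = free$chrom[j], start = free$start[j], end = s)
    right <- tibble(chrom = free$chrom[j], start = s + len, end = free$end[j])
    free <- bind_rows(free[-j, ], filter(bind_rows(left, right),
                                         .data$end > .data$start))
    out[[i]] <- piece
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}
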