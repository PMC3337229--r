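## Genome annotation: exon models plus derived introns and intergenic regions,
## kept as a single tidy region table.

ann_cols <- c("chrom", "start", "end", "strand", "kind", "gene")

#' Read a genome annotation and derive introns and intergenic regions
#'
#' Reads gene/exon annotation from GTF/GFF or BED and returns a tidy region
#' table in which exons have been union-merged per gene and introns (gaps
#' between consecutive merged exons of a gene) and intergenic regions
#' (gaps between gene extents on a chromosome) are derived deterministically.
#'
#' All coordinates in the returned table are 0-based, half-open; GTF/GFF
#' input (1-based, closed) is converted on read. BED input is taken as one
#' exon per record with the `name` field naming the gene.
#'
#' @param path Path to a GTF/GFF or BED file.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff"` or `"bed"`.
#' @param buffer Number of nucleotides excluded from intergenic regions on
#'   each side of a gene (default 0).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `kind` (`exon`, `intron` or `intergenic`) and `gene` (`NA` for
#'   intergenic regions).
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff", "bed"),
                            buffer = 0) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gtf = "gtf", gff = "gff", gff3 = "gff", bed = "bed",
      abort(paste0("cannot infer annotation format from extension '.", ext, "'"))
    )
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    exons <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene = as.character(gr$name %||% rep(NA_character_, length(gr)))
    )
  } else {
    gr <- rtracklayer::import(path, format = toupper(format))
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[tolower(as.character(gr$type)) == "exon"]
    md <- S4Vectors::mcols(gr)
    gene_field <- intersect(c("gene_id", "gene", "Name", "name", "ID"), names(md))
    if (length(gene_field) == 0)
      abort("annotation carries no gene identifier attribute")
    exons <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene = as.character(md[[gene_field[1]]])
    )
  }
  if (nrow(exons) == 0) abort("annotation contains zero genes")
  if (anyNA(exons$gene)) abort("annotation features lack gene identifiers")
  build_annotation(exons, buffer = buffer)
}

#' Build an annotation table from an exon table
#'
#' Union-merges exons per gene and derives introns and intergenic regions.
#' Merging already-merged exons is idempotent.
#'
#' @param exons A data frame with columns `chrom`, `start`, `end`, `gene`
#'   and optionally `strand` (0-based, half-open coordinates).
#' @inheritParams read_annotation
#' @return A region tibble as returned by [read_annotation()].
#' @export
build_annotation <- function(exons, buffer = 0) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(exons)))
  if (!"strand" %in% names(exons)) exons$strand <- "*"
  if (any(exons$end <= exons$start)) abort("exon with end <= start")
  merged <- exons %>%
    group_by(.data$gene, .data$chrom, .data$strand) %>%
    dplyr::reframe(merge_intervals(.data$start, .data$end)) %>%
    ungroup()

  introns <- merged %>%
    arrange(.data$gene, .data$start) %>%
    group_by(.data$gene, .data$chrom, .data$strand) %>%
    dplyr::reframe({
      s <- .data$start; e <- .data$end
      if (length(s) < 2) tibble(start = integer(0), end = integer(0))
      else tibble(start = e[-length(e)], end = s[-1])
    }) %>%
    ungroup() %>%
    filter(.data$end > .data$start)

  spans <- merged %>%
    group_by(.data$chrom, .data$gene) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  intergenic <- spans %>%
    group_by(.data$chrom) %>%
    dplyr::reframe({
      m <- merge_intervals(.data$start, .data$end)
      if (nrow(m) < 2) tibble(start = integer(0), end = integer(0))
      else tibble(start = m$end[-nrow(m)] + buffer, end = m$start[-1] - buffer)
    }) %>%
    filter(.data$end > .data$start) %>%
    mutate(strand = "*", gene = NA_character_)

  bind_rows(
    merged %>% mutate(kind = "exon"),
    introns %>% mutate(kind = "intron"),
    intergenic %>% mutate(kind = "intergenic")
  ) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    select(dplyr::all_of(ann_cols)) %>%
    arrange(.data$chrom, .data$start, .data$end, .data$kind)
}

## Union-merge a set of intervals (0-based half-open); returns tibble(start,end).
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      k <- length(out_s)
      if (start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], end[i])
      } else {
        out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
      }
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Write an annotation's exon models to GTF
#'
#' Exon records are written per gene with 1-based closed coordinates, so a
#' write/read round trip reproduces the internal 0-based half-open regions.
#'
#' @param annotation A region tibble from [read_annotation()] or
#'   [build_annotation()].
#' @param path Output file path (`.gtf`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  ex <- filter(annotation, .data$kind == "exon")
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand %in% c("+", "-"), ex$strand, "*")
  )
  gr$type <- "exon"
  gr$gene_id <- ex$gene
  gr$transcript_id <- ex$gene
  gr$source <- "saeseq"
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}

## Convert a region data frame (0-based half-open) to GRanges.
regions_to_granges <- function(x, use_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (use_strand && "strand" %in% names(x))
      ifelse(x$strand %in% c("+", "-"), x$strand, "*") else "*"
  )
}
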