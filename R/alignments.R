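## Aligned single-end reads: readers for SAM and BED6, plus writers used by
## the synthetic-data module. A read set is a tibble of placements with
## attributes subject_id, total_mapped and read_length.

#' Read aligned single-end reads from SAM or BED6
#'
#' Only mapped records are retained. Records on chromosomes absent from
#' `chromosomes` (when given) are skipped with a warning. The
#' `total_mapped` attribute defaults to the number of mapped records
#' retained, but can be overridden when the file holds only a subset of
#' the library (e.g. reads on one chromosome).
#'
#' @param path Path to a SAM (with header) or BED6 file.
#' @param subject_id Identifier attached to the returned read set.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @param chromosomes Optional character vector of valid chromosome names.
#' @param total_mapped Optional override for the per-million denominator.
#' @param read_length Read length in nt (default 43).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) and attributes `subject_id`, `total_mapped`,
#'   `read_length`.
#' @export
read_alignments <- function(path, subject_id,
                            format = c("auto", "sam", "bed"),
                            chromosomes = NULL, total_mapped = NULL,
                            read_length = 43L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bed = "bed",
      abort(paste0("cannot infer alignment format from extension '.", ext, "'")))
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    prm <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
    rec <- Rsamtools::scanBam(bam, param = prm)[[1]]
    reads <- tibble(
      chrom = as.character(rec$rname),
      start = rec$pos - 1L,
      end = rec$pos - 1L + rec$qwidth,
      strand = as.character(rec$strand)
    )
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    reads <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  if (!is.null(chromosomes)) {
    bad <- !(reads$chrom %in% chromosomes)
    if (any(bad)) {
      warn(sprintf("%d record(s) on unknown chromosomes skipped", sum(bad)))
      reads <- reads[!bad, ]
    }
  }
  new_read_set(reads, subject_id = subject_id,
               total_mapped = total_mapped %||% nrow(reads),
               read_length = read_length)
}

new_read_set <- function(reads, subject_id, total_mapped, read_length = 43L) {
  stopifnot(total_mapped >= nrow(reads))
  structure(as_tibble(reads),
            subject_id = subject_id,
            total_mapped = as.numeric(total_mapped),
            read_length = as.integer(read_length),
            class = c("sae_reads", class(as_tibble(reads))))
}

#' Total mapped reads of a read set
#' @param reads A read set from [read_alignments()] or [simulate_reads()].
#' @return The per-million denominator (a number).
#' @export
total_mapped <- function(reads) {
  attr(reads, "total_mapped") %||% nrow(reads)
}

#' Write a read set as SAM
#'
#' Emits a minimal header (`@HD`, `@SQ`) and one mapped record per read,
#' using a CIGAR of full-length matches. Used to materialise synthetic
#' read sets in a standard format.
#'
#' @param reads A read tibble (`chrom`, `start`, `end`, `strand`).
#' @param path Output path (`.sam`).
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   maximum end coordinate per chromosome.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(reads$end, reads$chrom, max)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  w <- reads$end - reads$start
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  rec <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                 seq_len(nrow(reads)), flag, reads$chrom, reads$start + 1L,
                 w, strrep("N", w))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a read set as BED6
#' @inheritParams write_sam
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  strand <- ifelse(reads$strand %in% c("+", "-"), reads$strand, ".")
  writeLines(sprintf("%s\t%d\t%d\tr%06d\t0\t%s", reads$chrom,
                     reads$start, reads$end, seq_len(nrow(reads)), strand),
             path)
  invisible(path)
}

#' Write a tidy table as TSV with deterministic ordering
#'
#' Rows are sorted by the first column (then remaining columns as
#' tie-breaks), columns keep their given order and numeric values are
#' written at fixed precision, so identical tables serialise to identical
#' bytes regardless of input row order.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 7).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, digits = 7) {
  tbl <- as_tibble(table)
  if (nrow(tbl) > 1) tbl <- tbl[do.call(order, as.list(tbl)), ]
  tbl <- mutate(tbl, across(dplyr::where(is.numeric),
                            ~ signif(.x, digits = digits)))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
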