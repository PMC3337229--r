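## Shared fixture builders (all data generated in code).

## A two-gene annotation: GA has 2 exons (intron between), GB single exon
## 10 kb downstream of GA's end.
toy_annotation <- function() {
  build_annotation(tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 2000L, 13000L),
    end = c(1500L, 2600L, 13800L),
    strand = c("+", "+", "-"),
    gene = c("GA", "GA", "GB")
  ))
}

## Long expression table from a gene x subject matrix of RPKM values.
toy_expr <- function(values) {
  genes <- rownames(values)
  subjects <- colnames(values)
  tidyr::expand_grid(gene = genes, subject = subjects) |>
    dplyr::mutate(
      group = ifelse(grepl("^NS", subject), "nonsmoker", "smoker"),
      rpkm = values[cbind(gene, subject)]
    )
}

## Gene x subject matrix with constant per-group values.
toy_values <- function(genes, ns_value, s_value = ns_value,
                       n_ns = 5, n_s = 6) {
  subjects <- c(sprintf("NS%02d", seq_len(n_ns)),
                sprintf("SM%02d", seq_len(n_s)))
  m <- matrix(0, nrow = length(genes), ncol = length(subjects),
              dimnames = list(genes, subjects))
  m[, seq_len(n_ns)] <- rep(ns_value, n_ns)
  m[, n_ns + seq_len(n_s)] <- rep(s_value, n_s)
  m
}

## Read tibble with an explicit total_mapped attribute.
new_read_set_for_test <- function(reads, subject, total) {
  structure(tibble::as_tibble(reads), subject_id = subject,
            total_mapped = total, read_length = 43L)
}

## Toy usage table exercising every exclusion rule.
toy_junction_table <- function() {
  subjects <- c(sprintf("NS%02d", 1:5), sprintf("SM%02d", 1:6))
  gene_vals <- list(
    LOW = rep(0.05, 11),                       # median below 0.125, SE 0
    NOISY = c(2, 8, 2, 8, 2, 8, 2, 8, 2, 8, 5), # median 5, SE ~ 0.9
    OK1 = rep(1, 11),
    OK2 = c(2.8, 3.2, 3, 2.9, 3.1, 3, 2.8, 3.2, 3, 2.9, 3.1)
  )
  expr <- purrr::imap_dfr(gene_vals, function(v, g) {
    tibble::tibble(gene = g, subject = subjects,
                   group = ifelse(grepl("NS", subjects),
                                  "nonsmoker", "smoker"),
                   rpkm = v)
  })
  counts <- tibble::tribble(
    ~junction, ~gene, ~per_subject,
    "LOW:j01",   "LOW",   5L,  # plenty of reads, host gene below limit
    "LOW:j02",   "LOW",   5L,
    "NOISY:j01", "NOISY", 5L,  # host gene too variable
    "NOISY:j02", "NOISY", 5L,
    "OK1:j01",   "OK1",   1L,  # no subject reaches 2 reads
    "OK1:j02",   "OK1",   1L,
    "OK1:j03",   "OK1",   4L,
    "OK2:j01",   "OK2",   3L,
    "OK2:j02",   "OK2",   6L,
    "OK2:j03",   "OK2",   0L
  )
  usage <- tidyr::expand_grid(counts, subject = subjects) |>
    dplyr::mutate(group = ifelse(grepl("NS", subject),
                                 "nonsmoker", "smoker"),
                  count = per_subject,
                  usage = count / 0.038) |>
    dplyr::select(junction, gene, subject, group, count, usage)
  list(usage = usage, expr = expr)
}

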