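## Smoking differential expression: per-gene two-sample t-test on RPKM
## with no multiple-testing correction for the headline call, signed
## fold-change of group medians, absolute change, modified-volcano data,
## stratified responsiveness and cross-platform fold-change concordance.

#' Signed fold-change of group medians
#'
#' `FC = smoker/nonsmoker` when expression increases and
#' `-(nonsmoker/smoker)` when it decreases, so the magnitude is always at
#' least 1 and the sign gives the direction (antisymmetric under group
#' swap). Undefined (NA) when either median is zero.
#'
#' @param ns_median,s_median Nonsmoker and smoker median RPKM (vectorised).
#' @return Signed fold-change values.
#' @export
signed_fold_change <- function(ns_median, s_median) {
  ifelse(ns_median <= 0 | s_median <= 0, NA_real_,
         ifelse(s_median >= ns_median, s_median / ns_median,
                -(ns_median / s_median)))
}

#' Absolute expression change
#'
#' `smoker median - nonsmoker median`, in RPKM. Unlike a log-ratio this
#' weights genes by how many transcripts actually change per cell.
#'
#' @inheritParams signed_fold_change
#' @return Absolute differences.
#' @export
absolute_change <- function(ns_median, s_median) s_median - ns_median

#' Per-gene smoking differential test
#'
#' For every expressed gene (group median above the detection threshold in
#' at least one group) the nonsmoker and smoker RPKM values are compared
#' with a two-sample t-test; genes at `p < alpha` are called
#' smoking-responsive, with no fold-change cut-off and no multiple-testing
#' correction. The default is the pooled-variance (Student) test on raw
#' RPKM; Welch and log-scale variants are available.
#'
#' @param expr A long expression tibble (`gene`, `subject`, `group`,
#'   `rpkm`).
#' @param alpha Responsiveness level (default 0.05).
#' @param threshold Detection threshold for the expressed-gene filter
#'   (default 0.125).
#' @param var_equal Pooled variance if `TRUE` (default); Welch otherwise.
#' @param log_scale Test on `log10(rpkm + 1e-3)` instead of raw RPKM.
#' @return A tibble of class `sae_differential` with columns `gene`,
#'   `nonsmoker_median`, `smoker_median`, `delta`, `fold_change`,
#'   `p_value`, `neg_log10_p`, `responsive`.
#' @export
smoking_test <- function(expr, alpha = 0.05, threshold = 0.125,
                         var_equal = TRUE, log_scale = FALSE) {
  groups <- split(expr$group, expr$gene)[[1]]
  if (sum(groups == "nonsmoker") < 2 || sum(groups == "smoker") < 2)
    abort("both groups need at least 2 subjects")
  med <- expr_medians(expr) %>%
    filter(pmax(.data$nonsmoker_median, .data$smoker_median) > threshold)
  vals <- expr %>% semi_join(med, by = "gene")
  p <- vals %>%
    group_by(.data$gene) %>%
    summarise(p_value = group_t_pvalue(
      .data$rpkm[.data$group == "nonsmoker"],
      .data$rpkm[.data$group == "smoker"],
      var_equal = var_equal, log_scale = log_scale), .groups = "drop")
  out <- med %>%
    left_join(p, by = "gene") %>%
    mutate(delta = absolute_change(.data$nonsmoker_median,
                                   .data$smoker_median),
           fold_change = signed_fold_change(.data$nonsmoker_median,
                                            .data$smoker_median),
           neg_log10_p = -log10(.data$p_value),
           responsive = .data$p_value < alpha) %>%
    select("gene", "nonsmoker_median", "smoker_median", "delta",
           "fold_change", "p_value", "neg_log10_p", "responsive") %>%
    arrange(.data$gene)
  structure(out, alpha = alpha, threshold = threshold,
            class = c("sae_differential", class(out)))
}

## t-test p value robust to degenerate (constant) groups.
group_t_pvalue <- function(x, y, var_equal = TRUE, log_scale = FALSE) {
  if (log_scale) { x <- log10(x + 1e-3); y <- log10(y + 1e-3) }
  if (sd(x) == 0 && sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(t.test(x, y, var.equal = var_equal)$p.value,
           error = function(e) NA_real_)
}

#' @method glance sae_differential
#' @export
glance.sae_differential <- function(x, ...) {
  tibble(n_genes = nrow(x), n_responsive = sum(x$responsive, na.rm = TRUE),
         pct_responsive = 100 * mean(x$responsive, na.rm = TRUE),
         alpha = attr(x, "alpha"), threshold = attr(x, "threshold"))
}

#' Modified-volcano table
#'
#' One row per expressed gene with the absolute change (`delta`, RPKM
#' smoker minus nonsmoker) and `-log10 p`; no thresholding is applied.
#'
#' @param records An `sae_differential` table from [smoking_test()].
#' @return A tibble (`gene`, `delta`, `neg_log10_p`).
#' @export
volcano_table <- function(records) {
  as_tibble(records) %>% select("gene", "delta", "neg_log10_p")
}

#' Responsive fraction per partition class and expression tier
#'
#' @param records An `sae_differential` table.
#' @param partitioned Output of [classify_ubiquitous()].
#' @return A tibble (`class`, `tier`, `n`, `n_responsive`,
#'   `pct_responsive`).
#' @export
responsive_by_stratum <- function(records, partitioned) {
  as_tibble(records) %>%
    inner_join(as_tibble(partitioned)[, c("gene", "class", "tier")],
               by = "gene") %>%
    group_by(.data$class, .data$tier) %>%
    summarise(n = n(), n_responsive = sum(.data$responsive),
              pct_responsive = 100 * mean(.data$responsive),
              .groups = "drop")
}

#' Induced and repressed genes by functional category
#'
#' Splits responsive genes into smoking-induced (`delta > 0`) and
#' smoking-repressed (`delta < 0`) per category, ordered by decreasing
#' `|delta|`, with `log10 |delta|` for plotting.
#'
#' @param records An `sae_differential` table.
#' @param category_map Tibble with `gene` and `category`.
#' @param responsive_only Restrict to responsive genes (default TRUE).
#' @return A tibble (`category`, `direction`, `gene`, `delta`,
#'   `log10_abs_delta`).
#' @export
direction_by_category <- function(records, category_map,
                                  responsive_only = TRUE) {
  rec <- as_tibble(records)
  if (responsive_only) rec <- filter(rec, .data$responsive)
  rec %>%
    inner_join(category_map, by = "gene", relationship = "many-to-many") %>%
    filter(.data$delta != 0) %>%
    mutate(direction = if_else(.data$delta > 0, "induced", "repressed"),
           log10_abs_delta = log10(abs(.data$delta))) %>%
    group_by(.data$category, .data$direction) %>%
    arrange(desc(abs(.data$delta)), .by_group = TRUE) %>%
    ungroup() %>%
    select("category", "direction", "gene", "delta", "log10_abs_delta")
}

#' Fold-change concordance between two platforms
#'
#' Pearson r-squared of signed fold-changes over the shared genes, plus
#' the fraction with agreeing direction (reported separately: perfectly
#' anti-correlated data has r-squared 1 but sign agreement 0).
#'
#' @param fc_a,fc_b Tibbles with `gene` and `fold_change`.
#' @return A one-row tibble (`n`, `r_squared`, `sign_agreement`), with the
#'   per-gene pairs as attribute `pairs`.
#' @export
concordance <- function(fc_a, fc_b) {
  pairs <- inner_join(fc_a %>% select("gene", fc_a = "fold_change"),
                      fc_b %>% select("gene", fc_b = "fold_change"),
                      by = "gene") %>%
    filter(!is.na(.data$fc_a), !is.na(.data$fc_b))
  if (nrow(pairs) < 3) abort("need at least 3 shared genes")
  if (sd(pairs$fc_a) == 0 || sd(pairs$fc_b) == 0)
    abort("zero variance in a fold-change vector")
  out <- tibble(n = nrow(pairs),
                r_squared = cor(pairs$fc_a, pairs$fc_b)^2,
                sign_agreement = mean(sign(pairs$fc_a) == sign(pairs$fc_b)))
  attr(out, "pairs") <- pairs
  out
}
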