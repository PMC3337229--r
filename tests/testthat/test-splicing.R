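## Five-exon gene for junction fixtures.
five_exon_ann <- function() {
  build_annotation(tibble::tibble(
    chrom = "chr1",
    start = seq(1000L, 9000L, by = 2000L),
    end = seq(1000L, 9000L, by = 2000L) + 500L,
    strand = "+", gene = "G1"
  ))
}

test_that("junction database enumerates consecutive exon pairs", {
  jdb <- build_junction_db(five_exon_ann())
  expect_equal(nrow(jdb), 4L)
  expect_true(all(jdb$effective_length == 38L))  # 43 - 2*3 + 1
  single <- build_annotation(tibble::tibble(chrom = "chr1", start = 0L,
                                            end = 900L, strand = "+",
                                            gene = "S"))
  expect_equal(nrow(build_junction_db(single)), 0L)
  expect_error(build_junction_db(five_exon_ann(), read_length = 5,
                                 min_overlap = 3), "twice")
})

test_that("junction reads require the minimum overlap on both exons", {
  jdb <- build_junction_db(five_exon_ann())
  j <- jdb$junction[1]
  ## offset 0: only 2 nt on the acceptor side; offset 39: 2 nt on the donor
  reads <- tibble::tibble(junction = j, offset = c(0L, 19L, 39L))
  cnt <- count_junction_reads(reads, jdb)
  expect_equal(cnt$count[cnt$junction == j], 1L)
  ## enumeration oracle: exactly effective_length offsets are admissible
  sweep <- tibble::tibble(junction = j, offset = -5:45)
  expect_equal(sum(count_junction_reads(sweep, jdb)$count), 38L)
})

test_that("junction usage follows its normalisation and homogeneity", {
  expect_equal(junction_usage(19, 38, 1e6, 100), 5)
  expect_equal(junction_usage(0, 38, 1e6, 100), 0)
  expect_equal(junction_usage(190, 38, 1e7, 100),
               junction_usage(19, 38, 1e6, 100))
  expect_true(is.na(junction_usage(3, 38, 1e6, 0)))
  expect_error(junction_usage(1, 0, 1e6, 1), "positive")
})

test_that("the filter cascade applies the three quoted rules", {
  fx <- toy_junction_table()
  ## check the fixture hits the intended gene-level statistics
  gs <- fx$expr |> dplyr::group_by(gene) |>
    dplyr::summarise(med = median(rpkm), se = sd(rpkm) / sqrt(11))
  expect_lt(gs$med[gs$gene == "LOW"], 0.125)
  expect_gt(gs$se[gs$gene == "NOISY"], 0.5)
  expect_true(all(gs$se[gs$gene %in% c("OK1", "OK2")] < 0.5))

  kept <- filter_junctions(fx$usage, fx$expr)
  excl <- attr(kept, "excluded")
  expect_setequal(unique(kept$junction),
                  c("OK1:j03", "OK2:j01", "OK2:j02"))
  expect_equal(excl$reason[excl$junction == "LOW:j01"], "gene-rpkm")
  expect_equal(excl$reason[excl$junction == "NOISY:j01"], "gene-se")
  expect_equal(excl$reason[excl$junction == "OK1:j01"], "min-reads")

  ## order independence: the retained set equals the complement of the
  ## union of independently evaluated predicates
  gstats <- fx$expr |> dplyr::group_by(gene) |>
    dplyr::summarise(med = median(rpkm), se = sd(rpkm) / sqrt(dplyr::n()))
  by_j <- fx$usage |> dplyr::distinct(junction, gene)
  f1 <- by_j$junction[gstats$med[match(by_j$gene, gstats$gene)] < 0.125]
  maxes <- fx$usage |> dplyr::group_by(junction, group) |>
    dplyr::summarise(mx = max(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = mx)
  f2 <- maxes$junction[maxes$nonsmoker < 2 & maxes$smoker < 2]
  f3 <- by_j$junction[gstats$se[match(by_j$gene, gstats$gene)] > 0.5]
  expect_setequal(unique(kept$junction),
                  setdiff(by_j$junction, union(union(f1, f2), f3)))

  ## an all-pass table is returned unchanged
  ok <- dplyr::filter(fx$usage, junction %in% c("OK2:j01", "OK2:j02"))
  kept2 <- filter_junctions(ok, fx$expr)
  expect_equal(nrow(kept2), nrow(ok))
  expect_equal(nrow(attr(kept2, "excluded")), 0L)
})

test_that("identical group usage gives p = 1 and the q-q machinery is sound", {
  subjects <- c(sprintf("NS%02d", 1:5), sprintf("SM%02d", 1:6))
  usage <- tidyr::expand_grid(junction = c("a:j01", "b:j01"),
                              subject = subjects) |>
    dplyr::mutate(group = ifelse(grepl("NS", subject),
                                 "nonsmoker", "smoker"),
                  usage = rep(c(1, 2, 1, 2, 1, 1, 2, 1, 2, 1, 1), 2))
  jt <- junction_test(usage)
  expect_true(all(jt$tests$p_value > 0))
  expect_equal(nrow(jt$qq), 2L)
  const <- dplyr::mutate(usage, usage = 4)
  expect_equal(junction_test(const)$tests$p_value, c(1, 1))
  expect_error(junction_test(dplyr::filter(usage, subject %in%
                                             c("NS01", "SM01", "SM02"))),
               "at least 2")
  ## q-q table against a direct sort (rows ascend in expected -log10 p,
  ## pairing the i-th smallest observed with the i-th smallest expected)
  p <- c(0.9, 0.1, 0.5)
  qq <- qq_table(p)
  expect_equal(qq$expected, sort(-log10((1:3 - 0.5) / 3)))
  expect_equal(qq$observed, sort(-log10(p)))
  expect_equal(qq$observed[which.max(qq$expected)], max(-log10(p)))
  expect_equal(inflation_factor(rep(0.5, 9)), 1)
})

test_that("an injected five-fold usage shift is detected with high power", {
  cfg <- sae_config(n_genes = 2, exon_count_mean = 3,
                    abundance_mu = 2, abundance_sigma = 0.1,
                    responsive_fraction = 0, depth = 1e6)
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    ann <- make_annotation(cfg, seed = 900 + s)
    truth <- simulate_expression(cfg, ann, seed = 900 + s)
    jdb <- build_junction_db(ann)
    eff <- tibble::tibble(junction = jdb$junction[1], smoker_multiplier = 5)
    jx <- simulate_junction_reads(truth, ann, usage_effects = eff,
                                  depth = 1e6, seed = 900 + s)
    cnt <- count_junction_reads(jx$reads, jx$junctions)
    u <- cnt |>
      dplyr::left_join(truth$subjects, by = "subject") |>
      dplyr::left_join(truth$expr,
                       by = c("gene", "subject", "group")) |>
      dplyr::mutate(usage = junction_usage(count, effective_length, 1e6,
                                           true_rpkm)) |>
      dplyr::filter(junction == jdb$junction[1])
    p <- junction_test(u)$tests$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("estimated usage tracks true relative usage across junctions", {
  cfg <- sae_config(n_genes = 15, abundance_mu = 1.5, abundance_sigma = 0.3,
                    responsive_fraction = 0, depth = 5e6)
  ann <- make_annotation(cfg, seed = 70)
  truth <- simulate_expression(cfg, ann, seed = 70)
  jdb <- build_junction_db(ann)
  withr::local_seed(71)
  true_u <- tibble::tibble(junction = jdb$junction,
                           usage = 10^runif(nrow(jdb), -0.7, 0.7))
  jx <- simulate_junction_reads(truth, ann, usage = true_u, seed = 70)
  cnt <- count_junction_reads(jx$reads, jx$junctions)
  est <- cnt |>
    dplyr::left_join(truth$subjects, by = "subject") |>
    dplyr::left_join(truth$expr, by = c("gene", "subject", "group")) |>
    dplyr::mutate(usage = junction_usage(count, effective_length,
                                         cfg$depth, true_rpkm)) |>
    dplyr::group_by(junction) |>
    dplyr::summarise(u_hat = mean(usage))
  joined <- dplyr::inner_join(est, true_u, by = "junction")
  expect_gt(cor(joined$u_hat, joined$usage, method = "spearman"), 0.95)
})
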