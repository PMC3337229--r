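test_that("signed fold-change is a ratio with sign, magnitude at least one", {
  expect_equal(signed_fold_change(333.1, 3112.7), 3112.7 / 333.1)
  expect_equal(round(signed_fold_change(38675.4, 17244), 1), -2.2)
  expect_equal(signed_fold_change(5, 5), 1)
  ## antisymmetry and the magnitude floor
  withr::local_seed(51)
  a <- rlnorm(50, 2, 1); b <- rlnorm(50, 2, 1)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
  ## direction agrees with the absolute change
  expect_true(all(sign(signed_fold_change(a, b)) ==
                    sign(absolute_change(a, b)) |
                    absolute_change(a, b) == 0))
  expect_true(is.na(signed_fold_change(0, 5)))
})

test_that("absolute change is the smoker minus nonsmoker median", {
  expect_equal(absolute_change(333.1, 3112.7), 2779.6)
  expect_equal(absolute_change(226.9, 2077.9), 1851)
  expect_equal(absolute_change(7, 7), 0)
})

test_that("the bundled published-median table reproduces its printed columns", {
  rep <- replicate_smoking_table(smoking_top_genes())
  expect_true(all(rep$fc_matches))
  expect_true(all(rep$delta_matches))
  msmb <- rep[rep$gene == "MSMB", ]
  expect_equal(msmb$delta, 2779.6)
  expect_equal(msmb$fc, 9.3)
})

test_that("smoking_test matches the closed-form t distribution and handles ties", {
  vals <- toy_values(c("flat", "up"), ns_value = 10)
  vals["up", 6:11] <- c(14, 15, 16, 15, 14, 16)
  vals["flat", ] <- c(9, 10, 11, 10, 10, 9, 11, 10, 10, 9, 11)
  expr <- toy_expr(vals)
  out <- smoking_test(expr)
  ## pooled two-sample t computed from first principles
  x <- vals["up", 1:5]; y <- vals["up", 6:11]
  sp2 <- (4 * var(x) + 5 * var(y)) / 9
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 6))
  expect_equal(out$p_value[out$gene == "up"], 2 * pt(-abs(tstat), df = 9))
  expect_true(out$responsive[out$gene == "up"])
  ## identical constant groups: p = 1, not responsive
  const <- toy_expr(toy_values("c", ns_value = 3))
  expect_equal(smoking_test(const)$p_value, 1)
  expect_false(smoking_test(const)$responsive)
  ## Welch option changes the degrees of freedom
  welch <- smoking_test(expr, var_equal = FALSE)
  expect_equal(welch$p_value[welch$gene == "up"],
               t.test(x, y)$p.value)
  expect_error(smoking_test(dplyr::filter(expr, subject %in%
                                            c("NS01", "SM01", "SM02"))),
               "at least 2")
})

test_that("power rises with the injected effect size", {
  power_at <- function(fold) {
    cfg <- sae_config(n_genes = 300, responsive_fraction = 1,
                      effect_range = c(fold, fold))
    truth <- simulate_expression(cfg, seed = 77)
    expr <- dplyr::rename(truth$expr, rpkm = true_rpkm)
    mean(smoking_test(expr, threshold = 0)$responsive)
  }
  p <- vapply(c(1.1, 1.25, 1.5), power_at, 0)
  expect_true(all(diff(p) > 0))
  expect_gt(p[3], 0.5)
})

test_that("volcano table carries delta and -log10 p for every expressed gene", {
  withr::local_seed(52)
  vals <- toy_values(sprintf("g%02d", 1:20),
                     ns_value = rlnorm(20, 2, 1)) *
    matrix(rlnorm(20 * 11, 0, 0.2), nrow = 20)
  out <- smoking_test(toy_expr(vals))
  v <- volcano_table(out)
  expect_equal(nrow(v), nrow(out))
  expect_equal(v$delta, absolute_change(out$nonsmoker_median,
                                        out$smoker_median))
  p05 <- out[which.min(abs(out$p_value - 0.05)), ]
  expect_equal(p05$neg_log10_p, -log10(p05$p_value))
  expect_equal(round(-log10(0.05), 3), 1.301)
  expect_s3_class(autoplot(out), "ggplot")
})

test_that("responsiveness stratifies correctly over class and tier", {
  withr::local_seed(53)
  genes <- sprintf("g%02d", 1:60)
  base <- 10^runif(60, -0.8, 2.5)
  vals <- toy_values(genes, base) * matrix(rlnorm(660, 0, 0.25), nrow = 60)
  vals[1:10, 6:11] <- vals[1:10, 6:11] * 6   # strong smoker induction
  expr <- toy_expr(vals)
  rec <- smoking_test(expr)
  part <- classify_ubiquitous(expr_medians(expr) |>
                                dplyr::filter(nonsmoker_median > 0.125),
                              genes[seq(1, 60, 2)])
  rs <- responsive_by_stratum(rec, part)
  expect_true(all(rs$pct_responsive >= 0 & rs$pct_responsive <= 100))
  ## brute-force tally
  joined <- dplyr::inner_join(tibble::as_tibble(rec),
                              tibble::as_tibble(part)[, c("gene", "class", "tier")],
                              by = "gene")
  for (i in seq_len(nrow(rs))) {
    sel <- joined$class == rs$class[i] &
      as.character(joined$tier) == as.character(rs$tier[i])
    expect_equal(rs$n_responsive[i], sum(joined$responsive[sel]))
  }
  ## no responsive genes at all
  quiet <- toy_expr(toy_values(genes[1:4], c(1, 2, 3, 4)))
  rs0 <- responsive_by_stratum(smoking_test(quiet),
                               classify_ubiquitous(
                                 expr_medians(quiet), genes[1:2]))
  expect_true(all(rs0$pct_responsive == 0))
})

test_that("induced/repressed splits order genes by absolute change", {
  rec <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    nonsmoker_median = c(10, 10, 10, 10),
    smoker_median = c(2789.6, 110, 8, 5),
    delta = c(2779.6, 100, -2, -5),
    fold_change = c(278, 11, -1.2, -2),
    p_value = c(0.01, 0.01, 0.01, 0.2),
    neg_log10_p = -log10(c(0.01, 0.01, 0.01, 0.2)),
    responsive = c(TRUE, TRUE, TRUE, FALSE)
  )
  cmap <- tibble::tibble(gene = c("a", "b", "c", "d"), category = "transport")
  dd <- direction_by_category(rec, cmap)
  expect_equal(dd$gene[dd$direction == "induced"], c("a", "b"))
  expect_equal(dd$gene[dd$direction == "repressed"], "c")
  expect_equal(round(dd$log10_abs_delta[1], 3), 3.444)
  all_up <- direction_by_category(rec[1:2, ], cmap)
  expect_false("repressed" %in% all_up$direction)
})

test_that("fold-change concordance separates correlation from direction", {
  withr::local_seed(54)
  fc <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                       fold_change = c(rlnorm(5, 1, 0.5), -rlnorm(5, 1, 0.5)))
  same <- concordance(fc, fc)
  expect_equal(same$r_squared, 1)
  expect_equal(same$sign_agreement, 1)
  flip <- concordance(fc, dplyr::mutate(fc, fold_change = -fold_change))
  expect_equal(flip$r_squared, 1)
  expect_equal(flip$sign_agreement, 0)
  ## closed-form covariance oracle
  other <- dplyr::mutate(fc, fold_change = fold_change * 2 + rnorm(10))
  got <- concordance(fc, other)
  x <- fc$fold_change; y <- other$fold_change
  r2 <- (sum((x - mean(x)) * (y - mean(y))) /
           sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(got$r_squared, r2)
  expect_error(concordance(fc[1:2, ], fc[1:2, ]), "at least 3")
  expect_error(concordance(fc, dplyr::mutate(fc, fold_change = 1)),
               "variance")
})

test_that("glance summarises a differential result", {
  vals <- toy_values(c("a", "b"), c(1, 2), c(1, 2)) *
    matrix(rlnorm(22, 0, 0.1), nrow = 2)
  g <- glance(smoking_test(toy_expr(vals)))
  expect_equal(g$n_genes, 2)
  expect_equal(g$alpha, 0.05)
})
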