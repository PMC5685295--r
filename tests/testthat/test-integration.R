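delta_rec <- function(gene, d, target = "YST", basis = "TSS") {
  tibble::tibble(gene = gene, target_sample = target,
                 reference_sample = "SEM", region_basis = basis,
                 delta_beta = d)
}

fc_rec <- function(gene, fold, direction, target = "YST") {
  tibble::tibble(gene = gene, target_sample = target,
                 reference_sample = "SEM", fold_change = fold,
                 direction = direction)
}

test_that("delta-beta binning uses half-open 0.05 bins with a closed top", {
  d <- delta_rec(c("a", "b", "c", "d"), c(0.72, 0.05, 0, 1.0))
  binned <- bin_delta_beta(d)
  expect_equal(binned$bin_lo[binned$gene == "a"], 0.70)
  expect_equal(binned$bin_hi[binned$gene == "a"], 0.75)
  # boundary value goes to the bin it opens
  expect_equal(binned$bin_lo[binned$gene == "b"], 0.05)
  expect_equal(binned$bin_lo[binned$gene == "c"], 0)
  # delta of exactly 1 is assigned to the top bin
  expect_equal(binned$bin_lo[binned$gene == "d"], 0.95)
})

test_that("negative delta-beta records are excluded and reported separately", {
  d <- delta_rec(c("a", "b"), c(0.3, -0.4))
  binned <- bin_delta_beta(d)
  expect_equal(binned$gene, "a")
  neg <- attr(binned, "excluded_negative")
  expect_equal(neg$gene, "b")
  expect_error(bin_delta_beta(dplyr::bind_rows(
    delta_rec("a", 0.3, basis = "TSS"), delta_rec("b", 0.3, basis = "Body"))),
    "one comparison")
})

test_that("bin counts equal a brute-force recount on random deltas", {
  set.seed(31)
  d <- delta_rec(sprintf("g%04d", 1:1000), round(runif(1000, 0, 1), 3))
  binned <- bin_delta_beta(d)
  counts <- table(binned$bin_lo)
  oracle <- table(pmin(floor(d$delta_beta / 0.05), 19) * 0.05)
  expect_equal(as.vector(counts), as.vector(oracle))
  expect_equal(names(counts), names(oracle))
})

test_that("expected counts derive from marginals and conserve totals", {
  tbl <- load_table1_fixture()
  ct <- contingency_from_counts(tbl)
  # row sums of expected equal row totals; column sums equal column marginals
  exp_m <- as.matrix(ct[c("exp_correlating", "exp_no_difference",
                          "exp_anticorrelating")])
  expect_equal(rowSums(exp_m), as.numeric(ct$total), tolerance = 1e-9)
  expect_equal(unname(colSums(exp_m)), c(772, 2953, 402), tolerance = 1e-9)
  expect_equal(sum(ct$total), 4127)
})

test_that("a single-bin table is degenerate: expected = observed, chi2 = 0", {
  one <- tibble::tibble(bin_lo = 0, bin_hi = 0.05, obs_correlating = 7L,
                        obs_no_difference = 11L, obs_anticorrelating = 2L)
  ct <- contingency_from_counts(one)
  expect_equal(ct$exp_correlating, 7)
  expect_equal(ct$exp_no_difference, 11)
  expect_equal(ct$chi2, 0)
  expect_equal(ct$p_value, 1)
})

test_that("two-df chi-square p matches the closed form exp(-x/2)", {
  tbl <- load_table1_fixture()
  ct <- contingency_from_counts(tbl)
  expect_equal(ct$p_value, exp(-ct$chi2 / 2), tolerance = 1e-12)
})

test_that("empty bins are retained with zero counts, never dropped", {
  d <- delta_rec(c("a", "b"), c(0.02, 0.31))
  fc <- fc_rec(c("a", "b"), c(3, 3), rep("higher_in_reference", 2))
  ct <- contingency_table(bin_delta_beta(d), fc)
  expect_equal(nrow(ct), 7) # bins 0 through 0.30-0.35
  mid <- ct[ct$bin_lo == 0.15, ]
  expect_equal(mid$total, 0L)
  expect_true(is.na(mid$p_value))
  expect_equal(mid$stars, "")
})

test_that("contingency assembly from records matches a hand-built count", {
  d <- delta_rec(sprintf("g%d", 1:6), c(0.01, 0.03, 0.02, 0.71, 0.72, 0.74))
  fc <- fc_rec(sprintf("g%d", 1:6), c(1, 1.5, 2.5, 4, 1, 2.2),
               c("no_difference", "no_difference", "higher_in_target",
                 "higher_in_reference", "no_difference",
                 "higher_in_reference"))
  ct <- contingency_table(bin_delta_beta(d), fc)
  lo <- ct[ct$bin_lo == 0, ]
  expect_equal(c(lo$obs_correlating, lo$obs_no_difference,
                 lo$obs_anticorrelating), c(0L, 2L, 1L))
  hi <- ct[ct$bin_lo == 0.7, ]
  expect_equal(c(hi$obs_correlating, hi$obs_no_difference,
                 hi$obs_anticorrelating), c(2L, 1L, 0L))
  # genes without an expression record cannot enter the table
  ct2 <- contingency_table(bin_delta_beta(d), fc[-1, ])
  expect_equal(sum(ct2$total), 5)
})

test_that("threshold selection finds the lowest qualifying bin", {
  ct <- contingency_from_counts(load_table1_fixture())
  thr <- select_threshold(ct)
  expect_equal(thr$selected_cut, 0.65)
  # removing the 0.65-0.70 row pushes the selection to 0.70
  thr2 <- select_threshold(contingency_from_counts(
    load_table1_fixture()[-14, ]))
  expect_equal(thr2$selected_cut, 0.70)
  # constructed table where only one middle bin qualifies
  mid <- tibble::tibble(
    bin_lo = seq(0, 0.30, by = 0.05), bin_hi = bin_lo + 0.05,
    obs_correlating = c(10L, 10L, 10L, 10L, 10L, 10L, 60L),
    obs_no_difference = c(90L, 90L, 90L, 90L, 90L, 90L, 40L),
    obs_anticorrelating = 0L
  )
  thr3 <- select_threshold(contingency_from_counts(mid))
  expect_equal(thr3$selected_cut, 0.30)
  expect_equal(sum(tidy(thr3)$qualifies), 1)
})

test_that("threshold selection reports no qualifying bin when none exists", {
  flat <- tibble::tibble(
    bin_lo = seq(0, 0.2, by = 0.05), bin_hi = bin_lo + 0.05,
    obs_correlating = 10L, obs_no_difference = 90L,
    obs_anticorrelating = 10L
  )
  thr <- select_threshold(contingency_from_counts(flat))
  expect_true(is.na(thr$selected_cut))
  expect_false(any(thr$bins$qualifies))
})

test_that("silenced-gene classification joins methylation and expression rules", {
  d <- dplyr::bind_rows(
    delta_rec("tss_hit", 0.8),
    delta_rec("body_hit", 0.5),
    delta_rec("body_hit", 0.7, basis = "Body"),
    delta_rec("weak_fold", 0.8),
    delta_rec("no_tss", 0.9, basis = "Body")
  )
  fc <- fc_rec(c("tss_hit", "body_hit", "weak_fold", "no_tss"),
               c(3, 4, 1.8, 2.5),
               c("higher_in_reference", "higher_in_reference",
                 "no_difference", "higher_in_reference"))
  calls <- classify_silenced(d, fc, cut = 0.65)
  expect_setequal(calls$gene, c("tss_hit", "body_hit", "no_tss"))
  expect_equal(calls$region_basis[calls$gene == "tss_hit"], "TSS")
  expect_false(calls$body_only[calls$gene == "tss_hit"])
  # body island above the cut while the TSS island is below it
  expect_equal(calls$region_basis[calls$gene == "body_hit"], "Body")
  expect_true(calls$body_only[calls$gene == "body_hit"])
  # no TSS island at all: body_only as well
  expect_true(calls$body_only[calls$gene == "no_tss"])
  # below 2-fold expression difference: no call despite high delta-beta
  expect_false("weak_fold" %in% calls$gene)
  # no cut selected -> empty call set
  expect_equal(nrow(classify_silenced(d, fc, cut = NA_real_)), 0)
})

test_that("raising the cut never adds silenced-gene calls", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:200)
  d <- delta_rec(genes, runif(200, 0, 1))
  dirs <- sample(c("higher_in_reference", "no_difference",
                   "higher_in_target"), 200, replace = TRUE)
  folds <- ifelse(dirs == "no_difference", runif(200, 1, 2),
                  runif(200, 2, 10))
  fc <- fc_rec(genes, folds, dirs)
  cuts <- seq(0.2, 0.9, by = 0.05)
  calls <- lapply(cuts, function(ct) classify_silenced(d, fc, ct)$gene)
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(calls[[i]] %in% calls[[i - 1]]))
  }
})

test_that("Venn region counts are exact set algebra", {
  v <- methylation_venn(list(X = c("A", "B"), Y = c("B", "C")))
  expect_equal(sum(v$count), 3)
  expect_equal(v$count[v$region == "X&Y"], 1L)
  expect_equal(v$count[v$region == "X"], 1L)
  expect_equal(v$count[v$region == "Y"], 1L)

  same <- methylation_venn(list(a = c("g1", "g2"), b = c("g1", "g2")))
  expect_equal(same$count[same$region == "a&b"], 2L)
  expect_equal(sum(same$count), 2)

  # four random sets against brute-force membership tabulation
  set.seed(12)
  sets <- lapply(1:4, function(i) sample(sprintf("g%02d", 1:40),
                                         sample(5:30, 1)))
  names(sets) <- c("w", "x", "y", "z")
  v4 <- methylation_venn(sets)
  expect_equal(nrow(v4), 15)
  universe <- unique(unlist(sets))
  expect_equal(sum(v4$count), length(universe))
  for (r in seq_len(nrow(v4))) {
    inside <- names(sets)[unlist(v4[r, names(sets)])]
    outside <- setdiff(names(sets), inside)
    n_oracle <- sum(vapply(universe, function(g) {
      all(vapply(inside, function(s) g %in% sets[[s]], logical(1))) &&
        !any(vapply(outside, function(s) g %in% sets[[s]], logical(1)))
    }, logical(1)))
    expect_equal(v4$count[r], n_oracle)
  }
})
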