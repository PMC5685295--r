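test_that("qc_filter applies detection-p, intensity and mapping rules at the stated boundaries", {
  manifest <- make_manifest()
  beta <- make_beta(list(s1 = rep(0.5, 10), s2 = rep(0.5, 10)))
  detp <- make_detp(c("s1", "s2"))
  # probe 1: detection p (0.04, 0.08), mean 0.06 -> removed
  detp$s1[1] <- 0.04; detp$s2[1] <- 0.08
  # probe 2: mean exactly 0.05 -> retained (rule is "> 0.05")
  detp$s1[2] <- 0.05; detp$s2[2] <- 0.05
  intensity <- tibble::tibble(
    probe_id = sprintf("cg%02d", 1:10),
    red = c(12, 12, 11.0, 11.1, rep(12, 6)), # probe 3 removed, 4 retained
    green = rep(12, 10)
  )
  res <- qc_filter(beta, detp, manifest, intensity = intensity)
  kept <- res$beta$probe_id
  expect_false("cg01" %in% kept) # mean detp 0.06
  expect_true("cg02" %in% kept)  # boundary detp
  expect_false("cg03" %in% kept) # intensity 11.0
  expect_true("cg04" %in% kept)  # intensity 11.1 boundary
  expect_false("cg09" %in% kept) # multi-gene
  expect_false("cg10" %in% kept) # multi-site (chr-MULTI)
  r <- res$report
  expect_equal(r$n_removed_detection_p, 1)
  expect_equal(r$n_removed_intensity, 1)
  expect_equal(r$n_removed_multi_site, 1)
  expect_equal(r$n_removed_multi_gene, 1)
  expect_equal(r$n_probes_out,
               r$n_probes_in - r$n_removed_detection_p -
                 r$n_removed_intensity - r$n_removed_multi_site -
                 r$n_removed_multi_gene)
})

test_that("qc_filter flags but keeps samples with poor bisulfite conversion", {
  manifest <- make_manifest()
  beta <- make_beta(list(s1 = rep(0.5, 10), s2 = rep(0.5, 10)))
  res <- qc_filter(beta, make_detp(c("s1", "s2")), manifest,
                   conversion_ratio = c(s1 = 0.1, s2 = 0.25))
  expect_equal(res$report$flagged_samples, "s2")
  expect_true(all(c("s1", "s2") %in% names(res$beta)))
  # boundary: ratio exactly 0.2 is flagged (rule "< 0.2" is good)
  res2 <- qc_filter(beta, make_detp(c("s1", "s2")), manifest,
                    conversion_ratio = c(s1 = 0.2, s2 = 0.19))
  expect_equal(res2$report$flagged_samples, "s1")
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  manifest <- make_manifest()
  beta <- make_beta(list(s1 = rep(0.5, 10)))
  detp <- make_detp("s1")
  detp$s1[c(1, 5)] <- 0.5
  once <- qc_filter(beta, detp, manifest)
  twice <- qc_filter(once$beta, detp, manifest)
  expect_identical(once$beta, twice$beta)
  expect_equal(twice$report$n_removed_detection_p, 0)

  detp_all <- make_detp("s1", p = 0.9)
  expect_error(qc_filter(beta, detp_all, manifest), "every probe")
})

test_that("island relation annotation follows strand-aware distance bands", {
  islands <- data.frame(start = 10000, end = 11000)
  expect_equal(annotate_island_relation(10500, "+", islands), "Island")
  expect_equal(annotate_island_relation(10000, "+", islands), "Island")
  # 1,500 bp left of the island start, gene on + strand -> north shore
  expect_equal(annotate_island_relation(8500, "+", islands), "N_Shore")
  expect_equal(annotate_island_relation(8500, "-", islands), "S_Shore")
  # 3,000 bp right of the island end: shelf, north only on the - strand
  expect_equal(annotate_island_relation(14000, "+", islands), "S_Shelf")
  expect_equal(annotate_island_relation(14000, "-", islands), "N_Shelf")
  # band boundaries are half open: 2,000 goes to the shore, 4,000 to the shelf
  expect_equal(annotate_island_relation(8000, "+", islands), "N_Shore")
  expect_equal(annotate_island_relation(6000, "+", islands), "N_Shelf")
  expect_equal(annotate_island_relation(5999, "+", islands), "OpenSea")
  expect_equal(annotate_island_relation(123, "+", NULL), "OpenSea")
})

test_that("island relation annotation matches a brute-force nearest-edge check", {
  set.seed(42)
  islands <- data.frame(start = c(5000, 20000, 40000),
                        end = c(6000, 22000, 40400))
  pos <- sample(1:50000, 1000)
  strand <- sample(c("+", "-"), 1000, replace = TRUE)
  got <- annotate_island_relation(pos, strand, islands)
  oracle <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    if (any(p >= islands$start & p <= islands$end)) return("Island")
    d_each <- pmin(abs(p - islands$start), abs(p - islands$end))
    j <- which.min(d_each)
    d <- d_each[j]
    if (d > 4000) return("OpenSea")
    left <- p < islands$start[j]
    north <- if (strand[i] == "+") left else !left
    paste0(if (north) "N_" else "S_", if (d <= 2000) "Shore" else "Shelf")
  }, character(1))
  expect_equal(got, oracle)
})

test_that("region summary classifies probes at the 0.6 and 0.3 boundaries", {
  manifest <- make_manifest()
  # 10 probes: 4 at/above 0.6, 3 below 0.3, 3 intermediate
  beta <- make_beta(list(
    s1 = c(0.9, 0.8, 0.7, 0.6, 0.3, 0.45, 0.5, 0.29, 0.1, 0.0)))
  manifest$island_relation <- "Island" # one class to keep the count simple
  s <- region_methylation_summary(beta, manifest)
  expect_equal(s$f_methylated, 0.4)
  expect_equal(s$f_unmethylated, 0.3)
  expect_equal(s$f_intermediate, 0.3)
  expect_equal(s$f_methylated + s$f_intermediate + s$f_unmethylated, 1)

  all_high <- make_beta(list(s1 = rep(0.9, 10)))
  expect_equal(region_methylation_summary(all_high, manifest)$f_methylated, 1)
})

test_that("gene island aggregation pools CpGs across islands and skips open sea", {
  manifest <- make_manifest()
  beta <- make_beta(list(s1 = c(0.7, 0.8, 0.9, 0.5, 0.99,
                                0.2, 0.4, 0.6, 0.5, 0.5)))
  prof <- gene_island_beta(beta, manifest)
  a <- prof[prof$gene == "A" & prof$sample == "s1", ]
  expect_equal(a$tss_island_mean_beta, 0.8) # mean(0.7, 0.8, 0.9)
  expect_equal(a$tss_island_cpg_count, 3L)
  expect_equal(a$body_island_mean_beta, 0.5)
  expect_equal(a$body_island_cpg_count, 1L)

  # a gene with two TSS islands of 2 and 4 probes: pooled mean over all 6
  # CpGs, not the mean of per-island means
  m2 <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6),
    gene_symbol = "G", chrom = "chr1",
    pos = c(100L, 140L, 5000L, 5040L, 5080L, 5120L),
    gene_region = c("TSS1500", "TSS1500", "TSS200", "TSS200", "UTR5",
                    "FirstExon"),
    island_relation = "Island",
    island_id = c("I1", "I1", "I2", "I2", "I2", "I2"),
    gene_symbols = as.list(rep("G", 6)), multi_gene = FALSE
  )
  b2 <- tibble::tibble(probe_id = sprintf("p%d", 1:6),
                       s1 = c(0.1, 0.2, 0.8, 0.8, 0.8, 0.8))
  pooled <- gene_island_beta(b2, m2)
  expect_equal(pooled$tss_island_mean_beta, mean(b2$s1))
  island_wise <- mean(c(mean(c(0.1, 0.2)), mean(rep(0.8, 4))))
  expect_false(isTRUE(all.equal(pooled$tss_island_mean_beta, island_wise)))

  # missing betas are omitted from the mean, not treated as zero
  b3 <- b2
  b3$s1[1] <- NA
  prof3 <- gene_island_beta(b3, m2)
  expect_equal(prof3$tss_island_mean_beta, mean(b2$s1[-1]))
  expect_equal(prof3$tss_island_cpg_count, 5L)
})

test_that("genes with only open-sea probes get missing aggregates", {
  m <- tibble::tibble(
    probe_id = c("p1", "p2"), gene_symbol = "G", chrom = "chr1",
    pos = c(100L, 200L), gene_region = "Intergenic",
    island_relation = "OpenSea", island_id = NA_character_,
    gene_symbols = as.list(rep("G", 2)), multi_gene = FALSE
  )
  b <- tibble::tibble(probe_id = c("p1", "p2"), s1 = c(0.5, 0.6))
  prof <- gene_island_beta(b, m)
  expect_equal(nrow(prof), 0) # no island probes at all -> no profile rows
})

test_that("aggregate means stay within the range of contributing probe betas", {
  cfg <- sim_config(n_genes = 50, seed = 13)
  sim <- simulate_methylome(cfg)
  prof <- gene_island_beta(sim$beta, sim$manifest)
  long <- sim$beta |>
    tidyr::pivot_longer(-probe_id, names_to = "sample", values_to = "beta") |>
    dplyr::inner_join(
      sim$manifest |>
        dplyr::filter(island_relation == "Island",
                      gene_region %in% c("TSS1500", "TSS200", "UTR5",
                                         "FirstExon")) |>
        dplyr::transmute(probe_id, gene = gene_symbol),
      by = "probe_id") |>
    dplyr::group_by(gene, sample) |>
    dplyr::summarise(lo = min(beta), hi = max(beta), .groups = "drop")
  chk <- prof |>
    dplyr::inner_join(long, by = c("gene", "sample")) |>
    dplyr::filter(!is.na(tss_island_mean_beta))
  expect_true(all(chk$tss_island_mean_beta >= chk$lo - 1e-12 &
                    chk$tss_island_mean_beta <= chk$hi + 1e-12))
})

test_that("methylation calls use an inclusive 0.6 boundary", {
  prof <- tibble::tibble(
    gene = c("A", "B", "C", "D"), sample = "s1",
    tss_island_mean_beta = c(0.8, 0.59, 0.60, NA),
    tss_island_cpg_count = c(3L, 3L, 3L, 0L),
    body_island_mean_beta = NA_real_, body_island_cpg_count = 0L
  )
  calls <- call_methylated(prof)
  expect_equal(calls$tss_methylated, c(TRUE, FALSE, TRUE, NA))
})

test_that("delta beta is target minus reference and keeps negative values", {
  prof <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 2),
    sample = rep(c("ref", "tgt"), 3),
    tss_island_mean_beta = c(0.1, 0.9, 0.5, 0.5, 0.9, 0.1),
    tss_island_cpg_count = 3L,
    body_island_mean_beta = NA_real_, body_island_cpg_count = 0L
  )
  d <- delta_beta(prof, "ref")
  expect_equal(nrow(d), 3)
  expect_equal(d$delta_beta[d$gene == "A"], 0.8)
  expect_equal(d$delta_beta[d$gene == "B"], 0)
  expect_equal(d$delta_beta[d$gene == "C"], -0.8)
  expect_true(all(d$region_basis == "TSS"))
  expect_error(delta_beta(prof, "missing"), "not found")
})
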