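#' Probe-level quality control of a beta-value matrix
#'
#' Removes probes whose mean detection p-value across samples exceeds
#' `detp_threshold`, probes whose averaged log2 signal intensity falls below
#' `log2_intensity_min` in either channel, probes mapping to multiple
#' genomic sites, and probes annotated to multiple genes. Samples whose
#' bisulfite conversion ratio is at or above `conversion_ratio_max` are
#' flagged in the report but never removed.
#'
#' Boundary conventions follow the filtering rules exactly: a probe is
#' removed when its mean detection p is strictly greater than the
#' threshold, and when its log2 intensity is strictly less than the
#' minimum; probes sitting exactly on either boundary are retained.
#'
#' @param beta Tibble from [read_matrix()] (`probe_id` + one column per
#'   sample of beta values).
#' @param detp Parallel detection-p tibble (same probes and samples).
#' @param manifest Manifest tibble from [read_manifest()]. Probes whose
#'   `chrom` is `"chr-MULTI"` (or `"MULTI"`) are treated as multi-site.
#' @param intensity Optional tibble of per-probe averaged log2 signal
#'   intensities: `probe_id` plus one or more channel columns (for
#'   two-colour data typically `red` and `green`). A probe failing the
#'   cutoff in any channel is removed.
#' @param conversion_ratio Optional named numeric vector of per-sample
#'   bisulfite conversion ratios (unmethylated/methylated control probe
#'   ratio).
#' @param detp_threshold Removal threshold on the mean detection p
#'   (default 0.05).
#' @param log2_intensity_min Minimum acceptable averaged log2 intensity
#'   (default 11.1).
#' @param conversion_ratio_max Conversion ratio at or above which a sample
#'   is flagged (default 0.2).
#' @return An object of class `qc_result`: a list with `beta` (the filtered
#'   tibble) and `report` (counts of probes removed per rule and per-sample
#'   conversion flags). Supports [tidy()] and [glance()].
#' @export
qc_filter <- function(beta, detp, manifest, intensity = NULL,
                      conversion_ratio = NULL,
                      detp_threshold = 0.05, log2_intensity_min = 11.1,
                      conversion_ratio_max = 0.2) {
  samples <- setdiff(names(beta), "probe_id")
  if (!identical(sort(names(detp)), sort(names(beta)))) {
    abort("detection-p table must have the same columns as the beta table")
  }
  detp <- detp[match(beta$probe_id, detp$probe_id), names(beta)]
  if (anyNA(detp$probe_id)) {
    abort("detection-p table must cover every probe in the beta table")
  }

  n_in <- nrow(beta)
  keep <- rep(TRUE, n_in)

  mean_detp <- rowMeans(as.matrix(detp[samples]), na.rm = TRUE)
  fail_detp <- keep & mean_detp > detp_threshold
  keep <- keep & !fail_detp

  fail_int <- rep(FALSE, n_in)
  if (!is.null(intensity)) {
    ch <- setdiff(names(intensity), "probe_id")
    m <- as.matrix(intensity[ch])
    low <- apply(m < log2_intensity_min, 1, any, na.rm = TRUE)
    low_ids <- intensity$probe_id[low]
    fail_int <- keep & beta$probe_id %in% low_ids
    keep <- keep & !fail_int
  }

  multi_site_ids <- manifest$probe_id[manifest$chrom %in%
                                        c("chr-MULTI", "MULTI")]
  fail_site <- keep & beta$probe_id %in% multi_site_ids
  keep <- keep & !fail_site

  multi_gene_ids <- manifest$probe_id[manifest$multi_gene]
  fail_gene <- keep & beta$probe_id %in% multi_gene_ids
  keep <- keep & !fail_gene

  if (!any(keep)) abort("quality control removed every probe")

  flagged <- character(0)
  conv <- NULL
  if (!is.null(conversion_ratio)) {
    conv <- tibble(sample = names(conversion_ratio),
                   conversion_ratio = unname(conversion_ratio),
                   flagged = unname(conversion_ratio) >= conversion_ratio_max)
    flagged <- conv$sample[conv$flagged]
  }

  report <- list(
    n_probes_in = n_in,
    n_removed_detection_p = sum(fail_detp),
    n_removed_intensity = sum(fail_int),
    n_removed_multi_site = sum(fail_site),
    n_removed_multi_gene = sum(fail_gene),
    n_probes_out = sum(keep),
    conversion = conv,
    flagged_samples = flagged
  )
  structure(list(beta = beta[keep, ], report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("Probe QC:", r$n_probes_in, "probes in,", r$n_probes_out, "retained\n")
  cat("  removed: detection p >", "threshold:", r$n_removed_detection_p,
      "| low intensity:", r$n_removed_intensity,
      "| multi-site:", r$n_removed_multi_site,
      "| multi-gene:", r$n_removed_multi_gene, "\n")
  if (length(r$flagged_samples) > 0) {
    cat("  samples flagged for poor bisulfite conversion:",
        paste(r$flagged_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate positions relative to CpG islands
#'
#' Classifies genomic positions as island, shore, shelf or open sea by
#' distance to the nearest island edge: inside an island, within 2,000 bp
#' (shore), within 2,000-4,000 bp (shelf), further away (open sea). Shores
#' and shelves are labelled north (5' of the associated gene) or south (3'):
#' for a gene on the + strand the north side is the lower-coordinate side,
#' for the - strand the higher-coordinate side. Distance bands are half
#' open, so a position exactly 2,000 bp from an island edge is a shore and
#' exactly 4,000 bp a shelf.
#'
#' @param pos Integer vector of 1-based positions.
#' @param strand `"+"` or `"-"` (length 1 or same length as `pos`): the
#'   strand of the associated gene.
#' @param islands Data frame with columns `start`, `end` (1-based
#'   inclusive), non-overlapping once merged.
#' @return Character vector of island-relation labels.
#' @export
annotate_island_relation <- function(pos, strand, islands) {
  if (length(strand) == 1) strand <- rep(strand, length(pos))
  stopifnot(length(strand) == length(pos), all(strand %in% c("+", "-")))
  if (is.null(islands) || nrow(islands) == 0) {
    return(rep("OpenSea", length(pos)))
  }
  starts <- islands$start
  ends <- islands$end
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    inside <- any(p >= starts & p <= ends)
    if (inside) return("Island")
    # signed distance to nearest edge: negative when 5' (left) of an island
    d_left <- starts - p   # > 0 when probe is left of this island
    d_right <- p - ends    # > 0 when probe is right of this island
    d <- pmax(d_left, d_right)
    j <- which.min(d)
    dist <- d[j]
    if (dist > 4000) return("OpenSea")
    side_left <- d_left[j] > 0 # probe lies on the lower-coordinate side
    upstream <- if (strand[i] == "+") side_left else !side_left
    band <- if (dist <= 2000) "Shore" else "Shelf"
    paste0(if (upstream) "N_" else "S_", band)
  }, character(1))
}

#' Region-wise methylation summary
#'
#' Tabulates, per sample and island-relation class, the fraction of probes
#' called methylated (beta >= `meth_cut`), unmethylated (beta <
#' `unmeth_cut`) or intermediate.
#'
#' @param beta Beta tibble (`probe_id` + sample columns).
#' @param manifest Manifest tibble.
#' @param meth_cut Beta at or above which a CpG is methylated (default 0.6).
#' @param unmeth_cut Beta below which a CpG is unmethylated (default 0.3).
#' @return Tibble with columns `sample`, `island_relation`, `n_probes`,
#'   `f_methylated`, `f_intermediate`, `f_unmethylated`; the three
#'   fractions sum to 1 within each row.
#' @export
region_methylation_summary <- function(beta, manifest, meth_cut = 0.6,
                                       unmeth_cut = 0.3) {
  stopifnot(unmeth_cut <= meth_cut)
  beta |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample",
                        values_to = "beta") |>
    filter(!is.na(.data$beta)) |>
    inner_join(manifest |> select("probe_id", "island_relation"),
               by = "probe_id") |>
    group_by(.data$sample, .data$island_relation) |>
    summarise(
      n_probes = n(),
      f_methylated = mean(.data$beta >= meth_cut),
      f_unmethylated = mean(.data$beta < unmeth_cut),
      f_intermediate = 1 - .data$f_methylated - .data$f_unmethylated,
      .groups = "drop"
    ) |>
    select("sample", "island_relation", "n_probes", "f_methylated",
           "f_intermediate", "f_unmethylated")
}

#' Gene-level CpG-island methylation profiles
#'
#' Aggregates island-probe beta values to one mean per gene, sample and
#' region basis. The TSS-associated aggregate pools every island probe
#' annotated within 1,500 bp upstream of the TSS or in the 5' UTR / first
#' exon (gene regions TSS1500, TSS200, UTR5, FirstExon); the body aggregate
#' pools island probes in the gene body. Genes with several islands are
#' pooled CpG-wise, not averaged island-wise. Multi-gene probes and missing
#' beta values are excluded; a gene with no qualifying probes for a basis
#' gets a missing aggregate and a CpG count of zero.
#'
#' @param beta QC-passed beta tibble.
#' @param manifest Manifest tibble.
#' @return Tibble with columns `gene`, `sample`, `tss_island_mean_beta`,
#'   `tss_island_cpg_count`, `body_island_mean_beta`,
#'   `body_island_cpg_count`.
#' @export
gene_island_beta <- function(beta, manifest) {
  probes <- manifest_gene_probes(manifest) |>
    filter(.data$island_relation == "Island") |>
    mutate(region_basis = dplyr::case_when(
      .data$gene_region %in% TSS_REGIONS ~ "TSS",
      .data$gene_region == "Body" ~ "Body",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$region_basis)) |>
    select("probe_id", "gene", "region_basis")

  long <- beta |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample",
                        values_to = "beta") |>
    inner_join(probes, by = "probe_id",
               relationship = "many-to-many") |>
    filter(!is.na(.data$beta))

  agg <- long |>
    group_by(.data$gene, .data$sample, .data$region_basis) |>
    summarise(mean_beta = mean(.data$beta), cpg_count = n(),
              .groups = "drop")

  wide <- agg |>
    tidyr::pivot_wider(names_from = "region_basis",
                       values_from = c("mean_beta", "cpg_count"))
  for (nm in c("mean_beta_TSS", "mean_beta_Body")) {
    if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  }
  for (nm in c("cpg_count_TSS", "cpg_count_Body")) {
    if (!nm %in% names(wide)) wide[[nm]] <- NA_integer_
  }

  genes <- unique(probes$gene)
  samples <- setdiff(names(beta), "probe_id")
  tidyr::expand_grid(gene = genes, sample = samples) |>
    left_join(wide, by = c("gene", "sample")) |>
    transmute(
      gene = .data$gene, sample = .data$sample,
      tss_island_mean_beta = .data$mean_beta_TSS,
      tss_island_cpg_count = as.integer(tidyr::replace_na(
        .data$cpg_count_TSS, 0L)),
      body_island_mean_beta = .data$mean_beta_Body,
      body_island_cpg_count = as.integer(tidyr::replace_na(
        .data$cpg_count_Body, 0L))
    )
}

#' Call genes methylated from island-mean beta
#'
#' A gene is called methylated, per region basis, when its island-mean beta
#' is at or above `cut`. Genes with a missing aggregate get no call (`NA`).
#'
#' @param profiles Tibble from [gene_island_beta()].
#' @param cut Methylation call boundary on the island-mean beta
#'   (default 0.6, inclusive).
#' @return `profiles` with logical columns `tss_methylated` and
#'   `body_methylated` added.
#' @export
call_methylated <- function(profiles, cut = 0.6) {
  profiles |>
    mutate(
      tss_methylated = .data$tss_island_mean_beta >= cut,
      body_methylated = .data$body_island_mean_beta >= cut
    )
}

#' Differential methylation relative to a reference sample
#'
#' Computes, for every gene, non-reference sample and region basis with
#' both aggregates present, the difference in island-mean beta between the
#' target and the reference (hypomethylated) sample. Positive values mean
#' the target is more methylated; negative values are retained.
#'
#' @param profiles Tibble from [gene_island_beta()].
#' @param reference_sample Name of the reference sample.
#' @return Tibble with columns `gene`, `target_sample`, `reference_sample`,
#'   `region_basis` (`"TSS"` or `"Body"`) and `delta_beta` in \[-1, 1\].
#' @export
delta_beta <- function(profiles, reference_sample) {
  if (!reference_sample %in% profiles$sample) {
    abort(paste0("reference sample '", reference_sample,
                 "' not found in profiles"))
  }
  long <- profiles |>
    tidyr::pivot_longer(
      c("tss_island_mean_beta", "body_island_mean_beta"),
      names_to = "region_basis", values_to = "mean_beta"
    ) |>
    mutate(region_basis = ifelse(
      .data$region_basis == "tss_island_mean_beta", "TSS", "Body")) |>
    filter(!is.na(.data$mean_beta))
  ref <- long |>
    filter(.data$sample == reference_sample) |>
    select("gene", "region_basis", ref_beta = "mean_beta")
  long |>
    filter(.data$sample != reference_sample) |>
    inner_join(ref, by = c("gene", "region_basis")) |>
    transmute(
      gene = .data$gene,
      target_sample = .data$sample,
      reference_sample = reference_sample,
      region_basis = .data$region_basis,
      delta_beta = .data$mean_beta - .data$ref_beta
    )
}
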