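#' Run the full methylation-silencing analysis
#'
#' Chains the whole pipeline: probe QC, gene-level island methylation
#' profiles, delta-beta against the reference sample, background filtering
#' and fold changes on the expression side, per-target contingency tables
#' of TSS-island delta-beta bins against expression categories, data-driven
#' threshold selection, and silenced-gene classification on both the TSS
#' and body bases at each target's selected cutoff.
#'
#' @param manifest Manifest tibble ([read_manifest()]).
#' @param beta,detp Probes x samples beta and detection-p tibbles.
#' @param expr Genes x samples expression tibble.
#' @param reference_sample The hypomethylated reference sample, present in
#'   both matrices.
#' @param intensity,conversion_ratio Optional QC inputs, see [qc_filter()].
#' @param background Expression background threshold(s), see
#'   [background_filter()].
#' @param de_cut Fold-change cutoff for differential expression
#'   (default 2).
#' @param bin_width Delta-beta bin width (default 0.05).
#' @param ratio_min,alpha Threshold-selection rule parameters, see
#'   [select_threshold()].
#' @param cut Optional fixed delta-beta cutoff; when `NULL` (default) each
#'   target uses its own selected threshold.
#' @return A `silencing_analysis` list: `qc`, `profiles`, `delta`,
#'   `fold_changes`, `contingency` (named list per target), `thresholds`
#'   (named list per target), and `silenced` (one tibble over all
#'   targets). Supports [glance()].
#' @export
silencing_pipeline <- function(manifest, beta, detp, expr, reference_sample,
                               intensity = NULL, conversion_ratio = NULL,
                               background = 0, de_cut = 2.0,
                               bin_width = 0.05, ratio_min = 2.0,
                               alpha = 0.05, cut = NULL) {
  qc <- qc_filter(beta, detp, manifest, intensity = intensity,
                  conversion_ratio = conversion_ratio)
  profiles <- gene_island_beta(qc$beta, manifest)
  delta <- delta_beta(profiles, reference_sample)
  expr_f <- background_filter(expr, background)
  fc <- fold_changes(expr_f, reference_sample, de_cut = de_cut)

  targets <- setdiff(setdiff(names(beta), "probe_id"), reference_sample)
  contingency <- list()
  thresholds <- list()
  silenced <- list()
  for (tg in targets) {
    d_t <- delta |> filter(.data$target_sample == tg)
    binned <- bin_delta_beta(d_t |> filter(.data$region_basis == "TSS"),
                             width = bin_width)
    ct <- contingency_table(binned, fc)
    thr <- select_threshold(ct, ratio_min = ratio_min, alpha = alpha)
    use_cut <- cut %||% thr$selected_cut
    contingency[[tg]] <- ct
    thresholds[[tg]] <- thr
    silenced[[tg]] <- classify_silenced(d_t, fc, cut = use_cut,
                                        de_cut = de_cut)
  }
  structure(list(
    qc = qc,
    profiles = profiles,
    delta = delta,
    fold_changes = fc,
    contingency = contingency,
    thresholds = thresholds,
    silenced = bind_rows(silenced)
  ), class = "silencing_analysis")
}

#' @export
print.silencing_analysis <- function(x, ...) {
  cat("Methylation-silencing analysis\n")
  cat("  probes retained after QC:", x$qc$report$n_probes_out, "of",
      x$qc$report$n_probes_in, "\n")
  for (tg in names(x$thresholds)) {
    cutv <- x$thresholds[[tg]]$selected_cut
    n_calls <- sum(x$silenced$target_sample == tg)
    cat(sprintf("  %s: delta-beta cutoff %s, %d silenced-gene calls\n",
                tg, ifelse(is.na(cutv), "none", format(cutv)), n_calls))
  }
  invisible(x)
}

#' Compare planted truth with recovered silenced-gene calls
#'
#' Summarises how well a pipeline run on synthetic data recovered the
#' planted silenced genes: sensitivity (recovered fraction of planted
#' genes) and false-discovery proportion (called genes not planted).
#'
#' @param calls Silenced-gene tibble (one target sample, or pooled).
#' @param truth Truth tibble from [simulate_methylome()].
#' @return One-row tibble: `n_true`, `n_called`, `n_recovered`,
#'   `sensitivity`, `fdp`.
#' @export
recovery_summary <- function(calls, truth) {
  true_genes <- truth$gene[truth$silenced]
  called <- unique(calls$gene)
  n_rec <- length(intersect(called, true_genes))
  tibble(
    n_true = length(true_genes),
    n_called = length(called),
    n_recovered = n_rec,
    sensitivity = ifelse(length(true_genes) == 0, NA_real_,
                         n_rec / length(true_genes)),
    fdp = ifelse(length(called) == 0, 0,
                 (length(called) - n_rec) / length(called))
  )
}
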