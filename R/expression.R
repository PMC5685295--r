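#' Remove genes below background in every sample
#'
#' A gene is removed only when its normalized intensity is below the
#' per-sample background threshold in every sample; a gene above background
#' in even one sample is retained.
#'
#' @param expr Expression tibble (`gene` + one column per sample).
#' @param background A single threshold applied to all samples, or a named
#'   numeric vector with one threshold per sample (default 0: nothing
#'   removed).
#' @return The filtered expression tibble.
#' @export
background_filter <- function(expr, background = 0) {
  samples <- setdiff(names(expr), "gene")
  if (length(background) == 1 && is.null(names(background))) {
    background <- setNames(rep(background, length(samples)), samples)
  }
  missing <- setdiff(samples, names(background))
  if (length(missing) > 0) {
    abort(paste0("no background threshold for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(expr[samples])
  below <- sweep(m, 2, background[samples], `<`)
  keep <- !apply(below, 1, all)
  expr[keep, ]
}

#' Average probe-level expression to gene level
#'
#' Gene value = unweighted mean of the values of its probes, per sample.
#'
#' @param expr Probe-level expression tibble (`probe_id` + sample columns).
#' @param probe2gene Data frame with columns `probe_id`, `gene`.
#' @return Gene-level expression tibble (`gene` + sample columns).
#' @export
aggregate_probes_to_genes <- function(expr, probe2gene) {
  expr |>
    inner_join(probe2gene, by = "probe_id") |>
    select(-"probe_id") |>
    group_by(.data$gene) |>
    summarise(across(everything(), mean), .groups = "drop")
}

#' Fold changes relative to a reference sample
#'
#' For every gene and non-reference sample, computes the fold change as the
#' larger intensity over the smaller (always >= 1) and records its
#' direction: `higher_in_reference` when the reference is at least
#' `de_cut`-fold higher, `higher_in_target` for the reverse, and
#' `no_difference` when the ratio falls below `de_cut`.
#'
#' @param expr Gene-level expression tibble (strictly positive values; run
#'   [background_filter()] first).
#' @param reference_sample Name of the reference sample column.
#' @param de_cut Differential-expression fold cutoff (default 2, inclusive).
#' @return Tibble with columns `gene`, `target_sample`, `reference_sample`,
#'   `fold_change`, `direction`.
#' @export
fold_changes <- function(expr, reference_sample, de_cut = 2.0) {
  samples <- setdiff(names(expr), "gene")
  if (!reference_sample %in% samples) {
    abort(paste0("reference sample '", reference_sample, "' not in matrix"))
  }
  long <- expr |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
  bad <- long |> filter(is.na(.data$value) | .data$value <= 0)
  if (nrow(bad) > 0) {
    abort(paste0("non-positive expression for gene '", bad$gene[1],
                 "' in sample '", bad$sample[1],
                 "'; filter or offset before computing fold changes"))
  }
  ref <- long |>
    filter(.data$sample == reference_sample) |>
    select("gene", ref_value = "value")
  long |>
    filter(.data$sample != reference_sample) |>
    inner_join(ref, by = "gene") |>
    transmute(
      gene = .data$gene,
      target_sample = .data$sample,
      reference_sample = reference_sample,
      fold_change = pmax(.data$value, .data$ref_value) /
        pmin(.data$value, .data$ref_value),
      direction = dplyr::case_when(
        .data$fold_change < de_cut ~ "no_difference",
        .data$ref_value > .data$value ~ "higher_in_reference",
        TRUE ~ "higher_in_target"
      )
    )
}

#' One-tailed Welch's t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and the right-tail p-value for the alternative that the mean of
#' `group_a` exceeds the mean of `group_b` (as used to test for higher
#' expression in seminomatous than non-seminomatous samples).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list with elements `t`, `df` and `p`.
#' @export
welch_one_tailed <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations")
  }
  fit <- t.test(group_a, group_b, alternative = "greater",
                var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
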