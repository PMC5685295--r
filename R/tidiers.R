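# broom-style tidiers for the package's fitted/result objects

#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) {
  r <- x$report
  tibble(
    rule = c("detection_p", "intensity", "multi_site", "multi_gene"),
    n_removed = c(r$n_removed_detection_p, r$n_removed_intensity,
                  r$n_removed_multi_site, r$n_removed_multi_gene)
  )
}

#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  r <- x$report
  tibble(
    n_probes_in = r$n_probes_in,
    n_probes_out = r$n_probes_out,
    n_removed = r$n_probes_in - r$n_probes_out,
    n_samples_flagged = length(r$flagged_samples)
  )
}

#' @method tidy contingency_tbl
#' @export
tidy.contingency_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "contingency_tbl")
  out
}

#' @method glance contingency_tbl
#' @export
glance.contingency_tbl <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_genes = sum(x$total),
    n_correlating = sum(x$obs_correlating),
    n_no_difference = sum(x$obs_no_difference),
    n_anticorrelating = sum(x$obs_anticorrelating),
    n_significant_bins = sum(x$stars != "", na.rm = TRUE)
  )
}

#' @method tidy threshold_decision
#' @export
tidy.threshold_decision <- function(x, ...) {
  x$bins
}

#' @method glance threshold_decision
#' @export
glance.threshold_decision <- function(x, ...) {
  tibble(
    selected_cut = x$selected_cut,
    n_qualifying_bins = sum(x$bins$qualifies),
    ratio_min = x$ratio_min,
    alpha = x$alpha
  )
}

#' @method glance overlap_test
#' @export
glance.overlap_test <- function(x, ...) {
  tibble(n = x$n, m = x$m, k = x$k, p0 = x$p0,
         p_value = x$p_value, log10_p = x$log10_p)
}

#' @method glance reactivation_test
#' @export
glance.reactivation_test <- function(x, ...) {
  tibble(gene = x$gene %||% NA_character_, ratio = x$ratio,
         p_value = x$p_value, n_boot = x$n_boot)
}

#' @method glance silencing_analysis
#' @export
glance.silencing_analysis <- function(x, ...) {
  bind_rows(lapply(names(x$thresholds), function(tg) {
    tibble(
      target_sample = tg,
      selected_cut = x$thresholds[[tg]]$selected_cut,
      n_silenced = sum(x$silenced$target_sample == tg),
      n_body_only = sum(x$silenced$target_sample == tg &
                          x$silenced$body_only)
    )
  }))
}
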