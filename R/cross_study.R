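#' Concordance of silenced-gene calls with external fold-change tables
#'
#' Marks each silenced-gene call as concordant with an external study when
#' that study reports the gene expressed more than `fold_cut`-fold higher
#' in the seminomatous group (same direction as the cell-line call). Gene
#' symbols are matched case-insensitively and exactly; genes absent from a
#' study are not assessable there (`NA`) and enter neither numerator nor
#' denominator of that study's concordance rate.
#'
#' @param calls Silenced-gene tibble from [classify_silenced()] (or any
#'   tibble with a `gene` column; one row per gene is assessed).
#' @param external A two-column data frame (`gene`, `fold`) or a named
#'   list of them, one per external study.
#' @param fold_cut External fold change that must be exceeded
#'   (default 1.5, strict).
#' @return A tibble with one row per distinct called gene: `gene`, one
#'   fold and one logical concordance column per study, `n_concordant`
#'   (studies where concordant, `NA`s ignored) and `any_concordant` /
#'   `all_concordant` flags (over assessable studies only).
#' @export
concordance_with_primary <- function(calls, external, fold_cut = 1.5) {
  if (is.data.frame(external)) external <- list(external = external)
  stopifnot(is.list(external), !is.null(names(external)))
  out <- tibble(gene = unique(calls$gene))
  conc_cols <- character(0)
  for (study in names(external)) {
    tbl <- external[[study]]
    stopifnot(all(c("gene", "fold") %in% names(tbl)))
    idx <- match(toupper(out$gene), toupper(tbl$gene))
    fold <- tbl$fold[idx]
    out[[paste0(study, "_fold")]] <- fold
    out[[paste0(study, "_concordant")]] <- fold > fold_cut
    conc_cols <- c(conc_cols, paste0(study, "_concordant"))
  }
  conc <- as.matrix(out[conc_cols])
  out$n_assessable <- rowSums(!is.na(conc))
  out$n_concordant <- rowSums(conc, na.rm = TRUE)
  out$any_concordant <- ifelse(out$n_assessable == 0, NA,
                               out$n_concordant > 0)
  out$all_concordant <- ifelse(out$n_assessable == 0, NA,
                               out$n_concordant == out$n_assessable)
  out
}

#' One-sided binomial test for a gene-set overlap
#'
#' Upper-tail probability of observing at least `k` of `m` tested genes in
#' a comparison set, under a binomial null with background rate `p0`
#' (defaulting to the comparison set's share of the gene universe).
#' Computed in log space so that very small p-values stay accurate.
#'
#' @param n Size of the shared gene universe.
#' @param k Observed overlap.
#' @param m Size of the tested set.
#' @param p0 Background success rate; when `NULL`, `comparison_size / n`.
#' @param comparison_size Size of the comparison set, used only to derive
#'   a default `p0`.
#' @return An `overlap_test`: list with `n`, `m`, `k`, `p0`, `p_value` and
#'   `log10_p`. Supports [glance()].
#' @examples
#' binomial_overlap(n = 1000, k = 10, m = 10, p0 = 0.5)
#' @export
binomial_overlap <- function(n, k, m, p0 = NULL, comparison_size = NULL) {
  if (is.null(p0)) {
    if (is.null(comparison_size)) {
      abort("supply either p0 or comparison_size")
    }
    p0 <- comparison_size / n
  }
  if (!(k >= 0 && k <= m && m <= n)) {
    abort("need 0 <= k <= m <= n")
  }
  if (p0 < 0 || p0 > 1) abort("p0 must be in [0, 1]")
  log_p <- if (k == 0) 0 else pbinom(k - 1, size = m, prob = p0,
                                     lower.tail = FALSE, log.p = TRUE)
  structure(list(n = n, m = m, k = k, p0 = p0,
                 p_value = exp(log_p), log10_p = log_p / log(10)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Binomial overlap test: %d of %d genes (universe %d, p0 = %.4g)\n",
    x$k, x$m, x$n, x$p0))
  cat(sprintf("  one-sided P = %.4g (log10 P = %.2f)\n",
              x$p_value, x$log10_p))
  invisible(x)
}
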