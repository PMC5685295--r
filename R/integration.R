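#' Bin differential-methylation records at fixed delta-beta intervals
#'
#' Assigns each non-negative delta-beta record to the half-open interval
#' `[k*width, (k+1)*width)`; a delta of exactly 1 goes to the top bin.
#' Records with negative delta-beta (reference more methylated than target)
#' do not belong in this table and are set aside, retrievable via
#' `attr(x, "excluded_negative")`.
#'
#' @param records Delta-beta tibble from [delta_beta()], restricted to one
#'   comparison (target sample) and one region basis.
#' @param width Bin width (default 0.05).
#' @return The non-negative records with `bin_lo` and `bin_hi` columns
#'   added; excluded negative records as the `excluded_negative` attribute.
#' @export
bin_delta_beta <- function(records, width = 0.05) {
  if (nrow(records) > 0) {
    if (length(unique(records$target_sample)) > 1 ||
        length(unique(records$region_basis)) > 1) {
      abort(paste0("bin_delta_beta expects records from one comparison and ",
                   "one region basis; split first"))
    }
  }
  neg <- records |> filter(.data$delta_beta < 0)
  pos <- records |> filter(.data$delta_beta >= 0)
  k <- floor(pos$delta_beta / width)
  top <- pos$delta_beta >= 1 - 1e-12
  k[top] <- round(1 / width) - 1
  # round the bounds so bins join exactly across computations
  out <- pos |>
    mutate(bin_lo = round(k * width, 10), bin_hi = round((k + 1) * width, 10))
  attr(out, "excluded_negative") <- neg
  out
}

#' Contingency table of methylation bins against expression categories
#'
#' Crosses delta-beta bins with three expression categories -- >=2-fold
#' lower in the target (correlating with its hypermethylation), no >=2-fold
#' difference, and >=2-fold higher in the target (anti-correlating) -- and
#' computes, per bin, the expected counts under the null hypothesis that
#' lower expression does not correlate with methylation
#' (`exp = row_total * column_marginal / grand_total`, marginals over the
#' whole table), the chi-square statistic (2 df, no continuity correction)
#' and its upper-tail p-value. Genes without a fold-change record (no
#' expression data) are dropped. Empty bins up to the highest occupied bin
#' are retained with zero counts and an undefined p.
#'
#' @param binned Binned delta-beta tibble from [bin_delta_beta()].
#' @param fc Fold-change tibble from [fold_changes()] for the same
#'   comparison.
#' @return A `contingency_tbl`: a tibble with columns `bin_lo`, `bin_hi`,
#'   `obs_correlating`, `obs_no_difference`, `obs_anticorrelating`,
#'   `exp_correlating`, `exp_no_difference`, `exp_anticorrelating`,
#'   `total`, `chi2`, `p_value`, `stars`.
#' @export
contingency_table <- function(binned, fc) {
  joined <- binned |>
    inner_join(fc |> select("gene", "target_sample", "direction"),
               by = c("gene", "target_sample"))
  if (nrow(joined) == 0) abort("no binned gene has a fold-change record")
  counts <- joined |>
    mutate(category = dplyr::recode(.data$direction,
                                    higher_in_reference = "obs_correlating",
                                    no_difference = "obs_no_difference",
                                    higher_in_target = "obs_anticorrelating"
    )) |>
    count(.data$bin_lo, .data$bin_hi, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (nm in c("obs_correlating", "obs_no_difference",
               "obs_anticorrelating")) {
    if (!nm %in% names(counts)) counts[[nm]] <- 0L
  }
  width <- counts$bin_hi[1] - counts$bin_lo[1]
  ladder <- tibble(
    bin_lo = round(seq(0, max(counts$bin_lo) + width / 2, by = width), 10)
  ) |>
    filter(.data$bin_lo <= max(counts$bin_lo) + 1e-9) |>
    mutate(bin_hi = round(.data$bin_lo + width, 10))
  counts <- ladder |>
    left_join(counts |> select(-"bin_hi"), by = "bin_lo") |>
    mutate(across(starts_with("obs_"),
                  \(x) as.integer(tidyr::replace_na(x, 0L))))
  contingency_from_counts(counts)
}

#' Expected counts, chi-square and p-values from observed bin counts
#'
#' Completes a table of observed counts per delta-beta bin (three expression
#' categories) with expected counts from the table-wide marginals, the
#' per-bin chi-square statistic on 2 degrees of freedom (no continuity
#' correction) and its upper-tail p-value, starred at p < 0.05 / 0.01 /
#' 0.001.
#'
#' @param counts Tibble with columns `bin_lo`, `bin_hi`, `obs_correlating`,
#'   `obs_no_difference`, `obs_anticorrelating`.
#' @return A `contingency_tbl` (see [contingency_table()]).
#' @export
contingency_from_counts <- function(counts) {
  obs_cols <- c("obs_correlating", "obs_no_difference",
                "obs_anticorrelating")
  stopifnot(all(c("bin_lo", "bin_hi", obs_cols) %in% names(counts)))
  obs <- as.matrix(counts[obs_cols])
  row_tot <- rowSums(obs)
  col_tot <- colSums(obs)
  grand <- sum(obs)
  if (grand == 0) abort("contingency table is empty")
  expd <- outer(unname(row_tot), unname(col_tot)) / grand
  # chi-square terms: cells with zero expectation contribute 0 when the
  # observed count is also 0 (structurally empty column), Inf otherwise
  term <- (obs - expd)^2 / expd
  term[expd == 0 & obs == 0] <- 0
  chi2 <- rowSums(term)
  p <- pchisq(chi2, df = 2, lower.tail = FALSE)
  chi2[row_tot == 0] <- NA_real_
  p[row_tot == 0] <- NA_real_
  out <- counts |>
    select("bin_lo", "bin_hi", all_of(obs_cols)) |>
    mutate(
      exp_correlating = expd[, 1],
      exp_no_difference = expd[, 2],
      exp_anticorrelating = expd[, 3],
      total = as.integer(row_tot),
      chi2 = chi2,
      p_value = p,
      stars = significance_stars(p)
    ) |>
    arrange(.data$bin_lo)
  class(out) <- c("contingency_tbl", class(out))
  out
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Select the delta-beta threshold from a contingency table
#'
#' A bin qualifies when its observed count of correlating genes (lower
#' expression in the hypermethylated target) is at least `ratio_min` times
#' the expected count and its chi-square p-value is below `alpha` -- a
#' substantial and significant excess over the random expectation. The
#' selected delta-beta cutoff is the lower bound of the lowest qualifying
#' bin (the unique qualifying bin with no qualifying bin below it), or
#' `NA` when no bin qualifies.
#'
#' @param table A `contingency_tbl`.
#' @param ratio_min Minimum observed/expected ratio for the correlating
#'   category (default 2).
#' @param alpha Significance level (default 0.05).
#' @return A `threshold_decision`: list with `selected_cut` (numeric or
#'   `NA`) and `bins` (per-bin ratio, p and qualification flag). Supports
#'   [tidy()] and [glance()].
#' @export
select_threshold <- function(table, ratio_min = 2.0, alpha = 0.05) {
  bins <- tibble(
    bin_lo = table$bin_lo,
    bin_hi = table$bin_hi,
    obs_correlating = table$obs_correlating,
    exp_correlating = table$exp_correlating,
    ratio = ifelse(table$exp_correlating > 0,
                   table$obs_correlating / table$exp_correlating, NA_real_),
    p_value = table$p_value,
    qualifies = !is.na(table$p_value) &
      table$exp_correlating > 0 &
      table$obs_correlating >= ratio_min * table$exp_correlating &
      table$p_value < alpha
  )
  selected <- if (any(bins$qualifies)) min(bins$bin_lo[bins$qualifies])
              else NA_real_
  structure(list(selected_cut = selected, bins = bins,
                 ratio_min = ratio_min, alpha = alpha),
            class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  if (is.na(x$selected_cut)) {
    cat("No qualifying delta-beta bin (observed <", x$ratio_min,
        "x expected or p >=", x$alpha, "in every bin)\n")
  } else {
    cat("Selected delta-beta cutoff:", x$selected_cut, "\n")
    cat("Qualifying bins:",
        paste(sprintf("[%.2f,%.2f)", x$bins$bin_lo[x$bins$qualifies],
                      x$bins$bin_hi[x$bins$qualifies]), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Classify genes silenced by methylation
#'
#' A gene is called silenced on the TSS basis when its TSS-island
#' delta-beta is at or above `cut` and its expression is at least
#' `de_cut`-fold higher in the reference sample; likewise on the body basis
#' for body-island delta-beta. Body calls are flagged `body_only` when the
#' gene has no TSS-island aggregate or its TSS delta-beta stays below the
#' cut -- body-island methylation alone accounts for the silencing.
#'
#' @param delta Delta-beta tibble from [delta_beta()] (one target sample,
#'   both region bases).
#' @param fc Fold-change tibble from [fold_changes()].
#' @param cut Delta-beta cutoff, typically from [select_threshold()]
#'   (inclusive).
#' @param de_cut Fold-change cutoff (default 2, inclusive).
#' @return Tibble with columns `gene`, `target_sample`, `region_basis`,
#'   `delta_beta`, `fold_change`, `body_only`.
#' @export
classify_silenced <- function(delta, fc, cut, de_cut = 2.0) {
  if (is.na(cut)) {
    return(tibble(gene = character(0), target_sample = character(0),
                  region_basis = character(0), delta_beta = double(0),
                  fold_change = double(0), body_only = logical(0)))
  }
  down <- fc |>
    filter(.data$direction == "higher_in_reference",
           .data$fold_change >= de_cut) |>
    select("gene", "target_sample", "fold_change")
  tss_delta <- delta |>
    filter(.data$region_basis == "TSS") |>
    select("gene", "target_sample", tss_delta = "delta_beta")
  calls <- delta |>
    filter(.data$delta_beta >= cut) |>
    inner_join(down, by = c("gene", "target_sample")) |>
    left_join(tss_delta, by = c("gene", "target_sample")) |>
    mutate(body_only = .data$region_basis == "Body" &
             (is.na(.data$tss_delta) | .data$tss_delta < cut)) |>
    select("gene", "target_sample", "region_basis", "delta_beta",
           "fold_change", "body_only") |>
    arrange(desc(.data$fold_change))
  calls
}

#' Venn region counts for gene methylation-call sets
#'
#' Exact set algebra over k gene sets: the number of genes in each of the
#' 2^k - 1 non-empty membership combinations (exclusive regions of a Venn
#' diagram).
#'
#' @param calls Named list of character vectors (genes methylated in each
#'   sample).
#' @return Tibble with one logical membership column per set, a `region`
#'   label, and `count`; counts over disjoint regions sum to the size of
#'   the union.
#' @export
methylation_venn <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 1, !is.null(names(calls)))
  sets <- lapply(calls, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- apply(combos, 1, function(cmb) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(m) all(m == cmb)))
  })
  as_tibble(combos) |>
    mutate(
      region = apply(combos, 1, function(cmb) {
        paste(names(sets)[as.logical(cmb)], collapse = "&")
      }),
      count = as.integer(counts)
    ) |>
    arrange(desc(rowSums(across(where(is.logical)))))
}
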