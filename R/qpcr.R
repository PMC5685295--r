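#' Construct a qPCR assay from a Ct replicate table
#'
#' Extracts the replicate Ct values of one gene from a long table of
#' threshold cycles and attaches the assay's amplification efficiency
#' (2 = perfect doubling per cycle).
#'
#' @param data Tibble with columns `gene`, `condition` (`"control"` /
#'   `"treated"`), `replicate`, `ct`.
#' @param gene Gene to extract.
#' @param efficiency Amplification efficiency in \[1, 2.2\] (default 2).
#' @return A `qpcr_assay` tibble (`condition`, `replicate`, `ct`) with the
#'   gene and efficiency stored as attributes.
#' @export
qpcr_assay <- function(data, gene, efficiency = 2.0) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(data)))
  if (efficiency < 1 || efficiency > 2.2) {
    abort("efficiency must lie in [1, 2.2]")
  }
  rows <- data |> filter(.data$gene == !!gene)
  if (nrow(rows) == 0) abort(paste0("no Ct rows for gene '", gene, "'"))
  bad <- setdiff(unique(rows$condition), c("control", "treated"))
  if (length(bad) > 0) {
    abort(paste0("unknown condition '", bad[1], "'"))
  }
  if (length(unique(rows$condition)) < 2) {
    abort(paste0("gene '", gene, "' is missing a condition"))
  }
  out <- rows |> select("condition", "replicate", "ct")
  attr(out, "gene") <- gene
  attr(out, "efficiency") <- efficiency
  class(out) <- c("qpcr_assay", class(out))
  out
}

assay_delta_ct <- function(assay) {
  mean(assay$ct[assay$condition == "control"]) -
    mean(assay$ct[assay$condition == "treated"])
}

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' The Pfaffl ratio `E_t^dCt_t / E_r^dCt_r`, where for each assay
#' `dCt = mean Ct(control) - mean Ct(treated)` and `E` is its
#' amplification efficiency. A ratio above 1 means the target gene is
#' expressed more highly in the treated (demethylated) condition relative
#' to the reference gene.
#'
#' @param target,reference `qpcr_assay` objects (reference typically a
#'   housekeeping gene such as ACTB).
#' @return A positive number.
#' @export
pfaffl_ratio <- function(target, reference) {
  stopifnot(inherits(target, "qpcr_assay"), inherits(reference, "qpcr_assay"))
  e_t <- attr(target, "efficiency")
  e_r <- attr(reference, "efficiency")
  e_t^assay_delta_ct(target) / e_r^assay_delta_ct(reference)
}

#' Pfaffl ratios for every gene in a Ct table
#'
#' @param data Long Ct tibble (`gene`, `condition`, `replicate`, `ct`).
#' @param reference_gene Housekeeping gene used as reference
#'   (default `"ACTB"`).
#' @param efficiency Amplification efficiency applied to all assays
#'   (default 2), or a named vector per gene.
#' @return Tibble with columns `gene` and `ratio` (reference gene
#'   excluded).
#' @export
pfaffl_ratios <- function(data, reference_gene = "ACTB", efficiency = 2.0) {
  genes <- setdiff(unique(data$gene), reference_gene)
  if (!reference_gene %in% data$gene) {
    abort(paste0("reference gene '", reference_gene, "' not in Ct table"))
  }
  eff_of <- function(g) {
    if (length(efficiency) == 1 && is.null(names(efficiency))) efficiency
    else efficiency[[g]]
  }
  ref <- qpcr_assay(data, reference_gene, eff_of(reference_gene))
  tibble(
    gene = genes,
    ratio = vapply(genes, function(g) {
      pfaffl_ratio(qpcr_assay(data, g, eff_of(g)), ref)
    }, double(1), USE.NAMES = FALSE)
  )
}

#' Bootstrap test for demethylation reactivation
#'
#' Tests whether a gene's Pfaffl ratio exceeds 1 (re-expression after
#' demethylating treatment) by resampling replicate Ct values with
#' replacement within each of the four gene-by-condition cells and
#' recomputing the ratio; the one-sided p-value is the bootstrap fraction
#' of ratios at or below 1. Deterministic for a fixed `seed`.
#'
#' @param target,reference `qpcr_assay` objects with at least 3 replicates
#'   per condition.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling.
#' @return A `reactivation_test`: list with `gene`, `ratio`, `p_value`,
#'   `n_boot`. Supports [glance()].
#' @export
reactivation_test <- function(target, reference, n_boot = 2000, seed = 1) {
  for (assay in list(target, reference)) {
    reps <- table(assay$condition)
    if (any(reps < 3)) {
      abort("reactivation_test needs >= 3 replicates per condition")
    }
  }
  cells <- list(
    tc = target$ct[target$condition == "control"],
    tt = target$ct[target$condition == "treated"],
    rc = reference$ct[reference$condition == "control"],
    rt = reference$ct[reference$condition == "treated"]
  )
  e_t <- attr(target, "efficiency")
  e_r <- attr(reference, "efficiency")
  ratio_of <- function(tc, tt, rc, rt) {
    e_t^(mean(tc) - mean(tt)) / e_r^(mean(rc) - mean(rt))
  }
  obs <- ratio_of(cells$tc, cells$tt, cells$rc, cells$rt)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      res <- lapply(cells, function(x) sample(x, length(x), replace = TRUE))
      ratio_of(res$tc, res$tt, res$rc, res$rt)
    }, double(1))
  })
  structure(list(gene = attr(target, "gene"), ratio = obs,
                 p_value = mean(boot <= 1), n_boot = n_boot),
            class = "reactivation_test")
}

#' @export
print.reactivation_test <- function(x, ...) {
  cat(sprintf("Reactivation of %s: Pfaffl ratio %.3g, bootstrap P = %.4g\n",
              x$gene %||% "gene", x$ratio, x$p_value))
  invisible(x)
}

#' Read a qPCR Ct replicate table
#'
#' @param path CSV with columns `gene`, `condition`, `replicate`, `ct`.
#' @return A tibble with those columns; Ct values must be positive.
#' @export
read_qpcr <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()
  ), progress = FALSE)
  if (any(is.na(tbl$ct) | tbl$ct <= 0)) {
    abort("Ct values must be positive")
  }
  tbl
}
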