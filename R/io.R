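#' Read a probe annotation manifest
#'
#' Reads a CSV manifest describing one array probe per row: its genomic
#' position, the gene(s) it is annotated to, its position within the gene
#' (TSS1500, first exon, body, ...) and its relation to the nearest CpG
#' island (island, shore, shelf or open sea). Probes annotated to more than
#' one gene (symbols separated by `;`) are kept but flagged with
#' `multi_gene = TRUE`; they are excluded later, during gene-level
#' aggregation, so that raw I/O stays lossless.
#'
#' @param path Path to a CSV file with columns `probe_id`, `gene_symbol`,
#'   `chrom`, `pos`, `gene_region`, `island_relation`, `island_id`.
#' @return A tibble with one row per probe: the seven manifest columns plus
#'   `gene_symbols` (list column of split symbols) and `multi_gene`
#'   (logical). Coordinates are 1-based inclusive.
#' @examples
#' path <- system.file("extdata", "example_manifest.csv",
#'                     package = "methylsilence")
#' read_manifest(path)
#' @export
read_manifest <- function(path) {
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    gene_region = readr::col_character(),
    island_relation = readr::col_character(),
    island_id = readr::col_character()
  ), progress = FALSE))
  required <- c("probe_id", "gene_symbol", "chrom", "pos", "gene_region",
                "island_relation", "island_id")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- raw$probe_id[duplicated(raw$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate probe_id in manifest: ",
                 paste(unique(dup), collapse = ", ")))
  }
  check_enum(raw, "gene_region", GENE_REGIONS)
  check_enum(raw, "island_relation", ISLAND_RELATIONS)
  bad_pos <- which(is.na(raw$pos) | raw$pos < 1)
  if (length(bad_pos) > 0) {
    abort(paste0("manifest row ", bad_pos[1], " (probe ",
                 raw$probe_id[bad_pos[1]], "): pos must be >= 1"))
  }
  no_island <- which(raw$island_relation == "Island" &
                       (is.na(raw$island_id) | raw$island_id == ""))
  if (length(no_island) > 0) {
    abort(paste0("manifest row ", no_island[1], " (probe ",
                 raw$probe_id[no_island[1]],
                 "): island_relation is Island but island_id is empty"))
  }
  raw |>
    mutate(
      pos = as.integer(.data$pos),
      gene_symbols = strsplit(ifelse(is.na(.data$gene_symbol), "",
                                     .data$gene_symbol), ";", fixed = TRUE),
      gene_symbols = purrr::map(.data$gene_symbols,
                                \(x) x[nzchar(x)]),
      multi_gene = lengths(.data$gene_symbols) > 1
    )
}

check_enum <- function(df, col, levels) {
  bad <- which(!(df[[col]] %in% levels) & !is.na(df[[col]]))
  if (col == "gene_region" || col == "island_relation") {
    bad <- which(is.na(df[[col]]) | !(df[[col]] %in% levels))
  }
  if (length(bad) > 0) {
    abort(paste0("manifest row ", bad[1], ": unrecognised ", col, " '",
                 df[[col]][bad[1]], "'"))
  }
  invisible(df)
}

#' Read a probes-by-samples or genes-by-samples matrix
#'
#' Reads a TSV whose first column holds row identifiers (probe or gene ids)
#' and whose remaining columns hold one sample each. Values are validated
#' according to `kind`: beta values and detection p-values must lie in
#' \[0, 1\] (missing values allowed, encoded as `NA`, never 0), expression
#' intensities must be non-negative.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"beta"`, `"detection_p"`, `"expression"`.
#' @return A tibble: first column `probe_id` (or `gene` for expression),
#'   one numeric column per sample.
#' @export
read_matrix <- function(path, kind = c("beta", "detection_p", "expression")) {
  kind <- match.arg(kind)
  id_col <- if (kind == "expression") "gene" else "probe_id"
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed matrix file ", path, ": ", probs$expected[1],
                 " at row ", probs$row[1]))
  }
  if (ncol(raw) < 2) abort("matrix file needs an id column plus >= 1 sample")
  names(raw)[1] <- id_col
  vals <- raw[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("non-numeric cells in matrix file")
  }
  m <- as.matrix(vals)
  if (kind %in% c("beta", "detection_p")) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0(kind, " value out of [0, 1] for id '",
                   raw[[id_col]][bad[1, 1]], "', sample '",
                   colnames(m)[bad[1, 2]], "': ", m[bad[1, , drop = FALSE]]))
    }
  } else {
    bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("negative expression value for gene '",
                   raw[[id_col]][bad[1, 1]], "', sample '",
                   colnames(m)[bad[1, 2]], "'"))
    }
  }
  if (anyDuplicated(raw[[id_col]])) {
    abort(paste0("duplicate row ids in ", path))
  }
  as_tibble(raw)
}

#' Packaged contingency table for the yolk-sac-tumour vs seminoma comparison
#'
#' Returns the published 19-bin contingency table of observed (and, for
#' cross-checking, printed expected) gene counts in three expression
#' categories -- lower in the non-seminoma line (correlating with
#' hypermethylation), no >=2-fold difference, and higher in the non-seminoma
#' line (anti-correlating) -- across delta-beta bins of width 0.05.
#'
#' @return A tibble with 19 rows and columns `bin_lo`, `bin_hi`,
#'   `obs_correlating`, `obs_no_difference`, `obs_anticorrelating`, the
#'   printed `printed_exp_*` values, `printed_total`, `printed_p` and
#'   `printed_stars`.
#' @examples
#' tbl <- load_table1_fixture()
#' sum(tbl$obs_correlating) # 772
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "contingency_yst_vs_seminoma.csv",
                      package = "methylsilence")
  tbl <- readr::read_csv(path, col_types = readr::cols(
    printed_stars = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  tbl$printed_stars[is.na(tbl$printed_stars)] <- ""
  tbl
}

#' Packaged cross-study fold-change table
#'
#' The published list of genes differentially methylated and >=2-fold
#' differentially expressed between the yolk-sac-tumour and seminoma cell
#' lines, with the fold change observed in the cell lines and in two
#' independent primary-tumour expression cohorts.
#'
#' @return A tibble with columns `gene`, `cell_line_fold`, `korkola_fold`,
#'   `palmer_fold`.
#' @export
load_primary_tumour_folds <- function() {
  path <- system.file("extdata", "primary_tumour_folds.csv",
                      package = "methylsilence")
  readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write analysis result tables to a directory
#'
#' Writes every table in `tables` as a TSV named after its list element, a
#' `run_summary.json` recording the configuration, seed and per-table row
#' counts, and -- for any table carrying island coordinates (columns
#' `chrom`, `island_start`, `island_end`, 1-based inclusive) -- a BED file
#' (0-based, half-open) with one interval per differentially methylated
#' island.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if absent.
#' @param config Optional named list recorded in the run summary.
#' @param seed Optional integer recorded in the run summary.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(tables = list(), out_dir, config = list(),
                          seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      abort(paste0("cannot create output directory ", out_dir))
    }
  }
  stopifnot(is.list(tables))
  if (length(tables) > 0 && is.null(names(tables))) {
    abort("tables must be a named list")
  }
  written <- character(0)
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, tsv, progress = FALSE)
    written <- c(written, tsv)
    if (all(c("chrom", "island_start", "island_end") %in% names(tbl))) {
      bed <- file.path(out_dir, paste0(nm, ".bed"))
      name_col <- if ("gene" %in% names(tbl)) tbl$gene else tbl$chrom
      bed_tbl <- tibble(
        chrom = tbl$chrom,
        start = as.integer(tbl$island_start) - 1L, # 1-based -> 0-based
        end = as.integer(tbl$island_end),
        name = name_col
      )
      readr::write_tsv(bed_tbl, bed, col_names = FALSE, progress = FALSE)
      written <- c(written, bed)
    }
  }
  summary <- list(
    config = config,
    seed = seed,
    tables = lapply(tables, nrow)
  )
  json <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  written <- c(written, json)
  invisible(written)
}

#' Island genomic intervals for silenced-gene calls
#'
#' Attaches, to each silenced-gene call, the genomic span (1-based
#' inclusive) of the CpG island on which the call is based: the minimum and
#' maximum manifest position of the island probes of that gene in the
#' relevant region (TSS-associated or gene body).
#'
#' @param calls A tibble of silenced-gene calls from [classify_silenced()].
#' @param manifest A manifest tibble from [read_manifest()].
#' @return `calls` with `chrom`, `island_start`, `island_end` columns added
#'   (`NA` where no island probes are found).
#' @export
attach_island_coordinates <- function(calls, manifest) {
  probes <- manifest_gene_probes(manifest) |>
    filter(.data$island_relation == "Island") |>
    mutate(region_basis = ifelse(.data$gene_region %in% TSS_REGIONS,
                                 "TSS",
                                 ifelse(.data$gene_region == "Body",
                                        "Body", NA_character_))) |>
    filter(!is.na(.data$region_basis)) |>
    group_by(.data$gene, .data$region_basis) |>
    summarise(chrom = .data$chrom[1],
              island_start = min(.data$pos),
              island_end = max(.data$pos),
              .groups = "drop")
  calls |>
    left_join(probes, by = c("gene", "region_basis"))
}

# one row per (probe, gene) for single-gene probes; multi-gene probes are
# excluded here, per the analysis rule
manifest_gene_probes <- function(manifest) {
  manifest |>
    filter(!.data$multi_gene, lengths(.data$gene_symbols) == 1) |>
    mutate(gene = purrr::map_chr(.data$gene_symbols, 1)) |>
    select(-"gene_symbols")
}
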