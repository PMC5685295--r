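#' Configuration for the synthetic methylation/expression generator
#'
#' Bundles and validates every tunable of the generator. The defaults
#' describe a hypomethylated reference cell line (seminoma-like) compared
#' against non-seminoma-like target lines in which a planted subset of
#' genes carries hypermethylated TSS and/or gene-body CpG islands
#' (island-mean delta-beta drawn in `delta_beta_effect_range`), with
#' expression coupled so that a tunable fraction of hypermethylated genes
#' is silenced (at least 2-fold down in the targets).
#'
#' @param n_genes Number of genes simulated (default 2000).
#' @param n_probes_per_island Inclusive range of island probe counts per
#'   island (default 4-10; the array averages ~17 CpGs per gene across all
#'   regions).
#' @param body_island_prob Probability that a gene carries a body CpG
#'   island in addition to its TSS island (default 0.6).
#' @param fraction_hypermethylated_tss Fraction of genes whose TSS island
#'   is hypermethylated in the target lines (default 0.1).
#' @param fraction_hypermethylated_body Fraction of body-island-bearing
#'   genes whose body island is hypermethylated (default 0.05).
#' @param fraction_silenced_given_hypermethylated Fraction of
#'   hypermethylated genes that are also silenced (default 0.5, matching
#'   the observation that about half of differentially methylated genes
#'   show a correlating expression loss).
#' @param beta_params_unmeth Beta-distribution shape pair for unmethylated
#'   probes (default `c(1.5, 13.5)`, mean 0.1).
#' @param beta_params_meth Shape pair for methylated probes (default
#'   `c(8, 2)`, mean 0.8).
#' @param delta_beta_effect_range Interval from which each hypermethylated
#'   island's true island-mean delta-beta is drawn (default
#'   `c(0.65, 0.9)`).
#' @param expr_fold_range_silenced Interval (>= 2) from which silenced
#'   genes' true fold changes are drawn, uniform on the log scale (default
#'   `c(2, 50)`).
#' @param expr_noise_cv Coefficient of variation of the multiplicative
#'   log-normal expression noise (default 0.2).
#' @param expr_base_mean,expr_base_sdlog Log-normal parameters of baseline
#'   expression intensities.
#' @param reference_sample,target_samples Sample names (defaults `"SEM"`
#'   and `c("YST", "EC", "TERA")`).
#' @param qpcr_delta_ct True Ct decrease of reactivated genes after
#'   treatment (default 3 cycles).
#' @param qpcr_noise_sd Replicate Ct standard deviation (default 0.2).
#' @param qpcr_replicates Replicates per condition (default 3).
#' @param seed Integer seed; each generated dataset derives its own RNG
#'   stream from `(seed, dataset name)`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_probes_per_island = c(4, 10),
                       body_island_prob = 0.6,
                       fraction_hypermethylated_tss = 0.1,
                       fraction_hypermethylated_body = 0.05,
                       fraction_silenced_given_hypermethylated = 0.5,
                       beta_params_unmeth = c(1.5, 13.5),
                       beta_params_meth = c(8, 2),
                       delta_beta_effect_range = c(0.65, 0.9),
                       expr_fold_range_silenced = c(2, 50),
                       expr_noise_cv = 0.2,
                       expr_base_mean = 500,
                       expr_base_sdlog = 1,
                       reference_sample = "SEM",
                       target_samples = c("YST", "EC", "TERA"),
                       qpcr_delta_ct = 3,
                       qpcr_noise_sd = 0.2,
                       qpcr_replicates = 3,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(body_island_prob, fraction_hypermethylated_tss,
             fraction_hypermethylated_body,
             fraction_silenced_given_hypermethylated)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (n_genes < 1) abort("n_genes must be >= 1")
  stopifnot(length(n_probes_per_island) == 2,
            n_probes_per_island[1] >= 1,
            n_probes_per_island[1] <= n_probes_per_island[2])
  if (any(delta_beta_effect_range < 0) ||
      any(delta_beta_effect_range > 1) ||
      delta_beta_effect_range[1] > delta_beta_effect_range[2]) {
    abort("delta_beta_effect_range must be an interval within [0, 1]")
  }
  if (delta_beta_effect_range[2] > 0.95) {
    abort(paste0("infeasible config: a delta-beta effect above 0.95 would ",
                 "push island beta values past 1"))
  }
  if (expr_fold_range_silenced[1] < 2 ||
      expr_fold_range_silenced[1] > expr_fold_range_silenced[2]) {
    abort("expr_fold_range_silenced must be an interval with lower end >= 2")
  }
  if (expr_noise_cv < 0) abort("expr_noise_cv must be non-negative")
  if (any(beta_params_unmeth <= 0) || any(beta_params_meth <= 0)) {
    abort("beta shape parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

# draw n beta values with a given mean and concentration (a + b)
rbeta_mean <- function(n, mean, conc = 100) {
  mean <- min(max(mean, 1e-3), 1 - 1e-3)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate an annotated methylome with planted hypermethylation
#'
#' Lays genes out along one synthetic chromosome, each with a
#' TSS-associated CpG island (probes labelled TSS1500/TSS200/UTR5/
#' FirstExon), optionally a body island, flanking shore and shelf probes
#' at the 2 kb annotation bands and an open-sea probe. Island probes draw
#' beta values from the unmethylated beta distribution in the reference
#' sample; in target samples, islands planted as hypermethylated draw
#' probe betas so that the island-mean delta-beta equals the gene's true
#' effect (drawn from `delta_beta_effect_range`). Identical seeds yield
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `manifest` (tibble as from
#'   [read_manifest()]), `beta` (probes x samples tibble),
#'   `detection_p` (parallel tibble, all passing), and `truth` (per-gene
#'   tibble: `gene`, `hypermethylated_tss`, `hypermethylated_body`,
#'   `silenced`, `true_delta_beta`, `true_fold_change`).
#' @export
simulate_methylome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stream_seed(cfg$seed, "methylome"), {
    n <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(n))
    has_body <- runif(n) < cfg$body_island_prob
    hyper_tss <- runif(n) < cfg$fraction_hypermethylated_tss
    hyper_body <- has_body & runif(n) < cfg$fraction_hypermethylated_body
    hyper_any <- hyper_tss | hyper_body
    silenced <- hyper_any &
      runif(n) < cfg$fraction_silenced_given_hypermethylated
    true_delta <- ifelse(hyper_any,
                         runif(n, cfg$delta_beta_effect_range[1],
                               cfg$delta_beta_effect_range[2]),
                         NA_real_)
    log_fold <- runif(n, log(cfg$expr_fold_range_silenced[1]),
                      log(cfg$expr_fold_range_silenced[2]))
    true_fold <- ifelse(silenced, exp(log_fold), 1)

    truth <- tibble(
      gene = genes,
      hypermethylated_tss = hyper_tss,
      hypermethylated_body = hyper_body,
      silenced = silenced,
      true_delta_beta = true_delta,
      true_fold_change = true_fold
    )

    k_tss <- sample(cfg$n_probes_per_island[1]:cfg$n_probes_per_island[2],
                    n, replace = TRUE)
    k_body <- sample(cfg$n_probes_per_island[1]:cfg$n_probes_per_island[2],
                     n, replace = TRUE)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      base <- (i - 1) * 50000 + 10000
      tss_regions <- rep(c("TSS1500", "TSS200", "UTR5", "FirstExon"),
                         length.out = k_tss[i])
      r <- list(tibble(
        gene = genes[i],
        pos = base + seq_len(k_tss[i]) * 40L,
        gene_region = tss_regions,
        island_relation = "Island",
        island_id = paste0("CGI_", genes[i], "_TSS")
      ))
      # shore/shelf/open-sea probes at the annotation distance bands
      r[[2]] <- tibble(
        gene = genes[i],
        pos = base + c(-1000L, k_tss[i] * 40L + 1000L, -3000L,
                       k_tss[i] * 40L + 3000L, 20000L),
        gene_region = c("TSS1500", "Body", "Intergenic", "Intergenic",
                        "Intergenic"),
        island_relation = c("N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                            "OpenSea"),
        island_id = NA_character_
      )
      if (has_body[i]) {
        r[[3]] <- tibble(
          gene = genes[i],
          pos = base + 8000L + seq_len(k_body[i]) * 40L,
          gene_region = "Body",
          island_relation = "Island",
          island_id = paste0("CGI_", genes[i], "_BODY")
        )
      }
      rows[[i]] <- bind_rows(r)
    }
    manifest <- bind_rows(rows) |>
      mutate(
        probe_id = sprintf("cg%06d", dplyr::row_number()),
        gene_symbol = .data$gene,
        chrom = "chrS",
        gene_symbols = as.list(.data$gene),
        multi_gene = FALSE
      )

    samples <- c(cfg$reference_sample, cfg$target_samples)
    a_u <- cfg$beta_params_unmeth[1]
    b_u <- cfg$beta_params_unmeth[2]
    a_m <- cfg$beta_params_meth[1]
    b_m <- cfg$beta_params_meth[2]
    n_probes <- nrow(manifest)
    beta <- matrix(NA_real_, nrow = n_probes, ncol = length(samples),
                   dimnames = list(manifest$probe_id, samples))

    is_island <- manifest$island_relation == "Island"
    is_shore <- manifest$island_relation %in% c("N_Shore", "S_Shore")
    is_outer <- !is_island & !is_shore
    island_key <- paste0(manifest$gene, "_",
                         ifelse(manifest$gene_region %in% TSS_REGIONS,
                                "TSS", "BODY"))

    gene_idx <- match(manifest$gene, genes)
    for (s in samples) {
      b <- numeric(n_probes)
      b[is_shore] <- rbeta(sum(is_shore), 2, 2)     # intermediate shores
      b[is_outer] <- rbeta(sum(is_outer), a_m, b_m) # methylated background
      b[is_island] <- rbeta(sum(is_island), a_u, b_u)
      if (s != cfg$reference_sample) {
        hyper_here <- is_island &
          ((island_key == paste0(manifest$gene, "_TSS") &
              hyper_tss[gene_idx]) |
             (island_key == paste0(manifest$gene, "_BODY") &
                hyper_body[gene_idx]))
        for (key in unique(island_key[hyper_here])) {
          idx <- which(island_key == key & is_island)
          g <- gene_idx[idx[1]]
          # reference island mean realized for this gene
          m0 <- mean(beta[idx, cfg$reference_sample])
          # cap the realized effect so island betas stay inside [0, 1];
          # infeasible only if the cap drops below the configured range
          d_eff <- min(true_delta[g], 0.985 - m0)
          if (d_eff < cfg$delta_beta_effect_range[1]) {
            abort("infeasible config: effect range forces island beta > 1")
          }
          target_mean <- m0 + d_eff
          draw <- rbeta_mean(length(idx), target_mean, conc = 150)
          # recentre so the island-mean delta-beta equals the planted effect
          draw <- draw - mean(draw) + target_mean
          for (tries in 1:100) {
            if (all(draw >= 0 & draw <= 1)) break
            draw <- rbeta_mean(length(idx), target_mean, conc = 150)
            draw <- draw - mean(draw) + target_mean
          }
          draw <- pmin(pmax(draw, 0), 1)
          b[idx] <- draw
        }
      }
      beta[, s] <- b # reference is first, so targets can read its islands
    }
    manifest <- manifest |>
      select("probe_id", "gene_symbol", "chrom", "pos", "gene_region",
             "island_relation", "island_id", "gene_symbols", "multi_gene")
    beta_tbl <- bind_cols(tibble(probe_id = manifest$probe_id),
                          as_tibble(beta))
    detp <- bind_cols(
      tibble(probe_id = manifest$probe_id),
      as_tibble(matrix(runif(n_probes * length(samples), 0, 0.01),
                       nrow = n_probes,
                       dimnames = list(NULL, samples)))
    )
    list(manifest = manifest, beta = beta_tbl, detection_p = detp,
         truth = truth)
  })
}

#' Simulate expression coupled to planted silencing
#'
#' Baseline intensities are log-normal per gene; in target samples,
#' silenced genes are reduced by their true fold change exactly, and every
#' value is then perturbed by multiplicative log-normal noise with
#' coefficient of variation `expr_noise_cv` (mean 1; zero noise gives
#' exact folds). Non-silenced genes are centred at fold 1.
#'
#' @param truth Truth tibble from [simulate_methylome()].
#' @param cfg The same [sim_config()].
#' @return Expression tibble: `gene` plus one column per sample.
#' @export
simulate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stream_seed(cfg$seed, "expression"), {
    n <- nrow(truth)
    base <- exp(rnorm(n, log(cfg$expr_base_mean), cfg$expr_base_sdlog))
    cv <- cfg$expr_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    noise <- function() {
      if (cv == 0) rep(1, n) else exp(rnorm(n, -sdlog^2 / 2, sdlog))
    }
    out <- tibble(gene = truth$gene)
    out[[cfg$reference_sample]] <- base * noise()
    for (s in cfg$target_samples) {
      out[[s]] <- base / truth$true_fold_change * noise()
    }
    out
  })
}

#' Simulate qPCR Ct replicates for a demethylation experiment
#'
#' Generates control and treated Ct replicates for the given genes plus
#' the ACTB reference. Reactivated genes have their treated Ct lowered by
#' `qpcr_delta_ct` cycles; the reference gene is equal across conditions
#' up to noise.
#'
#' @param genes Character vector of target genes.
#' @param reactivated Subset of `genes` that respond to demethylation.
#' @param cfg A [sim_config()] (fields `qpcr_delta_ct`, `qpcr_noise_sd`,
#'   `qpcr_replicates`, `seed`).
#' @param reference_gene Name of the housekeeping gene row added
#'   (default `"ACTB"`).
#' @return Long Ct tibble (`gene`, `condition`, `replicate`, `ct`).
#' @export
simulate_qpcr <- function(genes, reactivated, cfg,
                          reference_gene = "ACTB") {
  stopifnot(inherits(cfg, "sim_config"),
            all(reactivated %in% genes))
  withr::with_seed(stream_seed(cfg$seed, "qpcr"), {
    reps <- cfg$qpcr_replicates
    all_genes <- c(genes, reference_gene)
    grid <- tidyr::expand_grid(
      gene = all_genes,
      condition = c("control", "treated"),
      replicate = seq_len(reps)
    )
    base_ct <- setNames(
      c(runif(length(genes), 27, 31), 18), all_genes)
    grid |>
      mutate(
        shift = ifelse(.data$gene %in% reactivated &
                         .data$condition == "treated",
                       cfg$qpcr_delta_ct, 0),
        ct = base_ct[.data$gene] - .data$shift +
          rnorm(n(), 0, cfg$qpcr_noise_sd)
      ) |>
      select("gene", "condition", "replicate", "ct")
  })
}
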