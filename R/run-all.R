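## End-to-end analysis graph: scoring -> diversity -> per-diet-variable
## alpha associations and PERMANOVA -> dbRDA on the significant components
## -> extreme-decile ANOSIM -> per-taxon scans -> KO scan for the HFC score.

DIET_VARIABLES <- c("hfc_score", "fiber_score", "breads", "vegetables",
                    "fruits", "berries", "juices", "fish", "poultry",
                    "low_fat_cheeses", "dressings_oils", "nuts_seeds",
                    "red_processed_meat")

#' Run the full diet-microbiome analysis graph
#'
#' Reads the four input tables (FPQ responses, covariates, genus abundance,
#' KO abundance), scores the FPQ (participants with missing items are
#' excluded listwise), aligns all inputs by sample ID (intersection taken,
#' mismatches logged), and emits per diet variable (HFC score, combined
#' fiber sources score, and the 11 components): a covariate-adjusted alpha
#' diversity association and a PERMANOVA on Bray-Curtis distances; plus one
#' dbRDA constrained on the PERMANOVA-significant components and the
#' covariates, one extreme-decile ANOSIM on the HFC score, one per-taxon
#' scan per diet variable (BH-corrected within scan), and one KO scan for
#' the HFC score. All outputs are tidy TSVs stamped with the configuration
#' hash; a JSON run log records seed, thresholds and package version.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   the same entries.
#' @return (Invisibly) the result bundle: scores, distance matrix, result
#'   tables and file paths.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config_from_list(config)
  ## hash covers the analysis-relevant settings (not where results land)
  cfg_for_hash <- unclass(config)
  hash <- config_hash(cfg_for_hash[sort(setdiff(names(cfg_for_hash),
                                                "output_dir"))])
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- load and pre-flight ----
  fpq <- read_sample_table(config$fpq, id_column = "participant_id")
  cov <- read_sample_table(config$covariates)
  missing_cov <- setdiff(config$covariate_terms, names(cov))
  if (length(missing_cov))
    stop_dietbiome("[covariates] missing column(s): ",
                   paste(missing_cov, collapse = ", "))
  X <- read_abundance_table(config$abundance)
  K <- read_abundance_table(config$ko)
  items <- if (is.null(config$scoring_config)) default_food_items()
           else read_scoring_config(config$scoring_config)

  ## ---- scoring and alignment ----
  scores <- suppressMessages(score_fpq(fpq, items))
  n_incomplete <- sum(!scores$complete)
  scores <- scores[scores$complete, ]
  ids <- Reduce(intersect, list(scores$participant_id, cov$sample_id,
                                rownames(X), rownames(K)))
  ids <- sort(ids)
  dropped <- length(unique(c(scores$participant_id, cov$sample_id,
                             rownames(X), rownames(K)))) - length(ids)
  if (length(ids) < 20L)
    stop_dietbiome("[alignment] fewer than 20 samples shared across inputs")
  scores <- scores[match(ids, scores$participant_id), ]
  cov <- cov[match(ids, cov$sample_id), ]
  X <- X[ids, , drop = FALSE]
  K <- K[ids, , drop = FALSE]
  covariate_df <- cov[config$covariate_terms]
  rownames(covariate_df) <- ids

  ## ---- diversity ----
  X <- to_relative_abundance(X)
  shannon <- shannon_index(X)
  D <- bray_curtis_matrix(X)
  seed <- config$seed

  ## ---- per-diet-variable alpha + PERMANOVA ----
  diet_vars <- intersect(DIET_VARIABLES, names(scores))
  design_base <- cbind(sample_id = ids, covariate_df)
  alpha_tab <- do.call(rbind, lapply(diet_vars, function(v) {
    fit_linear_association(shannon, scores[[v]], covariate_df,
                           feature_id = v)
  }))
  names(alpha_tab)[1] <- "diet_variable"

  permanova_tab <- do.call(rbind, lapply(diet_vars, function(v) {
    dd <- design_base
    dd[[v]] <- scores[[v]]
    fit <- permanova(D, dd, c(config$covariate_terms, v),
                     n_perm = config$permutations, seed = seed)
    row <- fit$aov_tab[fit$aov_tab$term == v, ]
    data.frame(diet_variable = v, df = row$df, SS = row$SS, R2 = row$R2,
               F = row$F, p = row$p, stringsAsFactors = FALSE)
  }))

  ## ---- dbRDA on significant components + covariates ----
  sig_components <- setdiff(
    permanova_tab$diet_variable[permanova_tab$p < 0.05],
    c("hfc_score", "fiber_score"))
  dbrda_terms <- c(config$covariate_terms, sig_components)
  dd <- design_base
  for (v in sig_components) dd[[v]] <- scores[[v]]
  dbrda_fit <- if (length(sig_components))
    dbrda(D, dd, dbrda_terms, n_perm = config$permutations, seed = seed)
  else NULL

  ## ---- extreme-decile ANOSIM on the HFC score ----
  hfc <- stats::setNames(scores$hfc_score, ids)
  deciles <- extreme_decile_groups(hfc)
  Dsub <- D[deciles$sample_id, deciles$sample_id]
  class(Dsub) <- class(D)
  anosim_fit <- anosim(Dsub, stats::setNames(deciles$group,
                                             deciles$sample_id),
                       n_perm = config$permutations, seed = seed)

  ## ---- per-taxon scans (BH within each scan) ----
  taxa_scans <- lapply(diet_vars, function(v) {
    per_taxon_scan(X, stats::setNames(scores[[v]], ids), covariate_df,
                   detection = config$detection,
                   prevalence = config$prevalence, fdr = config$fdr)
  })
  names(taxa_scans) <- diet_vars

  ## ---- KO scan for the HFC score ----
  ko_fit <- ko_scan(K, hfc, covariate_df, pseudocount = config$pseudocount)

  ## ---- outputs ----
  out <- function(name) file.path(config$output_dir, name)
  write_result_table(scores, out("diet_scores.tsv"), hash)
  write_result_table(data.frame(sample_id = ids, shannon = shannon),
                     out("alpha_diversity.tsv"), hash)
  write_distance_matrix(D, out("bray_curtis.tsv"))
  write_result_table(alpha_tab, out("alpha_associations.tsv"), hash)
  write_result_table(permanova_tab, out("permanova.tsv"), hash)
  if (!is.null(dbrda_fit)) {
    write_result_table(
      data.frame(term = rownames(dbrda_fit$biplot_scores),
                 dbrda_fit$biplot_scores, check.names = FALSE),
      out("dbrda_biplot.tsv"), hash)
    write_result_table(
      data.frame(constrained_prop = dbrda_fit$constrained_prop,
                 F = dbrda_fit$F, p = dbrda_fit$p),
      out("dbrda_summary.tsv"), hash)
  }
  write_result_table(
    data.frame(R = anosim_fit$statistic, p = anosim_fit$p,
               n_low = sum(deciles$group == "low"),
               n_high = sum(deciles$group == "high")),
    out("anosim_extreme_deciles.tsv"), hash)
  for (v in diet_vars)
    write_result_table(taxa_scans[[v]],
                       out(sprintf("taxa_scan_%s.tsv", v)), hash)
  write_result_table(ko_fit$all, out("ko_scan_hfc.tsv"), hash)
  write_result_table(ko_fit$positive, out("ko_scan_hfc_positive.tsv"), hash)
  write_result_table(ko_fit$negative, out("ko_scan_hfc_negative.tsv"), hash)

  log <- list(config_hash = hash, seed = seed,
              permutations = config$permutations,
              detection = config$detection, prevalence = config$prevalence,
              fdr = config$fdr,
              n_samples = length(ids),
              n_incomplete_fpq = n_incomplete,
              n_unmatched_ids = dropped,
              n_core_taxa = nrow(taxa_scans[[1]]),
              package_version = as.character(utils::packageVersion("dietbiome")))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(scores = scores, shannon = shannon, distance = D,
                 alpha = alpha_tab, permanova = permanova_tab,
                 dbrda = dbrda_fit, anosim = anosim_fit,
                 taxa_scans = taxa_scans, ko = ko_fit, log = log,
                 output_dir = config$output_dir))
}

#' Write the four synthetic input tables plus a truth manifest
#'
#' Convenience wrapper used by the command-line `simulate` subcommand and
#' the test suite: simulates a cohort, abundance and KO tables, and writes
#' them in the formats [run_all()] consumes, together with a JSON manifest
#' of the generator's ground truth (planted effects, loadings, seed).
#'
#' @param dir Output directory.
#' @param spec A [cohort_spec()].
#' @param effects An [effect_spec()].
#' @param n_taxa,n_kos Panel sizes.
#' @param seed Integer seed.
#' @return (Invisibly) the list of file paths.
#' @export
simulate_inputs <- function(dir, spec = cohort_spec(),
                            effects = effect_spec(), n_taxa = 191L,
                            n_kos = 200L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec, seed = seed)
  X <- simulate_abundances(cohort, effects, n_taxa = n_taxa, seed = seed)
  K <- simulate_ko_table(cohort, effects, n_kos = n_kos, seed = seed)
  paths <- list(fpq = file.path(dir, "fpq_responses.tsv"),
                covariates = file.path(dir, "covariates.tsv"),
                abundance = file.path(dir, "abundance.tsv"),
                ko = file.path(dir, "ko.tsv"),
                manifest = file.path(dir, "truth_manifest.json"))
  utils::write.table(cohort$responses, paths$fpq, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$covariates, paths$covariates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_abundance_table(X, paths$abundance)
  write_abundance_table(K, paths$ko)
  manifest <- list(seed = seed, n_participants = spec$n_participants,
                   loading = spec$loading,
                   female_shift = spec$female_shift,
                   alpha_beta = effects$alpha_beta,
                   covariate_alpha_betas = as.list(effects$covariate_alpha_betas),
                   planted_taxa = effects$planted_taxa,
                   planted_kos = effects$planted_kos)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
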