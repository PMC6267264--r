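# End-to-end pipeline: simulate -> build connectomes -> detect modules ->
# verify topology -> cognitive signature -> RSA, fully determined by one
# seed, with every artifact carrying a provenance block.

#' Pipeline run configuration
#'
#' Bundles and validates every tunable parameter of the demo pipeline.
#' Defaults follow the study conditions the pipeline emulates: 43 ROIs,
#' 5 planted modules, 24 structural subjects, 78 functional subjects
#' (motion-censored at 3 mm / 1 degree), 3 task studies, individual Poisson
#' threshold at alpha = 0.05, inclusive half-cohort group consistency.
#'
#' @param seed master seed for every source of randomness.
#' @param n_rois,n_modules parcellation size and planted module count.
#' @param n_subjects_struct,n_subjects_func,n_subjects_task cohort sizes.
#' @param n_studies number of task-fMRI studies.
#' @param within_edge_prob,between_edge_prob,streamline_scale,lambda_noise,
#'   ts_length,within_corr,beta_noise_sd generator parameters, see
#'   [planted_design()].
#' @param alpha individual Poisson-threshold significance level.
#' @param min_fraction group-consistency fraction in (0, 1].
#' @param combine directional combination rule, `"mean"` or `"max"`.
#' @param lambda_estimator Poisson rate estimator.
#' @param n_iter Louvain restarts for module detection.
#' @param verify_density density at which the weighted functional network
#'   is binarized for small-world verification.
#' @param n_null rewired null graphs for small-world verification.
#' @param zscore_scope z-scoring scope for signatures.
#' @param n_comparisons Bonferroni family size for RSA.
#' @param rsa_n_perm label permutations for the model-to-model comparison.
#' @param verify run the small-world verification stage.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_rois = 43L, n_modules = 5L,
                       n_subjects_struct = 24L, n_subjects_func = 78L,
                       n_subjects_task = 20L, n_studies = 3L,
                       within_edge_prob = 0.9, between_edge_prob = 0.05,
                       streamline_scale = 20000L, lambda_noise = 2,
                       ts_length = 128L, within_corr = 0.8,
                       beta_noise_sd = 0.5,
                       alpha = 0.05, min_fraction = 0.5,
                       combine = "mean",
                       lambda_estimator = "nonzero_mean",
                       n_iter = 100L,
                       verify_density = 0.2, n_null = 20L,
                       zscore_scope = "study",
                       n_comparisons = 6L, rsa_n_perm = 2000L,
                       verify = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  if (verify_density <= 0 || verify_density > 1) {
    stop("verify_density must be in (0, 1]", call. = FALSE)
  }
  if (within_corr < 0 || within_corr >= 1) stop("within_corr must be in [0, 1)", call. = FALSE)
  if (n_subjects_struct < 2 || n_subjects_func < 2 || n_subjects_task < 2) {
    stop("all cohorts need at least 2 subjects", call. = FALSE)
  }
  combine <- match.arg(combine, c("mean", "max"))
  lambda_estimator <- match.arg(lambda_estimator, c("nonzero_mean", "all_mean"))
  zscore_scope <- match.arg(zscore_scope, c("study", "contrast"))
  cfg$combine <- combine
  cfg$lambda_estimator <- lambda_estimator
  cfg$zscore_scope <- zscore_scope
  structure(cfg, class = "run_config")
}

pipeline_design <- function(cfg, n_subjects, seed_shift = 0L) {
  planted_design(
    roi_set = cfg$n_rois,
    true_partition = balanced_partition(roi_set(cfg$n_rois), cfg$n_modules),
    n_subjects = n_subjects,
    seed = (cfg$seed + seed_shift) %% 2147483647,
    within_edge_prob = cfg$within_edge_prob,
    between_edge_prob = cfg$between_edge_prob,
    streamline_scale = cfg$streamline_scale,
    lambda_noise = cfg$lambda_noise,
    ts_length = cfg$ts_length,
    within_corr = cfg$within_corr,
    beta_noise_sd = cfg$beta_noise_sd
  )
}

#' Run the full pipeline on a simulated dataset
#'
#' Generates structural, functional and task cohorts from the planted
#' design, builds the group binary (double-thresholded) and weighted
#' (Fisher-z averaged) connectomes, detects modules in both, optionally
#' verifies small-world topology against rewired nulls, computes each
#' study's cognitive signature for both recovered partitions, and runs
#' group RSA of the individual activation RDMs against both recovered
#' model RDMs plus the planted-truth model RDM, ending with the
#' model-to-model comparison. Identical configurations (including the
#' seed) give identical result bundles.
#'
#' @param cfg a [run_config()].
#' @return list bundle with elements `design`, `structural`
#'   (`connectome`, `partition`, `ari`), `functional` (`connectome`,
#'   `partition`, `ari`, `censoring`), `verification`, `signatures`,
#'   `rsa`, `model_comparison`, `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  design <- pipeline_design(cfg, cfg$n_subjects_struct)

  # --- structural branch: double threshold then binary modularity
  struct_cohort <- generate_structural_cohort(design)
  subject_binary <- lapply(struct_cohort, function(m) {
    poisson_threshold(combine_directional(m, rule = cfg$combine),
                      alpha = cfg$alpha, lambda_estimator = cfg$lambda_estimator)
  })
  struct_conn <- group_consistency(subject_binary, min_fraction = cfg$min_fraction)
  struct_part <- detect_modules(struct_conn$adjacency, mode = "binary",
                                n_iter = cfg$n_iter,
                                seed = stream_seed(cfg$seed, "graph"))
  struct_ari <- mclust::adjustedRandIndex(struct_part$assignment[names(design$true_partition)],
                                          design$true_partition)

  # --- functional branch: censor, correlate, Fisher-z average, weighted modularity
  func_design <- pipeline_design(cfg, cfg$n_subjects_func, seed_shift = 1L)
  func_cohort <- generate_functional_cohort(func_design)
  cens <- censor_subjects(func_cohort)
  subject_corr <- lapply(cens$included, subject_functional_matrix)
  func_conn <- group_functional_matrix(subject_corr)
  func_part <- detect_modules(func_conn$weights, mode = "weighted",
                              n_iter = cfg$n_iter,
                              seed = stream_seed(cfg$seed, "graph") + 1)
  func_ari <- mclust::adjustedRandIndex(func_part$assignment[names(design$true_partition)],
                                        design$true_partition)

  # --- topology verification against degree-preserving nulls
  verification <- NULL
  if (isTRUE(cfg$verify)) {
    func_bin <- threshold_at_density(func_conn, cfg$verify_density)
    verification <- list(
      structural = small_worldness(
        struct_conn$adjacency,
        rewire_null(struct_conn$adjacency, n = cfg$n_null,
                    seed = stream_seed(cfg$seed, "graph") + 2)),
      functional = small_worldness(
        func_bin,
        rewire_null(func_bin, n = cfg$n_null,
                    seed = stream_seed(cfg$seed, "graph") + 3))
    )
  }

  # --- task betas, cognitive signatures, RSA
  task_design <- pipeline_design(cfg, cfg$n_subjects_task, seed_shift = 2L)
  studies <- generate_task_betas(task_design, n_studies = cfg$n_studies)
  signatures <- lapply(studies, function(b) {
    list(structural = network_activity(b, struct_part, cfg$zscore_scope),
         functional = network_activity(b, func_part, cfg$zscore_scope))
  })
  names(signatures) <- vapply(studies, function(b) b$study_id, "")

  model_struct <- model_rdm(struct_part)
  model_func <- model_rdm(func_part)
  model_true <- model_rdm(as_partition(design$true_partition))
  rsa <- lapply(seq_along(studies), function(i) {
    rdms <- subject_rdms(studies[[i]])
    list(structural = group_rsa(rdms, model_struct, cfg$n_comparisons),
         functional = group_rsa(rdms, model_func, cfg$n_comparisons),
         true_model = group_rsa(rdms, model_true, cfg$n_comparisons),
         # no-correspondence control: per-subject label-shuffled model
         shuffled_model = group_rsa(rdms, model_true, cfg$n_comparisons,
                                    shuffle_labels = TRUE,
                                    seed = stream_seed(cfg$seed, "rsa") + i))
  })
  names(rsa) <- names(signatures)

  model_comparison <- compare_model_rdms(model_struct, model_func,
                                         n_perm = cfg$rsa_n_perm,
                                         seed = stream_seed(cfg$seed, "rsa"))

  bundle <- list(design = design,
                 structural = list(connectome = struct_conn,
                                   partition = struct_part,
                                   ari = struct_ari),
                 functional = list(connectome = func_conn,
                                   partition = func_part,
                                   ari = func_ari,
                                   censoring = cens$report),
                 verification = verification,
                 signatures = signatures,
                 rsa = rsa,
                 model_comparison = model_comparison,
                 config = cfg)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

provenance_block <- function(cfg) {
  prov <- unclass(cfg)
  prov$out_dir <- NULL
  list(config = prov,
       package = "connsig",
       version = as.character(utils::packageVersion("connsig")))
}

#' Write a pipeline result bundle to disk
#'
#' Writes the group matrices as TSV, partitions as JSON, and a summary
#' JSON (ARIs, small-world ratios, RSA statistics) with a provenance block
#' echoing the full configuration.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(bundle$structural$connectome$adjacency,
               file.path(dir, "structural_adjacency.tsv"))
  write_matrix(bundle$functional$connectome$weights,
               file.path(dir, "functional_weights.tsv"))
  write_partition(bundle$structural$partition, file.path(dir, "structural_partition.json"))
  write_partition(bundle$functional$partition, file.path(dir, "functional_partition.json"))
  summary <- list(
    provenance = provenance_block(bundle$config),
    structural_ari = bundle$structural$ari,
    functional_ari = bundle$functional$ari,
    verification = bundle$verification,
    rsa = lapply(bundle$rsa, function(st) lapply(st, function(r) {
      list(mean_rho = r$mean_rho, p_uncorrected = r$p_uncorrected,
           p_corrected = r$p_corrected)
    })),
    model_comparison = bundle$model_comparison
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
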