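## End-to-end synthetic pipeline ----------------------------------------------

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage on generated inputs with planted ground truth:
#' simulate gene models and write/read them as GTF; build splice graphs and
#' enumerate the event catalog; simulate Dirichlet-multinomial feature
#' counts with inclusion changes planted on a fraction of events;
#' write/read the feature count table, attach counts and run the DAS test;
#' derive the disease splicing signature; generate a splicing-factor
#' compendium whose planted factors overlap the true disease signature and
#' compare signatures (splicing and expression paths); fit the
#' design-covariate linear models on simulated metadata, normalize and
#' correlate the counts. Every stage output is written under `out_dir`
#' together with a run manifest, and reruns with the same config are
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param planted_frac Fraction of enumerated events given a true
#'   inclusion change of magnitude `config$delta_psi_true` (random sign).
#' @param dpsi_cut,q_cut DAS calling thresholds.
#' @param lfc_bp |log2FC| threshold for the disease expression signature.
#' @param q_candidate Candidate threshold for signature comparisons.
#' @return List: `das_results`, `das_calls`, `splicing_results`,
#'   `expression_results`, `meta` (fits, normalized counts, correlation),
#'   `truth`, `manifest` (paths of stage outputs).
#' @export
run_pipeline <- function(config, out_dir, planted_frac = 0.1,
                         dpsi_cut = 0.05, q_cut = 0.05, lfc_bp = 0.5,
                         q_candidate = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  .check_number(planted_frac, "planted_frac", lower = 0, upper = 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  outfile <- function(nm) {
    paths[[nm]] <<- file.path(out_dir, nm)
    paths[[nm]]
  }

  ## stage 1: gene models -> GTF
  gm <- gen_gene_models(config)
  write_gtf(gm$genes, outfile("annotation.gtf"))

  ## stage 2: splice graphs -> event catalog
  genes <- read_gtf(paths$annotation.gtf)
  events <- do.call(rbind, lapply(genes, function(g)
    enumerate_events(build_splice_graph(g))))
  rownames(events) <- NULL
  .write_tsv(events, outfile("events.tsv"))

  ## stage 3: planted DMN counts -> feature count table
  set.seed(.module_seed(config$seed, "pipeline"))
  n_pl <- round(planted_frac * nrow(events))
  planted_ev <- sample(events$event_id, n_pl)
  delta <- stats::setNames(
    sample(c(-1, 1), n_pl, replace = TRUE) * config$delta_psi_true,
    planted_ev)
  sim <- gen_event_counts(config, event_ids = events$event_id,
                          delta_psi = delta,
                          n_features = as.matrix(events[c("n_inc", "n_exc")]))
  fc <- sim_feature_counts(events, sim$counts)
  .write_tsv(fc, outfile("feature_counts.tsv"))

  ## stage 4: counts -> DAS test
  fc_in <- read_counts(paths$feature_counts.tsv)
  conditions <- data.frame(
    sample_id = sim$counts[[1L]]$sample_id,
    condition = sim$counts[[1L]]$condition, stringsAsFactors = FALSE)
  ecs <- assign_counts(events, fc_in, conditions)
  das <- das_test(ecs, baseline = sim$conditions[1L])
  das$type <- events$type[match(das$event_id, events$event_id)]
  .write_tsv(das, outfile("das_results.tsv"))
  calls <- call_das(das, dpsi_cut, q_cut)

  ## stage 5: splicing signature comparison against a planted compendium
  disease_meta <- perturbation_meta("disease_cmp", "disease", sign = 1,
                                    tissue = "synthetic")
  disease_sig <- splicing_signature(das, disease_meta, dpsi_cut, q_cut)
  truth_states <- ifelse(sim$truth$true_delta_psi > 0, "+",
                         ifelse(sim$truth$true_delta_psi < 0, "-", "0"))
  names(truth_states) <- sim$truth$event_id
  tested_universe <- das$event_id[das$tested]
  comp <- gen_compendium(
    config,
    disease_states = truth_states[tested_universe][
      truth_states[tested_universe] != "0"],
    universe = tested_universe)
  compendium <- lapply(seq_len(nrow(comp$meta)), function(j) {
    meta <- perturbation_meta(comp$meta$comparison_id[j],
                              comp$meta$factor_id[j], comp$meta$sign[j],
                              comp$meta$tissue[j])
    list(signature = splicing_signature(comp$sf_tables[[j]], meta,
                                        dpsi_cut, q_cut),
         meta = meta)
  })
  spl_res <- compare_splicing(disease_sig, compendium, q_cut = q_candidate)
  .write_tsv(spl_res, outfile("splicing_comparison.tsv"))

  ## stage 6: expression signature comparison
  deg <- gen_deg_tables(config, truth = comp$truth)
  disease_esig <- expression_signature_bp(deg$disease, "disease_cmp",
                                          lfc_cut = lfc_bp)
  ecomp <- lapply(seq_len(nrow(deg$meta)), function(j) {
    meta <- perturbation_meta(deg$meta$comparison_id[j],
                              deg$meta$factor_id[j], deg$meta$sign[j],
                              deg$meta$tissue[j])
    list(signature = expression_signature_sf(deg$sf_tables[[j]], meta),
         meta = meta)
  })
  exp_res <- compare_expression(disease_esig, ecomp, q_cut = q_candidate)
  .write_tsv(exp_res, outfile("expression_comparison.tsv"))

  ## stage 7: design-covariate models on simulated metadata
  mm <- gen_meta(config)
  das_fit <- fit_das_model(mm$meta, mm$das)
  deg_fit <- fit_deg_model(mm$meta, mm$deg)
  kept <- filter_comparisons(mm$meta)
  keep_idx <- match(kept$comparison_id, mm$meta$comparison_id)
  das_fit_f <- fit_das_model(kept, mm$das[keep_idx])
  deg_fit_f <- fit_deg_model(kept, mm$deg[keep_idx])
  norm_das <- normalize_counts(das_fit_f)
  norm_deg <- normalize_counts(deg_fit_f)
  corr <- correlate_normalized(norm_das$normalized, norm_deg$normalized)
  .write_tsv(data.frame(comparison_id = kept$comparison_id,
                        norm_das = norm_das$normalized,
                        norm_deg = norm_deg$normalized),
             outfile("meta_normalized.tsv"))

  ## manifest
  manifest <- list(
    package = "spliceKey",
    version = as.character(utils::packageVersion("spliceKey")),
    seed = config$seed,
    config = unclass(config),
    planted_frac = planted_frac,
    thresholds = list(dpsi = dpsi_cut, q_das = q_cut, lfc_bp = lfc_bp,
                      q_candidate = q_candidate),
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(das_results = das, das_calls = calls,
       splicing_results = spl_res, expression_results = exp_res,
       meta = list(das_fit = das_fit, deg_fit = deg_fit,
                   das_fit_filtered = das_fit_f,
                   deg_fit_filtered = deg_fit_f,
                   normalized = data.frame(comparison_id = kept$comparison_id,
                                           das = norm_das$normalized,
                                           deg = norm_deg$normalized),
                   correlation = corr),
       truth = list(events = sim$truth, compendium = comp$truth,
                    deg = deg$truth, genes = gm$truth),
       manifest = c(paths, manifest = file.path(out_dir, "manifest.json")))
}
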