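#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults describe the reference simulation conditions used
#' throughout the package's tests: moderately deep bulk RNA-seq (about 200
#' reads informative for each splicing event per sample), five biological
#' replicates per condition, replicate-level overdispersion corresponding to
#' a PSI standard deviation of roughly 0.05 at PSI = 0.5 (Dirichlet
#' concentration `precision = 100`), and planted splicing effects of
#' |delta PSI| = 0.2 — well above the 0.05 calling threshold, so recovery
#' tests measure the method rather than raw power.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`. Module-level streams are derived by fixed offsets.
#' @param n_genes Number of synthetic gene models.
#' @param n_events_per_gene Alternative-splicing units per gene model.
#' @param n_samples_per_condition Replicates per condition (two conditions).
#' @param depth Expected informative reads per event per sample; per-sample
#'   totals are Poisson around this value.
#' @param precision Dirichlet-multinomial concentration A = sum(alpha).
#' @param psi_null Baseline inclusion proportion in (0, 1).
#' @param delta_psi_true Planted inclusion change in \[-1, 1\];
#'   `psi_null + delta_psi_true` must stay in \[0, 1\].
#' @param n_sfs Number of splicing-factor perturbation comparisons in the
#'   synthetic compendium.
#' @param n_planted Number of true key factors planted in the compendium.
#' @param overlap_frac Fraction of the disease signature's signed events
#'   (genes) shared, sign-concordantly, with each planted factor.
#' @param lfc_effect Planted |log2 fold change| for signature genes.
#' @param deg_noise_sd Gaussian noise SD added to planted log2 fold changes.
#' @param n_events_universe Size of the abstract event universe used by
#'   [gen_compendium()] when no event catalog is supplied.
#' @param n_genes_universe Size of the expressed-gene background used by
#'   [gen_deg_tables()].
#' @param signature_size Number of signed (+/-) entries per signature, split
#'   evenly between + and -.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 10)
#' cfg$depth
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       n_events_per_gene = 1L,
                       n_samples_per_condition = 5L,
                       depth = 200,
                       precision = 100,
                       psi_null = 0.5,
                       delta_psi_true = 0.2,
                       n_sfs = 10L,
                       n_planted = 2L,
                       overlap_frac = 0.3,
                       lfc_effect = 1,
                       deg_noise_sd = 0.1,
                       n_events_universe = 2000L,
                       n_genes_universe = 2000L,
                       signature_size = 200L) {
  .check_number(seed, "seed", integer = TRUE)
  .check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  .check_number(n_events_per_gene, "n_events_per_gene", lower = 1, integer = TRUE)
  .check_number(n_samples_per_condition, "n_samples_per_condition",
                lower = 1, integer = TRUE)
  .check_number(depth, "depth", lower = 0, strict_lower = TRUE)
  .check_number(precision, "precision", lower = 0, strict_lower = TRUE)
  .check_number(psi_null, "psi_null", lower = 0, upper = 1)
  .check_number(delta_psi_true, "delta_psi_true", lower = -1, upper = 1)
  if (psi_null + delta_psi_true < 0 || psi_null + delta_psi_true > 1)
    stop("'psi_null + delta_psi_true' must lie in [0, 1]", call. = FALSE)
  .check_number(n_sfs, "n_sfs", lower = 1, integer = TRUE)
  .check_number(n_planted, "n_planted", lower = 0, integer = TRUE)
  if (n_planted > n_sfs)
    stop("'n_planted' must not exceed 'n_sfs'", call. = FALSE)
  .check_number(overlap_frac, "overlap_frac", lower = 0, upper = 1)
  .check_number(lfc_effect, "lfc_effect", lower = 0)
  .check_number(deg_noise_sd, "deg_noise_sd", lower = 0)
  .check_number(n_events_universe, "n_events_universe", lower = 1, integer = TRUE)
  .check_number(n_genes_universe, "n_genes_universe", lower = 1, integer = TRUE)
  .check_number(signature_size, "signature_size", lower = 2, integer = TRUE)

  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_events_per_gene = as.integer(n_events_per_gene),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    depth = depth,
    precision = precision,
    psi_null = psi_null,
    delta_psi_true = delta_psi_true,
    n_sfs = as.integer(n_sfs),
    n_planted = as.integer(n_planted),
    overlap_frac = overlap_frac,
    lfc_effect = lfc_effect,
    deg_noise_sd = deg_noise_sd,
    n_events_universe = as.integer(n_events_universe),
    n_genes_universe = as.integer(n_genes_universe),
    signature_size = as.integer(signature_size)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
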