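## Synthetic perturbation compendium ------------------------------------------

.rand_states <- function(n_pos, n_neg, ids) {
  stats::setNames(c(rep("+", n_pos), rep("-", n_neg)),
                  ids[seq_len(n_pos + n_neg)])
}

## Emit a DAS result table realizing the given signature-frame states for a
## perturbation with the given sign: observed delta_psi = frame_state * sign
## * 0.2 for signed events, noise for '0' events.
.states_to_das_table <- function(universe, states, sign, dpsi_mag = 0.2) {
  st <- rep("0", length(universe))
  names(st) <- universe
  st[names(states)] <- states
  signed <- st != "0"
  delta <- stats::runif(length(universe), -0.04, 0.04)
  q <- stats::runif(length(universe), 0.1, 1)
  delta[signed] <- ifelse(st[signed] == "+", 1, -1) * sign * dpsi_mag
  q[signed] <- stats::runif(sum(signed), 0.001, 0.04)
  data.frame(event_id = universe, delta_psi = delta, q = q,
             tested = TRUE, stringsAsFactors = FALSE)
}

#' Generate a synthetic splicing-factor perturbation compendium
#'
#' Builds a disease DAS table plus `config$n_sfs` splicing-factor DAS tables
#' over a shared event universe. `config$n_planted` factors are planted key
#' regulators: a fraction `config$overlap_frac` of the disease signature's
#' signed events reappears in their signatures with concordant sign (after
#' the perturbation-sign convention); the remaining factors are decoys whose
#' signed events are drawn uniformly from the universe, so they overlap the
#' disease signature only at the chance background rate.
#'
#' @param config A [sim_config()].
#' @param disease_states Optional named character vector (`+`/`-`) giving
#'   the disease signature's signed events over a caller-supplied universe;
#'   by default an abstract universe of `config$n_events_universe` events
#'   with `config$signature_size` signed entries is simulated.
#' @param universe Optional event-id universe accompanying
#'   `disease_states`.
#' @return List: `disease` (DAS table), `sf_tables` (named list of DAS
#'   tables), `meta` (data.frame comparison_id, factor_id,
#'   perturbation_type, sign, tissue), `truth` (planted ids, per-factor
#'   shared events, disease states, event assignments).
#' @export
gen_compendium <- function(config, disease_states = NULL, universe = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.module_seed(config$seed, "compendium"))

  if (is.null(disease_states)) {
    universe <- sprintf("EV%05d", seq_len(config$n_events_universe))
    half <- config$signature_size %/% 2L
    picked <- sample(universe, 2L * half)
    disease_states <- .rand_states(half, half, picked)
  } else {
    if (is.null(universe)) universe <- names(disease_states)
    disease_states <- disease_states[disease_states %in% c("+", "-")]
  }
  n_signed <- length(disease_states)
  disease <- .states_to_das_table(universe, disease_states, sign = 1)

  n_shared <- round(config$overlap_frac * n_signed)
  if (config$overlap_frac > 0 && n_shared < 1)
    warning("overlap_frac * signature size < 1: planted factors share no events",
            call. = FALSE)

  sf_ids <- sprintf("SF%02d", seq_len(config$n_sfs))
  planted <- sort(sample(sf_ids, config$n_planted))
  signs <- sample(c(1L, -1L), config$n_sfs, replace = TRUE)
  meta <- data.frame(
    comparison_id = paste0(sf_ids, "_cmp1"),
    factor_id = sf_ids,
    perturbation_type = ifelse(signs == 1L, "OE", "KO"),
    sign = signs,
    tissue = "synthetic",
    stringsAsFactors = FALSE)

  ## factor signatures match the disease signature's size, bounded by the
  ## configured size and by what the universe can accommodate
  half_sf <- min(config$signature_size, n_signed,
                 (length(universe) - n_signed) %/% 2L + n_signed %/% 2L) %/% 2L
  sf_tables <- vector("list", config$n_sfs)
  shared_map <- vector("list", config$n_sfs)
  for (j in seq_len(config$n_sfs)) {
    if (sf_ids[j] %in% planted && n_shared >= 1L) {
      shared <- sample(names(disease_states), n_shared)
      own_pool <- setdiff(universe, names(disease_states))
      n_own <- min(max(0L, 2L * half_sf - n_shared), length(own_pool))
      own <- sample(own_pool, n_own)
      own_states <- stats::setNames(
        sample(c("+", "-"), n_own, replace = TRUE), own)
      states <- c(disease_states[shared], own_states)
    } else {
      picked <- sample(universe, 2L * half_sf)
      states <- .rand_states(half_sf, half_sf, picked)
      shared <- character(0)
    }
    sf_tables[[j]] <- .states_to_das_table(universe, states, sign = signs[j])
    shared_map[[j]] <- shared
  }
  names(sf_tables) <- meta$comparison_id
  names(shared_map) <- sf_ids

  assignment <- rep("null", length(universe))
  names(assignment) <- universe
  assignment[names(disease_states)] <- "disease-only"
  for (sf in planted)
    assignment[shared_map[[sf]]] <- paste0("shared-with-", sf)

  list(disease = disease, sf_tables = sf_tables, meta = meta,
       truth = list(planted_sf_ids = planted,
                    sf_signs = stats::setNames(signs, sf_ids),
                    shared_events = shared_map,
                    disease_states = disease_states,
                    event_assignments = assignment))
}

#' Generate synthetic differential-expression tables
#'
#' Emits a disease (biological-process) DEG table plus one DEG table per
#' splicing-factor comparison over a shared expressed-gene background.
#' Planted factors share `config$overlap_frac` of the disease up and down
#' genes, concordantly after the perturbation-sign convention. Signature
#' genes get `log2FC = +/- config$lfc_effect + Normal(0,
#' config$deg_noise_sd)` (times the perturbation sign in factor tables) and
#' q-values drawn below 0.05; background genes are null. q-values are
#' emitted directly rather than recomputed from a differential-expression
#' test, since that test sits upstream of this package's scope.
#'
#' @param config A [sim_config()].
#' @param truth Optional `truth` element from [gen_compendium()]; reuses
#'   its planted factor ids and perturbation signs so the splicing and
#'   expression compendia describe the same factors.
#' @return List: `disease` (DEG table), `sf_tables` (named list), `meta`,
#'   `truth` (planted ids, per-factor shared genes, disease up/down sets).
#' @export
gen_deg_tables <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.module_seed(config$seed, "deg"))

  genes <- sprintf("G%05d", seq_len(config$n_genes_universe))
  half <- config$signature_size %/% 2L
  picked <- sample(genes, 2L * half)
  disease_up <- picked[seq_len(half)]
  disease_down <- picked[half + seq_len(half)]

  emit <- function(up, down, sign) {
    lfc <- stats::rnorm(length(genes), 0, 0.1)
    q <- stats::runif(length(genes), 0.1, 1)
    iu <- match(up, genes); idn <- match(down, genes)
    lfc[iu] <- sign * (config$lfc_effect +
                         stats::rnorm(length(iu), 0, config$deg_noise_sd))
    lfc[idn] <- sign * (-config$lfc_effect +
                          stats::rnorm(length(idn), 0, config$deg_noise_sd))
    q[c(iu, idn)] <- stats::runif(length(iu) + length(idn), 0.001, 0.04)
    data.frame(gene_id = genes, log2FC = lfc, q = q, expressed = TRUE,
               stringsAsFactors = FALSE)
  }
  disease <- emit(disease_up, disease_down, sign = 1L)

  sf_ids <- if (!is.null(truth)) names(truth$sf_signs) else
    sprintf("SF%02d", seq_len(config$n_sfs))
  signs <- if (!is.null(truth)) unname(truth$sf_signs) else
    sample(c(1L, -1L), config$n_sfs, replace = TRUE)
  planted <- if (!is.null(truth)) truth$planted_sf_ids else
    sort(sample(sf_ids, config$n_planted))
  meta <- data.frame(
    comparison_id = paste0(sf_ids, "_cmp1"),
    factor_id = sf_ids,
    perturbation_type = ifelse(signs == 1L, "OE", "KO"),
    sign = signs,
    tissue = "synthetic",
    stringsAsFactors = FALSE)

  n_shared <- round(config$overlap_frac * half)
  sf_tables <- vector("list", length(sf_ids))
  shared_map <- vector("list", length(sf_ids))
  for (j in seq_along(sf_ids)) {
    if (sf_ids[j] %in% planted && n_shared >= 1L) {
      sh_up <- sample(disease_up, n_shared)
      sh_down <- sample(disease_down, n_shared)
      own_pool <- setdiff(genes, c(disease_up, disease_down))
      own <- sample(own_pool, 2L * (half - n_shared))
      up <- c(sh_up, own[seq_len(half - n_shared)])
      down <- c(sh_down, own[half - n_shared + seq_len(half - n_shared)])
      shared_map[[j]] <- c(sh_up, sh_down)
    } else {
      picked <- sample(genes, 2L * half)
      up <- picked[seq_len(half)]
      down <- picked[half + seq_len(half)]
      shared_map[[j]] <- character(0)
    }
    sf_tables[[j]] <- emit(up, down, sign = signs[j])
  }
  names(sf_tables) <- meta$comparison_id
  names(shared_map) <- sf_ids

  list(disease = disease, sf_tables = sf_tables, meta = meta,
       truth = list(planted_sf_ids = planted,
                    sf_signs = stats::setNames(signs, sf_ids),
                    shared_genes = shared_map,
                    disease_up = disease_up, disease_down = disease_down))
}
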