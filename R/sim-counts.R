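## Synthetic event counts -----------------------------------------------------

#' Generate Dirichlet-multinomial event counts with planted effects
#'
#' For each event and sample, the per-sample total is Poisson around
#' `config$depth` and the two category counts are Multinomial given a
#' Dirichlet-distributed proportion with concentration `config$precision`
#' around the condition's category probabilities. Baseline inclusion is
#' `config$psi_null`; events listed in `delta_psi` get that inclusion shift
#' in the perturbed condition. When an event pools several inclusion (or
#' exclusion) junctions, expected category counts scale with the number of
#' pooled features, mirroring how junction reads accumulate; the PSI
#' averaging convention in [compute_psi()] inverts this exactly.
#'
#' @param config A [sim_config()].
#' @param event_ids Character vector of event ids (default: abstract ids
#'   `EV00001...` of length `config$n_genes * config$n_events_per_gene`).
#' @param delta_psi Named numeric vector (subset of `event_ids`) of planted
#'   inclusion changes; unnamed events are null. Default: none.
#' @param n_features Matrix/data.frame with columns `n_inc`, `n_exc` and one
#'   row per event (default: 1 and 1).
#' @param conditions Length-2 condition labels, baseline first.
#' @return List with `counts` (named list of [event_counts()]),
#'   `conditions`, and `truth` (data.frame event_id, true_delta_psi).
#' @export
gen_event_counts <- function(config, event_ids = NULL, delta_psi = NULL,
                             n_features = NULL,
                             conditions = c("baseline", "perturbed")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(event_ids))
    event_ids <- sprintf("EV%05d", seq_len(config$n_genes * config$n_events_per_gene))
  if (is.null(delta_psi)) delta_psi <- stats::setNames(numeric(0), character(0))
  if (length(delta_psi) && is.null(names(delta_psi)))
    stop("'delta_psi' must be named by event id", call. = FALSE)
  unknown <- setdiff(names(delta_psi), event_ids)
  if (length(unknown))
    stop("'delta_psi' names not in event_ids: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  if (is.null(n_features))
    n_features <- matrix(1L, length(event_ids), 2L,
                         dimnames = list(NULL, c("n_inc", "n_exc")))

  set.seed(.module_seed(config$seed, "counts"))
  ns <- config$n_samples_per_condition
  cond <- rep(conditions, each = ns)
  sample_id <- paste0(rep(conditions, each = ns), "_", rep(seq_len(ns), 2L))

  truth <- data.frame(event_id = event_ids, true_delta_psi = 0)
  truth$true_delta_psi[match(names(delta_psi), event_ids)] <- unname(delta_psi)

  counts <- vector("list", length(event_ids))
  for (i in seq_along(event_ids)) {
    psi <- c(config$psi_null, config$psi_null + truth$true_delta_psi[i])
    if (any(psi <= 0) || any(psi >= 1))
      stop("degenerate inclusion proportion for event ", event_ids[i],
           " (psi must lie strictly in (0, 1))", call. = FALSE)
    ki <- n_features[i, 1L]; ke <- n_features[i, 2L]
    x <- matrix(0L, 2L * ns, 2L)
    for (cidx in 1:2) {
      w <- c(ki * psi[cidx], ke * (1 - psi[cidx]))
      alpha <- config$precision * w / sum(w)
      N <- stats::rpois(ns, config$depth * sum(w))
      x[seq_len(ns) + (cidx - 1L) * ns, ] <- rdirmultinom(ns, N, alpha)
    }
    counts[[i]] <- event_counts(event_ids[i], x, sample_id, cond,
                                n_features = c(ki, ke))
  }
  names(counts) <- event_ids
  list(counts = counts, conditions = conditions, truth = truth)
}

#' Expand event-level counts into a per-feature count table
#'
#' Distributes each event's category counts over its features so that
#' [assign_counts()] recovers the category totals exactly: every feature in
#' a category receives the integer share `floor(total / k)` and the first
#' feature absorbs the remainder.
#'
#' @param events Event catalog from [enumerate_events()].
#' @param counts Named list of [event_counts()] (names = event ids).
#' @return data.frame feature_id, sample_id, count (long format), plus the
#'   per-event category totals as attribute `"ledger"`.
#' @export
sim_feature_counts <- function(events, counts) {
  rows <- list()
  ledger <- list()
  for (i in seq_len(nrow(events))) {
    ec <- counts[[events$event_id[i]]]
    if (is.null(ec)) next
    feats <- list(strsplit(events$inclusion_features[i], ",", fixed = TRUE)[[1L]],
                  strsplit(events$exclusion_features[i], ",", fixed = TRUE)[[1L]])
    for (cat in 1:2) {
      f <- feats[[cat]]
      tot <- ec$counts[, cat]
      base <- floor(tot / length(f))
      extra <- tot - base * length(f)
      for (fi in seq_along(f)) {
        cnt <- base + if (fi == 1L) extra else 0
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = f[fi], sample_id = ec$sample_id, count = cnt,
          stringsAsFactors = FALSE)
      }
    }
    ledger[[length(ledger) + 1L]] <- data.frame(
      event_id = ec$event_id,
      sample_id = ec$sample_id,
      inc = ec$counts[, 1L], exc = ec$counts[, 2L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ## features shared between events would be double-counted; generated gene
  ## models give each event private junctions, but guard anyway
  out <- stats::aggregate(count ~ feature_id + sample_id, out,
                          FUN = function(z) z[1L])
  attr(out, "ledger") <- do.call(rbind, ledger)
  out
}
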