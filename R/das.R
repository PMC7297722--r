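## Differential alternative splicing test -------------------------------------

#' Likelihood-ratio test for one splicing event
#'
#' Compares H0 (one shared Dirichlet-multinomial parameter vector for both
#' conditions) against H1 (a separate vector per condition) and refers
#' `2 * (loglik_H1 - loglik_H0)`, floored at 0, to chi-square with `df = m`
#' (H1 has `2m` free parameters, H0 has `m`).
#'
#' @param ec An [event_counts()] object with exactly two condition labels.
#' @return List: `lrt_stat`, `df`, `p`, `fits` (named per-condition
#'   `dmn_fit`s plus `pooled`), `tested` (FALSE when one condition carries
#'   no reads; then `p = 1` by convention).
#' @export
lrt_event <- function(ec) {
  stopifnot(inherits(ec, "event_counts"))
  conds <- unique(ec$condition)
  if (length(conds) != 2L)
    stop("exactly 2 conditions required, got ", length(conds), call. = FALSE)
  x1 <- ec$counts[ec$condition == conds[1L], , drop = FALSE]
  x2 <- ec$counts[ec$condition == conds[2L], , drop = FALSE]
  m <- ncol(ec$counts)
  if (sum(x1) == 0 || sum(x2) == 0) {
    return(list(lrt_stat = 0, df = m, p = 1, fits = NULL, tested = FALSE))
  }
  f0 <- fit_dmn(rbind(x1, x2))
  f1 <- fit_dmn(x1)
  f2 <- fit_dmn(x2)
  stat <- max(0, 2 * (f1$loglik + f2$loglik - f0$loglik))
  list(lrt_stat = stat, df = m,
       p = stats::pchisq(stat, df = m, lower.tail = FALSE),
       fits = stats::setNames(list(f1, f2, f0), c(conds, "pooled")),
       tested = TRUE)
}

#' Percent-spliced-in from counts and fits
#'
#' Per-sample PSI uses per-junction averaging: when an event pools k
#' inclusion features, the pooled inclusion count is divided by k (and
#' likewise for exclusion) before forming
#' `PSI = inc_avg / (inc_avg + exc_avg)`, so events with more inclusion
#' junctions are not biased upward. Condition-level PSI applies the same
#' correction to the fitted Dirichlet proportions `alpha / sum(alpha)`.
#' `delta_psi` is condition 2 minus condition 1 in the order the condition
#' labels first appear (perturbed minus baseline when supplied that way).
#'
#' @param ec An [event_counts()] object.
#' @param fits Named list of per-condition `dmn_fit`s (as returned in
#'   `lrt_event()$fits`).
#' @return List: `psi_per_sample` (NA for zero-total samples),
#'   `psi_condition` (named length-2), `delta_psi`.
#' @export
compute_psi <- function(ec, fits) {
  stopifnot(inherits(ec, "event_counts"))
  k <- ec$n_features
  inc <- ec$counts[, 1L] / k[1L]
  exc <- ec$counts[, 2L] / k[2L]
  tot <- inc + exc
  psi <- ifelse(tot > 0, inc / tot, NA_real_)
  names(psi) <- ec$sample_id

  conds <- unique(ec$condition)
  psi_cond <- vapply(conds, function(cd) {
    f <- fits[[cd]]
    if (is.null(f)) return(NA_real_)
    pr <- f$alpha / sum(f$alpha)
    (pr[1L] / k[1L]) / (pr[1L] / k[1L] + pr[2L] / k[2L])
  }, 0)
  list(psi_per_sample = psi,
       psi_condition = psi_cond,
       delta_psi = unname(psi_cond[2L] - psi_cond[1L]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * n / j)`, clipped to 1, mapped back to the
#' input order. Stable under permutation of the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.04, 0.5))  # 0.015 0.060 0.500
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Run the DAS test over a collection of events
#'
#' Applies the minimum-coverage rule (events with pooled total below
#' `min_reads` in either condition are reported untested), runs
#' [lrt_event()] and [compute_psi()] per event, and adjusts p-values with
#' [bh_adjust()] across the tested events only.
#'
#' @param event_counts_list List of [event_counts()] objects.
#' @param baseline Condition label to use as baseline; `delta_psi` is the
#'   other condition minus this one. Default: first label encountered.
#' @param min_reads Minimum pooled reads per condition for testing.
#' @return data.frame: event_id, psi_baseline, psi_perturbed, delta_psi,
#'   lrt_stat, df, p, q, tested.
#' @export
das_test <- function(event_counts_list, baseline = NULL, min_reads = 10) {
  stopifnot(length(event_counts_list) >= 1L)
  if (is.null(baseline))
    baseline <- unique(event_counts_list[[1L]]$condition)[1L]
  rows <- lapply(event_counts_list, function(ec) {
    conds <- unique(ec$condition)
    other <- setdiff(conds, baseline)
    if (length(other) != 1L)
      stop("event ", ec$event_id, ": need baseline + one other condition",
           call. = FALSE)
    ## order conditions baseline-first so delta_psi = perturbed - baseline
    ord <- order(ec$condition != baseline)
    ec2 <- event_counts(ec$event_id, ec$counts[ord, , drop = FALSE],
                        ec$sample_id[ord], ec$condition[ord], ec$n_features)
    n1 <- sum(ec2$counts[ec2$condition == baseline, ])
    n2 <- sum(ec2$counts[ec2$condition == other, ])
    if (n1 < min_reads || n2 < min_reads) {
      return(data.frame(event_id = ec$event_id, psi_baseline = NA_real_,
                        psi_perturbed = NA_real_, delta_psi = NA_real_,
                        lrt_stat = NA_real_, df = ncol(ec$counts),
                        p = NA_real_, tested = FALSE))
    }
    lr <- lrt_event(ec2)
    ps <- if (lr$tested) compute_psi(ec2, lr$fits) else
      list(psi_condition = c(NA_real_, NA_real_), delta_psi = NA_real_)
    data.frame(event_id = ec$event_id,
               psi_baseline = unname(ps$psi_condition[1L]),
               psi_perturbed = unname(ps$psi_condition[2L]),
               delta_psi = ps$delta_psi,
               lrt_stat = lr$lrt_stat, df = lr$df, p = lr$p,
               tested = lr$tested)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- NA_real_
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Call differential alternative splicing events
#'
#' Strict thresholds as printed: an event is called when `|delta_psi| >
#' dpsi_cut` AND `q < q_cut` (defaults 0.05 and 0.05).
#'
#' @param results data.frame from [das_test()] (columns event_id,
#'   delta_psi, q, tested; a `type` column, if present, feeds the tally).
#' @param dpsi_cut,q_cut Calling thresholds.
#' @return A `das_calls` list: `called` (event ids), `thresholds`,
#'   `by_type` (per-type tally, when types are available), `n_tested`.
#' @export
call_das <- function(results, dpsi_cut = 0.05, q_cut = 0.05) {
  .check_columns(results, c("event_id", "delta_psi", "q"), "results")
  tested <- if ("tested" %in% names(results)) results$tested else
    !is.na(results$q)
  hit <- tested & !is.na(results$q) &
    abs(results$delta_psi) > dpsi_cut & results$q < q_cut
  by_type <- if ("type" %in% names(results))
    table(factor(results$type[hit], levels = .event_types)) else NULL
  structure(list(called = results$event_id[hit],
                 thresholds = c(dpsi_cut = dpsi_cut, q_cut = q_cut),
                 by_type = by_type,
                 n_tested = sum(tested)),
            class = "das_calls")
}

#' @export
print.das_calls <- function(x, ...) {
  cat(sprintf("das_calls: %d of %d tested events called (|dPSI| > %g, q < %g)\n",
              length(x$called), x$n_tested,
              x$thresholds["dpsi_cut"], x$thresholds["q_cut"]))
  if (!is.null(x$by_type)) print(x$by_type)
  invisible(x)
}
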