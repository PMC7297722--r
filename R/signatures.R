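## Signed splicing / expression signatures ------------------------------------

#' Perturbation metadata for one comparison
#'
#' @param comparison_id Identifier of the experimental comparison.
#' @param factor_id Identifier of the perturbed splicing factor.
#' @param sign `+1` for increased expression of the factor (overexpression,
#'   knockin), `-1` for decreased (knockout, knockdown). Perturbations with
#'   no defined direction (e.g. point mutations) have no sign and must be
#'   given one explicitly by the caller to be usable.
#' @param tissue Free-text tissue/context label.
#' @return A `perturbation_meta` object.
#' @export
perturbation_meta <- function(comparison_id, factor_id, sign,
                              tissue = "") {
  if (!is.numeric(sign) || length(sign) != 1L || !sign %in% c(1, -1))
    stop("'sign' must be +1 (increased expression) or -1 (decreased)",
         call. = FALSE)
  structure(list(comparison_id = comparison_id, factor_id = factor_id,
                 sign = as.integer(sign), tissue = tissue),
            class = "perturbation_meta")
}

#' Build a signed splicing signature from a DAS table
#'
#' An event is positively regulated by the factor (`+`) when it gains
#' inclusion upon increased factor expression or loses inclusion upon
#' decreased expression — i.e. `state = sign(delta_psi) * meta$sign` when
#' `|delta_psi| > dpsi_cut` and `q < q_cut` — and negatively regulated
#' (`-`) in the opposite case; otherwise `0`. Untested events are absent
#' from the universe rather than `0`, keeping "not changed" distinct from
#' "not measured".
#'
#' @param das_table data.frame with columns event_id, delta_psi, q and
#'   optionally `tested`.
#' @param meta A [perturbation_meta()].
#' @param dpsi_cut,q_cut Thresholds (strict, as printed: `|dPSI| > 0.05`,
#'   `q < 0.05`).
#' @return A `splicing_signature`: `comparison_id`, `states` (named `+`/
#'   `-`/`0` over the universe), `universe`.
#' @export
splicing_signature <- function(das_table, meta, dpsi_cut = 0.05,
                               q_cut = 0.05) {
  .check_columns(das_table, c("event_id", "delta_psi", "q"), "das_table")
  stopifnot(inherits(meta, "perturbation_meta"))
  tested <- if ("tested" %in% names(das_table)) das_table$tested else
    !is.na(das_table$q)
  tab <- das_table[tested & !is.na(das_table$q), , drop = FALSE]
  if (anyDuplicated(tab$event_id))
    stop("duplicate event_id in das_table", call. = FALSE)
  signed <- abs(tab$delta_psi) > dpsi_cut & tab$q < q_cut
  st <- rep("0", nrow(tab))
  st[signed] <- ifelse(sign(tab$delta_psi[signed]) * meta$sign > 0, "+", "-")
  structure(list(comparison_id = meta$comparison_id,
                 states = stats::setNames(st, tab$event_id),
                 universe = tab$event_id),
            class = "splicing_signature")
}

#' @export
print.splicing_signature <- function(x, ...) {
  tb <- table(factor(x$states, levels = c("+", "-", "0")))
  cat(sprintf("splicing_signature %s: %d tested events (+%d / -%d / 0:%d)\n",
              x$comparison_id, length(x$universe), tb["+"], tb["-"], tb["0"]))
  invisible(x)
}

.check_deg_table <- function(deg_table) {
  .check_columns(deg_table, c("gene_id", "log2FC", "q", "expressed"),
                 "deg_table")
  if (anyDuplicated(deg_table$gene_id))
    stop("duplicate gene_id in deg_table", call. = FALSE)
  deg_table
}

.expression_signature <- function(comparison_id, tab, up_sel, down_sel,
                                  semantics) {
  structure(list(comparison_id = comparison_id,
                 up = tab$gene_id[up_sel],
                 down = tab$gene_id[down_sel],
                 background = tab$gene_id,
                 semantics = semantics),
            class = "expression_signature")
}

#' Factor-directional expression signature
#'
#' Up = genes positively regulated by the factor: `meta$sign * log2FC >
#' lfc_cut` with `q < q_cut`; down symmetric. The background is the set of
#' expressed genes in the table (genes already past upstream low-count
#' filtering).
#'
#' @param deg_table data.frame: gene_id, log2FC, q, expressed.
#' @param meta A [perturbation_meta()].
#' @param lfc_cut,q_cut Thresholds (strict).
#' @return An `expression_signature` with semantics `"sf-regulated"`.
#' @export
expression_signature_sf <- function(deg_table, meta, lfc_cut = 0.5,
                                    q_cut = 0.05) {
  .check_deg_table(deg_table)
  stopifnot(inherits(meta, "perturbation_meta"))
  de <- abs(deg_table$log2FC) > lfc_cut & deg_table$q < q_cut
  if (any(de & !deg_table$expressed))
    stop("gene flagged differentially expressed but not expressed",
         call. = FALSE)
  tab <- deg_table[deg_table$expressed, , drop = FALSE]
  eff <- meta$sign * tab$log2FC
  keep <- tab$q < q_cut
  .expression_signature(meta$comparison_id, tab,
                        keep & eff > lfc_cut, keep & eff < -lfc_cut,
                        "sf-regulated")
}

#' Direction-of-change expression signature (disease / biological process)
#'
#' Up/down assigned by the raw sign of log2FC, independent of any factor's
#' perturbation direction. `lfc_cut` has no default because applications
#' legitimately vary it (e.g. 0.2 for weak transcriptomic phenotypes, 1.0
#' for strong ones).
#'
#' @param deg_table data.frame: gene_id, log2FC, q, expressed.
#' @param comparison_id Identifier for the comparison.
#' @param lfc_cut Mandatory |log2FC| threshold (strict).
#' @param q_cut q-value threshold (strict).
#' @return An `expression_signature` with semantics `"bp-directional"`.
#' @export
expression_signature_bp <- function(deg_table, comparison_id, lfc_cut,
                                    q_cut = 0.05) {
  if (missing(lfc_cut))
    stop("'lfc_cut' must be given explicitly for a process signature",
         call. = FALSE)
  .check_deg_table(deg_table)
  de <- abs(deg_table$log2FC) > lfc_cut & deg_table$q < q_cut
  if (any(de & !deg_table$expressed))
    stop("gene flagged differentially expressed but not expressed",
         call. = FALSE)
  tab <- deg_table[deg_table$expressed, , drop = FALSE]
  keep <- tab$q < q_cut
  .expression_signature(comparison_id, tab,
                        keep & tab$log2FC > lfc_cut,
                        keep & tab$log2FC < -lfc_cut,
                        "bp-directional")
}

#' @export
print.expression_signature <- function(x, ...) {
  cat(sprintf("expression_signature %s (%s): %d up, %d down, background %d\n",
              x$comparison_id, x$semantics, length(x$up), length(x$down),
              length(x$background)))
  invisible(x)
}
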