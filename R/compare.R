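## Signature comparison with a noncentral Fisher null -------------------------

#' Cross-tabulate two splicing signatures
#'
#' Builds the 3x3 contingency table of event states (+, -, 0) over the
#' intersection of the two signatures' tested universes; rows index the
#' first (disease) signature, columns the second.
#'
#' @param sig_a,sig_b `splicing_signature` objects.
#' @return 3x3 integer matrix with dimnames `+`, `-`, `0`.
#' @export
splicing_contingency <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "splicing_signature"),
            inherits(sig_b, "splicing_signature"))
  shared <- intersect(sig_a$universe, sig_b$universe)
  if (!length(shared))
    stop("no common tested events between signatures", call. = FALSE)
  lv <- c("+", "-", "0")
  tab <- table(factor(sig_a$states[shared], levels = lv),
               factor(sig_b$states[shared], levels = lv))
  m <- matrix(as.integer(tab), 3L, 3L, dimnames = list(lv, lv))
  m
}

#' Collapse a 3x3 state table into the ++ and -- enrichment tables
#'
#' The `++` table focuses on the `+` state: `a = N[+,+]`, `b` = remaining
#' `+` row, `c` = remaining `+` column, `d` = everything else; the `--`
#' table does the same with `-` as the focal state.
#'
#' @param t3 3x3 matrix from [splicing_contingency()].
#' @return List of two 2x2 matrices, `pos` and `neg` (cell order a, b / c,
#'   d).
#' @export
collapse_tables <- function(t3) {
  stopifnot(is.matrix(t3), all(dim(t3) == c(3L, 3L)))
  focus <- function(i) {
    a <- t3[i, i]
    b <- sum(t3[i, ]) - a
    c_ <- sum(t3[, i]) - a
    d <- sum(t3) - a - b - c_
    matrix(c(a, b, c_, d), 2L, 2L, byrow = TRUE,
           dimnames = list(c("focal", "other"), c("focal", "other")))
  }
  list(pos = focus(1L), neg = focus(2L))
}

## Upper-tail probabilities P(X >= a) of Fisher's noncentral hypergeometric
## distribution for every a in the support, given margins (m1 = a+b,
## m2 = c+d, k = a+c) and odds ratio psi. Direct enumeration over the
## support with log-space normalization.
.nchg_tail <- function(m1, m2, k, psi) {
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  x <- lo:hi
  lw <- lchoose(m1, x) + lchoose(m2, k - x) + x * log(psi)
  w <- exp(lw - max(lw))
  tail <- rev(cumsum(rev(w))) / sum(w)
  list(support = x, tail = pmin(tail, 1))
}

#' One-sided Fisher test under a noncentral (log-odds-ratio) null
#'
#' Tests enrichment of the concordant cell `a` against the null hypothesis
#' that the log odds ratio is below `log_or_null`: the p-value is
#' `P(X >= a)` under Fisher's noncentral hypergeometric distribution with
#' the table's margins and odds ratio `psi0 = log_base ^ log_or_null`
#' (natural log by default, so `psi0 = exp(0.5) ~ 1.649`). With
#' `log_or_null = 0` this reduces to the classical one-sided Fisher exact
#' test. The reported odds ratio is the sample `ad/bc`, Haldane-corrected
#' (+0.5 per cell) and flagged when any cell is zero; p-values never use
#' the correction, the exact enumeration handles zeros natively.
#'
#' @param t2 2x2 matrix (or length-4 vector a, b, c, d) of non-negative
#'   counts; `a` is the concordant cell.
#' @param log_or_null Null log-odds-ratio boundary (default 0.5).
#' @param log_base Base of the logarithm in the null (default `exp(1)`).
#' @return List: `p`, `odds_ratio`, `haldane` (flag), `psi0`,
#'   `degenerate` (all margins zero; then `p = 1` by convention).
#' @export
#' @examples
#' fisher_noncentral_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
#'                     log_or_null = 0)$p  # 17/70
fisher_noncentral_p <- function(t2, log_or_null = 0.5, log_base = exp(1)) {
  x <- as.vector(if (is.matrix(t2)) t(t2) else t2)
  if (length(x) != 4L || any(x < 0) || any(!is.finite(x)))
    stop("'t2' must hold 4 non-negative counts", call. = FALSE)
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  psi0 <- log_base^log_or_null
  if (sum(x) == 0)
    return(list(p = 1, odds_ratio = NA_real_, haldane = NA, psi0 = psi0,
                degenerate = TRUE))
  haldane <- any(x == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  nt <- .nchg_tail(a + b, c_ + d, a + c_, psi0)
  p <- nt$tail[match(a, nt$support)]
  list(p = p, odds_ratio = or, haldane = haldane, psi0 = psi0,
       degenerate = FALSE)
}

.bh_flag <- function(df, q_cut) {
  df$q <- NA_real_
  ok <- !is.na(df$p)
  df$q[ok] <- bh_adjust(df$p[ok])
  df$candidate <- !is.na(df$q) & df$q < q_cut
  df[order(df$q, df$p), , drop = FALSE]
}

#' Compare a disease splicing signature against a compendium
#'
#' For each splicing-factor comparison, builds the 3x3 state table on the
#' shared tested universe, collapses it into the ++ and -- tables, tests
#' each with [fisher_noncentral_p()], then adjusts all p-values of the
#' disease comparison jointly (both directions, all factors) with
#' Benjamini-Hochberg. Candidates are tests with `q < q_cut`.
#'
#' @param disease_sig A `splicing_signature`.
#' @param compendium List of elements each holding `signature` (a
#'   `splicing_signature`) and `meta` (a [perturbation_meta()]).
#' @param log_or_null,log_base Null boundary, see [fisher_noncentral_p()].
#' @param q_cut Candidate threshold (strict; default 0.25).
#' @return data.frame, sorted by (q, p): disease_comparison_id,
#'   sf_comparison_id, factor_id, direction (`concordant-positive` /
#'   `concordant-negative`), a, b, c, d, odds_ratio, haldane, p, q,
#'   candidate.
#' @export
compare_splicing <- function(disease_sig, compendium, log_or_null = 0.5,
                             log_base = exp(1), q_cut = 0.25) {
  stopifnot(inherits(disease_sig, "splicing_signature"),
            length(compendium) >= 1L)
  rows <- lapply(compendium, function(el) {
    sig <- el$signature; meta <- el$meta
    res <- try(splicing_contingency(disease_sig, sig), silent = TRUE)
    base <- data.frame(disease_comparison_id = disease_sig$comparison_id,
                       sf_comparison_id = meta$comparison_id,
                       factor_id = meta$factor_id,
                       direction = c("concordant-positive",
                                     "concordant-negative"),
                       a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                       odds_ratio = NA_real_, haldane = NA,
                       p = NA_real_, stringsAsFactors = FALSE)
    if (inherits(res, "try-error")) return(base)  # untested, excluded from BH
    cl <- collapse_tables(res)
    for (i in 1:2) {
      t2 <- cl[[i]]
      ft <- fisher_noncentral_p(t2, log_or_null, log_base)
      base[i, c("a", "b", "c", "d")] <- as.vector(t(t2))
      base$odds_ratio[i] <- ft$odds_ratio
      base$haldane[i] <- ft$haldane
      base$p[i] <- ft$p
    }
    base
  })
  .bh_flag(do.call(rbind, rows), q_cut)
}

#' Compare a disease expression signature against a compendium
#'
#' The universe is the intersection of all backgrounds. For each factor
#' comparison and each requested disease side (default: up-regulated
#' genes), two 2x2 overlap tables are tested — disease side vs the
#' factor's up set and vs its down set — with [fisher_noncentral_p()];
#' Benjamini-Hochberg is applied over the pooled p-values of the disease
#' comparison.
#'
#' @param disease_sig An `expression_signature`.
#' @param compendium List of elements with `signature` (an
#'   `expression_signature`) and `meta` (a [perturbation_meta()]).
#' @param disease_sides Subset of `c("up", "down")`.
#' @param log_or_null,log_base,q_cut See [compare_splicing()].
#' @return data.frame, sorted by (q, p), one row per (factor, disease
#'   side, factor side) test; `direction` is e.g. `"up-vs-up"`.
#' @export
compare_expression <- function(disease_sig, compendium,
                               disease_sides = "up", log_or_null = 0.5,
                               log_base = exp(1), q_cut = 0.25) {
  stopifnot(inherits(disease_sig, "expression_signature"),
            length(compendium) >= 1L)
  disease_sides <- match.arg(disease_sides, c("up", "down"),
                             several.ok = TRUE)
  rows <- lapply(compendium, function(el) {
    sig <- el$signature; meta <- el$meta
    universe <- intersect(disease_sig$background, sig$background)
    if (!length(universe))
      stop("empty background intersection with ", meta$comparison_id,
           call. = FALSE)
    out <- list()
    for (ds in disease_sides) for (ss in c("up", "down")) {
      A <- intersect(disease_sig[[ds]], universe)
      B <- intersect(sig[[ss]], universe)
      a <- length(intersect(A, B))
      b <- length(A) - a
      c_ <- length(B) - a
      d <- length(universe) - a - b - c_
      ft <- fisher_noncentral_p(c(a, b, c_, d), log_or_null, log_base)
      out[[length(out) + 1L]] <- data.frame(
        disease_comparison_id = disease_sig$comparison_id,
        sf_comparison_id = meta$comparison_id,
        factor_id = meta$factor_id,
        direction = paste0(ds, "-vs-", ss),
        a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, haldane = ft$haldane, p = ft$p,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  .bh_flag(do.call(rbind, rows), q_cut)
}
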