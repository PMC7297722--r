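# Independent oracles used to cross-check the package's own implementations.
# Each one deliberately takes a different computational route from the code
# under test.

# --- brute-force event oracle ------------------------------------------------
# Classifies transcript-pair differences by interval arithmetic on exon
# coverage (no splice graph, no segmentation): elementary intervals between
# exon boundaries are labelled by which transcript covers them, coverage
# differences are merged into events, and each event is classified from how
# its pieces attach to commonly covered sequence.
oracle_events <- function(gene) {
  tx <- gene$transcripts
  out <- list()
  combs <- utils::combn(length(tx), 2)
  for (ci in seq_len(ncol(combs))) {
    e1 <- tx[[combs[1, ci]]]
    e2 <- tx[[combs[2, ci]]]
    pts <- sort(unique(c(e1, e2)))
    iv <- cbind(pts[-length(pts)], pts[-1])
    cov <- function(ex, a, b) any(ex[, 1] <= a & ex[, 2] >= b)
    c1 <- vapply(seq_len(nrow(iv)), function(i) cov(e1, iv[i, 1], iv[i, 2]), NA)
    c2 <- vapply(seq_len(nrow(iv)), function(i) cov(e2, iv[i, 1], iv[i, 2]), NA)
    diff_iv <- which(c1 != c2)
    if (!length(diff_iv)) next
    common <- which(c1 & c2)
    L0 <- if (length(common)) iv[min(common), 1] else Inf
    R0 <- if (length(common)) iv[max(common), 2] else -Inf

    # merge contiguous diff intervals into pieces
    pieces <- list()
    cur <- diff_iv[1]
    run <- c(cur)
    for (i in diff_iv[-1]) {
      prev <- run[length(run)]
      if (i == prev + 1 && iv[i, 1] == iv[prev, 2] && c1[i] == c1[prev]) {
        run <- c(run, i)
      } else {
        pieces[[length(pieces) + 1]] <- run
        run <- c(i)
      }
    }
    pieces[[length(pieces) + 1]] <- run

    piece_df <- do.call(rbind, lapply(pieces, function(r) data.frame(
      start = iv[r[1], 1], end = iv[r[length(r)], 2], in1 = c1[r[1]])))

    # group pieces separated by gaps with no common coverage
    has_common_between <- function(a, b)
      any(c1 & c2 & iv[, 1] >= a & iv[, 2] <= b)
    grp <- cumsum(c(TRUE, vapply(seq_len(nrow(piece_df))[-1], function(i)
      has_common_between(piece_df$end[i - 1], piece_df$start[i]), NA)))

    for (g in unique(grp)) {
      pc <- piece_df[grp == g, , drop = FALSE]
      vs <- min(pc$start); ve <- max(pc$end)
      strand <- gene$strand
      if (ve <= L0) {
        type <- if (strand == "+") "AFE" else "ALE"
      } else if (vs >= R0) {
        type <- if (strand == "+") "ALE" else "AFE"
      } else if (length(unique(pc$in1)) > 1) {
        # pieces from both transcripts: ME when all junction-bounded
        jb <- vapply(seq_len(nrow(pc)), function(i) {
          lft <- which(iv[, 2] == pc$start[i])
          rgt <- which(iv[, 1] == pc$end[i])
          lcom <- length(lft) && c1[lft] && c2[lft]
          rcom <- length(rgt) && c1[rgt] && c2[rgt]
          !lcom && !rcom
        }, NA)
        type <- if (all(jb)) "ME" else "ES"
      } else {
        lft <- which(iv[, 2] == vs)
        rgt <- which(iv[, 1] == ve)
        lcom <- length(lft) > 0 && c1[lft] && c2[lft]
        rcom <- length(rgt) > 0 && c1[rgt] && c2[rgt]
        type <- if (lcom && rcom) "IR"
          else if (!lcom && !rcom) "ES"
          else if (lcom) { if (strand == "+") "A5SS" else "A3SS" }
          else { if (strand == "+") "A3SS" else "A5SS" }
      }
      out[[length(out) + 1]] <- data.frame(
        gene_id = gene$gene_id, type = type, var_start = vs, var_end = ve)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), type = character(0),
                      var_start = integer(0), var_end = integer(0)))
  unique(do.call(rbind, out))
}

# --- noncentral hypergeometric tail oracle -----------------------------------
# Weights the central hypergeometric pmf (stats::dhyper) by psi^x; the code
# under test instead enumerates log binomial coefficients directly.
nchg_tail_oracle <- function(m1, m2, k, psi) {
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  w <- stats::dhyper(x, m1, m2, k) * psi^x
  list(support = x, tail = rev(cumsum(rev(w))) / sum(w))
}

# --- DMN profile grid oracle -------------------------------------------------
# Profile log-likelihood over an (inclusion proportion, concentration) grid
# for two-category data; returns the grid optimum.
dmn_grid_oracle <- function(x, n_pi = 199, n_A = 121) {
  pis <- seq(0.005, 0.995, length.out = n_pi)
  As <- exp(seq(log(0.5), log(1e6), length.out = n_A))
  best <- -Inf
  for (A in As) {
    ll <- vapply(pis, function(p) dmn_loglik(c(A * p, A * (1 - p)), x), 0)
    best <- max(best, max(ll))
  }
  best
}

# --- independent least-squares oracle (QR, no lm machinery) -----------------
ols_oracle <- function(X, y) unname(drop(qr.coef(qr(X), y)))

# --- small gene-model fixtures ----------------------------------------------
mk_gene <- function(strand = "+", ...) {
  tx <- list(...)
  names(tx) <- paste0("t", seq_along(tx))
  gene_model("g1", "chr1", strand, tx)
}
ex <- function(...) {
  v <- c(...)
  matrix(as.integer(v), ncol = 2, byrow = TRUE)
}
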