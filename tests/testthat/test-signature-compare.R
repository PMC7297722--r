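mk_sig <- function(states, comparison_id = "sig") {
  structure(list(comparison_id = comparison_id, states = states,
                 universe = names(states)),
            class = "splicing_signature")
}

test_that("the 3x3 contingency table tallies shared-universe states", {
  st <- setNames(c(rep("+", 5), rep("-", 3), rep("0", 12)),
                 sprintf("e%02d", 1:20))
  t3 <- splicing_contingency(mk_sig(st), mk_sig(st))
  expect_equal(diag(t3), c(`+` = 5L, `-` = 3L, `0` = 12L))
  expect_equal(sum(t3) - sum(diag(t3)), 0L)

  # a signature with no signed events leaves the first two rows empty
  allz <- setNames(rep("0", 20), names(st))
  t30 <- splicing_contingency(mk_sig(allz), mk_sig(st))
  expect_equal(sum(t30[c("+", "-"), ]), 0L)

  # random paired states against a direct tally
  set.seed(301)
  a <- setNames(sample(c("+", "-", "0"), 200, TRUE), sprintf("e%03d", 1:200))
  b <- setNames(sample(c("+", "-", "0"), 200, TRUE), sprintf("e%03d", 1:200))
  t3r <- splicing_contingency(mk_sig(a), mk_sig(b))
  for (r in c("+", "-", "0")) for (cc in c("+", "-", "0"))
    expect_equal(t3r[r, cc], sum(a == r & b == cc))

  # disjoint universes cannot be compared
  b2 <- setNames(rep("0", 5), sprintf("x%d", 1:5))
  expect_error(splicing_contingency(mk_sig(a), mk_sig(b2)), "no common")
})

test_that("collapsing the 3x3 focuses each signed state and conserves totals", {
  t3 <- matrix(0L, 3, 3, dimnames = list(c("+", "-", "0"), c("+", "-", "0")))
  t3["+", "+"] <- 5L
  cl <- collapse_tables(t3)
  expect_equal(as.vector(t(cl$pos)), c(5, 0, 0, 0))

  diag(t3) <- c(5L, 3L, 12L)
  t3["+", "+"] <- 5L
  cl <- collapse_tables(t3)
  expect_equal(as.vector(t(cl$pos)), c(5, 0, 0, 15))
  expect_equal(as.vector(t(cl$neg)), c(3, 0, 0, 17))

  set.seed(302)
  t3r <- matrix(sample(0:9, 9, TRUE), 3, 3,
                dimnames = list(c("+", "-", "0"), c("+", "-", "0")))
  clr <- collapse_tables(t3r)
  expect_equal(sum(clr$pos), sum(t3r))
  expect_equal(sum(clr$neg), sum(t3r))
  expect_equal(clr$pos[1, 1], t3r["+", "+"])
  expect_equal(clr$pos[1, 2], sum(t3r["+", ]) - t3r["+", "+"])
  expect_equal(clr$pos[2, 1], sum(t3r[, "+"]) - t3r["+", "+"])
})

test_that("noncentral Fisher p-values match enumeration oracles", {
  # central case, worked by hand: support weights C(4,x)C(4,4-x),
  # tail x >= 3 is 17/70
  p <- fisher_noncentral_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
                           log_or_null = 0)$p
  expect_equal(p, 17 / 70, tolerance = 1e-12)

  # minimum of the support: the whole mass is in the tail
  expect_equal(fisher_noncentral_p(c(0, 5, 5, 0))$p, 1)
  # empty table: p = 1 by convention, flagged degenerate
  d <- fisher_noncentral_p(c(0, 0, 0, 0))
  expect_equal(d$p, 1)
  expect_true(d$degenerate)

  set.seed(303)
  for (r in 1:300) {
    t2 <- sample(0:15, 4, TRUE)
    psi <- sample(c(1, exp(0.5), 2), 1)
    mine <- fisher_noncentral_p(t2, log_or_null = log(psi))
    orc <- nchg_tail_oracle(t2[1] + t2[2], t2[3] + t2[4], t2[1] + t2[3], psi)
    expect_equal(mine$p, orc$tail[match(t2[1], orc$support)],
                 tolerance = 1e-12)
    # central case equals the classical one-sided Fisher exact test
    if (psi == 1 && sum(t2) > 0) {
      ft <- fisher.test(matrix(t2, 2, byrow = TRUE), alternative = "greater")
      expect_equal(mine$p, ft$p.value, tolerance = 1e-10)
    }
  }

  # exact rational-arithmetic spot check via an external enumeration
  set.seed(304)
  tabs <- t(replicate(40, sample(0:12, 4, TRUE)))
  writeLines(apply(tabs, 1, paste, collapse = " "), "tabs.txt")
  code <- paste(
    "from math import comb",
    "import decimal",
    "decimal.getcontext().prec = 50",
    "for line in open('tabs.txt'):",
    "    a,b,c,d = map(int, line.split())",
    "    m1, m2, k = a+b, c+d, a+c",
    "    lo, hi = max(0, k-m2), min(k, m1)",
    "    # weights w(x) = C(m1,x) C(m2,k-x) psi^x at psi = e^0.5 (50 digits)",
    "    psi = decimal.Decimal(1).exp() ** decimal.Decimal('0.5')",
    "    ws = [decimal.Decimal(comb(m1,x)*comb(m2,k-x)) * psi**x for x in range(lo,hi+1)]",
    "    tot = sum(ws)",
    "    tail = sum(ws[a-lo:]) / tot if tot else decimal.Decimal(1)",
    "    print(tail)",
    sep = "\n")
  writeLines(code, "nchg_oracle.py")
  res <- suppressWarnings(system2("python", "nchg_oracle.py",
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0)
  exact <- as.numeric(res)
  mine <- apply(tabs, 1, function(t2) fisher_noncentral_p(t2)$p)
  expect_lt(max(abs(mine - exact)), 1e-12)
  file.remove("tabs.txt", "nchg_oracle.py")
})

test_that("noncentral p is monotone in the concordant cell at fixed margins", {
  set.seed(305)
  for (r in 1:50) {
    m1 <- sample(1:20, 1); m2 <- sample(1:20, 1)
    k <- sample(0:(m1 + m2), 1)
    lo <- max(0, k - m2); hi <- min(k, m1)
    ps <- vapply(lo:hi, function(a)
      fisher_noncentral_p(c(a, m1 - a, k - a, m2 - k + a))$p, 0)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("swapping the two signatures transposes the table, p unchanged", {
  set.seed(306)
  a <- setNames(sample(c("+", "-", "0"), 150, TRUE, c(.2, .2, .6)),
                sprintf("e%03d", 1:150))
  b <- setNames(sample(c("+", "-", "0"), 150, TRUE, c(.25, .15, .6)),
                sprintf("e%03d", 1:150))
  t_ab <- splicing_contingency(mk_sig(a), mk_sig(b))
  t_ba <- splicing_contingency(mk_sig(b), mk_sig(a))
  expect_identical(t_ba, t(t_ab))
  for (dir in c("pos", "neg")) {
    p_ab <- fisher_noncentral_p(collapse_tables(t_ab)[[dir]])$p
    p_ba <- fisher_noncentral_p(collapse_tables(t_ba)[[dir]])$p
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
  }
})

test_that("compendium comparison flags planted factors and pools BH", {
  cfg <- sim_config(seed = 42)
  comp <- gen_compendium(cfg)
  dmeta <- perturbation_meta("disease", "disease", 1)
  dsig <- splicing_signature(comp$disease, dmeta)
  compendium <- lapply(seq_len(nrow(comp$meta)), function(j) {
    meta <- perturbation_meta(comp$meta$comparison_id[j],
                              comp$meta$factor_id[j], comp$meta$sign[j])
    list(signature = splicing_signature(comp$sf_tables[[j]], meta),
         meta = meta)
  })
  res <- compare_splicing(dsig, compendium)
  cand <- unique(res$factor_id[res$candidate])
  expect_setequal(cand, comp$truth$planted_sf_ids)

  # q depends only on the pooled p list, not result ordering
  expect_equal(sort(res$q), sort(bh_adjust(res$p)))
  # results sorted by q then p
  expect_true(!is.unsorted(res$q))

  # maximal concordance: both directions at the minimum attainable p
  ident <- list(list(signature = dsig, meta = perturbation_meta("self", "sf", 1)))
  res_id <- compare_splicing(dsig, ident)
  for (i in 1:2) {
    tt <- unlist(res_id[i, c("a", "b", "c", "d")])
    pmin_attain <- fisher_noncentral_p(
      c(min(tt[1] + tt[2], tt[1] + tt[3]),
        tt[1] + tt[2] - min(tt[1] + tt[2], tt[1] + tt[3]),
        tt[1] + tt[3] - min(tt[1] + tt[2], tt[1] + tt[3]),
        sum(tt) - tt[1] - tt[2] - tt[3] +
          min(tt[1] + tt[2], tt[1] + tt[3])))$p
    expect_equal(res_id$p[i], pmin_attain, tolerance = 1e-12)
  }
})

test_that("expression comparison builds overlap tables on the shared background", {
  bg <- sprintf("g%04d", 1:1000)
  up <- bg[1:50]
  dsig <- structure(list(comparison_id = "d", up = up, down = bg[51:80],
                         background = bg, semantics = "bp-directional"),
                    class = "expression_signature")
  # factor up set identical to disease up, down disjoint
  ssig <- structure(list(comparison_id = "s", up = up, down = bg[101:130],
                         background = bg, semantics = "sf-regulated"),
                    class = "expression_signature")
  res <- compare_expression(dsig, list(list(
    signature = ssig, meta = perturbation_meta("s", "sf1", 1))))
  uu <- res[res$direction == "up-vs-up", ]
  expect_equal(unlist(uu[c("a", "b", "c", "d")]),
               c(a = 50, b = 0, c = 0, d = 950))
  # disjoint sets put a at the support minimum: p = 1
  ud <- res[res$direction == "up-vs-down", ]
  expect_equal(ud$a, 0)
  expect_equal(ud$p, 1)

  bad <- ssig; bad$background <- sprintf("x%d", 1:10); bad$up <- character(0); bad$down <- character(0)
  expect_error(compare_expression(dsig, list(list(
    signature = bad, meta = perturbation_meta("s", "sf1", 1)))),
    "background")
})
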