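test_that("generators are deterministic in (config, seed) and validate inputs", {
  cfg <- sim_config(seed = 5, n_genes = 8, n_events_per_gene = 2)
  g1 <- gen_gene_models(cfg)
  g2 <- gen_gene_models(cfg)
  expect_identical(g1, g2)

  c1 <- gen_event_counts(cfg)
  c2 <- gen_event_counts(cfg)
  expect_identical(c1, c2)

  d1 <- gen_deg_tables(cfg)
  d2 <- gen_deg_tables(cfg)
  expect_identical(d1, d2)

  m1 <- gen_meta(cfg, n = 20)
  m2 <- gen_meta(cfg, n = 20)
  expect_identical(m1, m2)

  expect_error(sim_config(psi_null = 0.9, delta_psi_true = 0.2), "psi_null")
  expect_error(sim_config(n_planted = 5, n_sfs = 3), "n_planted")
  expect_error(sim_config(depth = -1), "depth")
  expect_error(gen_gene_models(cfg, templates = "XX"), "unknown event type")
})

test_that("forced templates yield exactly the requested events", {
  cfg1 <- sim_config(seed = 1, n_genes = 1)
  gm <- gen_gene_models(cfg1, templates = "ES")
  expect_equal(nrow(gm$truth), 1L)
  expect_equal(gm$truth$type, "ES")
  ev <- enumerate_events(build_splice_graph(gm$genes[[1]]))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  # an ES gene has a 3-exon inclusion isoform and a 2-exon skip isoform
  n_ex <- sort(vapply(gm$genes[[1]]$transcripts, nrow, 0L))
  expect_equal(n_ex, c(2L, 3L), ignore_attr = TRUE)

  # mixed corpus: per-type enumerated counts equal the generator's ledger
  cfg <- sim_config(seed = 9, n_genes = 100)
  gm <- gen_gene_models(cfg)
  ev <- do.call(rbind, lapply(gm$genes, function(g)
    enumerate_events(build_splice_graph(g))))
  expect_equal(table(ev$type), table(gm$truth$type))
})

test_that("event counts follow the DMN model with planted effects", {
  # null symmetry: mean observed delta-PSI near 0 across 200 events
  cfg <- sim_config(seed = 2, n_genes = 200, n_samples_per_condition = 5)
  sim <- gen_event_counts(cfg)
  dps <- vapply(sim$counts, function(ec) {
    p <- tapply(ec$counts[, 1] / rowSums(ec$counts), ec$condition, mean)
    p[["perturbed"]] - p[["baseline"]]
  }, 0)
  expect_lt(abs(mean(dps)), 0.02)

  # near-multinomial limit: proportion variance matches binomial closed form
  cfg_hi <- sim_config(seed = 3, n_genes = 200, n_samples_per_condition = 5,
                       precision = 1e9, depth = 200)
  sim_hi <- gen_event_counts(cfg_hi)
  props <- unlist(lapply(sim_hi$counts, function(ec)
    ec$counts[, 1] / rowSums(ec$counts)))
  ns <- unlist(lapply(sim_hi$counts, function(ec) rowSums(ec$counts)))
  v_emp <- stats::var(props)
  v_bin <- mean(0.5 * 0.5 / ns)
  expect_lt(abs(v_emp - v_bin) / v_bin, 0.15)

  # planted effect: pooled-count PSI difference lands near the planted value
  cfg_eff <- sim_config(seed = 7, n_genes = 200, depth = 200,
                        psi_null = 0.5, delta_psi_true = 0.3)
  ids <- sprintf("EV%05d", 1:200)
  sim_eff <- gen_event_counts(cfg_eff, event_ids = ids,
                              delta_psi = setNames(rep(0.3, 200), ids))
  dps <- vapply(sim_eff$counts, function(ec) {
    pool <- rowsum(ec$counts, ec$condition)
    (pool["perturbed", 1] / sum(pool["perturbed", ])) -
      (pool["baseline", 1] / sum(pool["baseline", ]))
  }, 0)
  expect_gte(mean(dps >= 0.2 & dps <= 0.4), 0.95)

  # degenerate inclusion proportions are rejected
  expect_error(
    gen_event_counts(sim_config(seed = 1, n_genes = 1, psi_null = 0.8),
                     event_ids = "e1", delta_psi = c(e1 = 0.2)),
    "degenerate")
})

test_that("compendium planting controls signed overlap and truth records it", {
  cfg <- sim_config(seed = 4, n_sfs = 10, n_planted = 2, overlap_frac = 0.3)
  comp <- gen_compendium(cfg)
  expect_length(comp$truth$planted_sf_ids, 2L)
  expect_true(all(comp$truth$planted_sf_ids %in% comp$meta$factor_id))

  # planted factors carry the promised signed-concordant shared events
  n_signed <- length(comp$truth$disease_states)
  for (sf in comp$truth$planted_sf_ids) {
    shared <- comp$truth$shared_events[[sf]]
    expect_length(shared, round(0.3 * n_signed))
    cmp_id <- comp$meta$comparison_id[comp$meta$factor_id == sf]
    meta <- perturbation_meta(cmp_id, sf,
                              comp$meta$sign[comp$meta$factor_id == sf])
    sig <- splicing_signature(comp$sf_tables[[cmp_id]], meta)
    expect_identical(unname(sig$states[shared]),
                     unname(comp$truth$disease_states[shared]))
  }
  # every universe event has exactly one assignment
  expect_setequal(names(comp$truth$event_assignments),
                  comp$disease$event_id)

  # full signed-concordant overlap: the ++ cell carries the whole + set
  cfg1 <- sim_config(seed = 4, n_sfs = 2, n_planted = 1, overlap_frac = 1)
  comp1 <- gen_compendium(cfg1)
  sf <- comp1$truth$planted_sf_ids
  cmp_id <- comp1$meta$comparison_id[comp1$meta$factor_id == sf]
  dmeta <- perturbation_meta("disease", "disease", 1)
  smeta <- perturbation_meta(cmp_id, sf,
                             comp1$meta$sign[comp1$meta$factor_id == sf])
  t3 <- splicing_contingency(
    splicing_signature(comp1$disease, dmeta),
    splicing_signature(comp1$sf_tables[[cmp_id]], smeta))
  expect_equal(t3["+", "+"], sum(comp1$truth$disease_states == "+"))
  expect_equal(t3["+", "-"] + t3["+", "0"], 0)
})

test_that("DEG tables plant exact effects and reuse compendium truth", {
  cfg0 <- sim_config(seed = 6, deg_noise_sd = 0, lfc_effect = 1)
  deg <- gen_deg_tables(cfg0)
  up <- deg$disease$log2FC[match(deg$truth$disease_up, deg$disease$gene_id)]
  expect_true(all(up == 1.0))
  expect_true(all(deg$disease$expressed))
  expect_equal(length(deg$truth$disease_up) + length(deg$truth$disease_down),
               2 * (cfg0$signature_size %/% 2))

  comp <- gen_compendium(cfg0)
  deg2 <- gen_deg_tables(cfg0, truth = comp$truth)
  expect_identical(deg2$truth$planted_sf_ids, comp$truth$planted_sf_ids)
  expect_identical(deg2$truth$sf_signs, comp$truth$sf_signs)
})

test_that("noiseless meta simulation is exactly linear in the design", {
  cfg <- sim_config(seed = 8)
  mm <- gen_meta(cfg, n = 40, sigma = 0, integerize = FALSE)
  X <- cbind(1, mm$meta$spots, mm$meta$L, mm$meta$n_samples,
             mm$meta$spots * mm$meta$L, mm$meta$spots * mm$meta$n_samples)
  expect_equal(drop(X %*% mm$beta_das), mm$das, tolerance = 1e-12)
  expect_true(all(mm$meta$L == ifelse(mm$meta$layout == "paired",
                                      2 * mm$meta$read_length,
                                      mm$meta$read_length)))
})
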