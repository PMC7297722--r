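test_that("splice graph segments the exon union and keeps transcripts as paths", {
  # single one-exon transcript: one node, no edges
  g <- mk_gene("+", ex(0, 100))
  sg <- build_splice_graph(g)
  expect_equal(nrow(sg$segments), 1L)
  expect_equal(nrow(sg$edges), 0L)

  # classic skip gene: 3 nodes, junction edges e1-e2, e2-e3, e1-e3
  g <- mk_gene("+", ex(0, 100, 200, 300, 400, 500), ex(0, 100, 400, 500))
  sg <- build_splice_graph(g)
  expect_equal(nrow(sg$segments), 3L)
  j <- sg$edges[sg$edges$type == "junction", c("from", "to")]
  expect_setequal(paste(j$from, j$to), c("1 2", "2 3", "1 3"))

  # every transcript of a random corpus is a path: consecutive path segments
  # are connected by an edge of that transcript
  gm <- gen_gene_models(sim_config(seed = 21, n_genes = 50,
                                   n_events_per_gene = 2))
  for (g in gm$genes) {
    sg <- build_splice_graph(g)
    for (nm in names(sg$tx_paths)) {
      p <- sg$tx_paths[[nm]]
      if (length(p) < 2) next
      e <- sg$edges[sg$edges$transcript == nm, ]
      expect_true(all(paste(p[-length(p)], p[-1]) %in% paste(e$from, e$to)))
      expect_true(all(diff(p) > 0))  # acyclic in coordinate order
    }
  }

  # overlapping exons within one transcript are rejected
  expect_error(mk_gene("+", ex(0, 100, 50, 200)), "overlapping")
})

test_that("canonical two-isoform structures classify to their event type", {
  # exon skip
  g <- mk_gene("+", ex(0, 100, 200, 300, 400, 500), ex(0, 100, 400, 500))
  evs <- enumerate_events(build_splice_graph(g))
  expect_equal(evs$type, "ES")
  expect_equal(c(evs$var_start, evs$var_end), c(200L, 300L))
  expect_equal(evs$n_inc, 2L)  # two inclusion junctions
  expect_equal(evs$n_exc, 1L)

  # intron retention
  g <- mk_gene("+", ex(0, 300), ex(0, 100, 200, 300))
  evs <- enumerate_events(build_splice_graph(g))
  expect_equal(evs$type, "IR")
  expect_equal(c(evs$var_start, evs$var_end), c(100L, 200L))
  expect_match(evs$inclusion_features, "^E:")  # retained segment, no junction
  expect_match(evs$exclusion_features, "^J:")

  # alternative donor on plus = A5SS; same structure on minus = A3SS
  g <- mk_gene("+", ex(0, 150, 300, 400), ex(0, 100, 300, 400))
  expect_equal(enumerate_events(build_splice_graph(g))$type, "A5SS")
  g <- mk_gene("-", ex(0, 150, 300, 400), ex(0, 100, 300, 400))
  expect_equal(enumerate_events(build_splice_graph(g))$type, "A3SS")

  # mutually exclusive exons
  g <- mk_gene("+", ex(0, 100, 200, 260, 500, 600),
               ex(0, 100, 350, 410, 500, 600))
  evs <- enumerate_events(build_splice_graph(g))
  expect_equal(evs$type, "ME")
  expect_equal(c(evs$var_start, evs$var_end), c(200L, 410L))

  # alternative first / last exons, strand-aware
  g <- mk_gene("+", ex(0, 80, 500, 600), ex(200, 280, 500, 600))
  expect_equal(enumerate_events(build_splice_graph(g))$type, "AFE")
  g <- mk_gene("-", ex(0, 80, 500, 600), ex(200, 280, 500, 600))
  expect_equal(enumerate_events(build_splice_graph(g))$type, "ALE")

  # single path: no events
  g <- mk_gene("+", ex(0, 100, 200, 300))
  expect_equal(nrow(enumerate_events(build_splice_graph(g))), 0L)
})

test_that("enumeration agrees with the transcript-pair interval oracle", {
  gm <- gen_gene_models(sim_config(seed = 31, n_genes = 100,
                                   n_events_per_gene = 2))
  for (g in gm$genes) {
    evs <- enumerate_events(build_splice_graph(g))
    orc <- oracle_events(g)
    key <- function(d) sort(paste(d$type, d$var_start, d$var_end))
    expect_identical(key(evs), key(orc))
  }
})

test_that("mirroring a gene swaps A5SS<->A3SS and AFE<->ALE only", {
  gm <- gen_gene_models(sim_config(seed = 32, n_genes = 60))
  swap <- c(ES = "ES", ME = "ME", IR = "IR", A5SS = "A3SS", A3SS = "A5SS",
            AFE = "ALE", ALE = "AFE")
  for (g in gm$genes) {
    t_fwd <- enumerate_events(build_splice_graph(g))$type
    t_mir <- enumerate_events(build_splice_graph(mirror_gene(g)))$type
    expect_identical(sort(unname(swap[t_fwd])), sort(t_mir))
  }
})

test_that("event ids are deterministic across repeated enumeration", {
  gm <- gen_gene_models(sim_config(seed = 33, n_genes = 20))
  e1 <- lapply(gm$genes, function(g) enumerate_events(build_splice_graph(g)))
  e2 <- lapply(gm$genes, function(g) enumerate_events(build_splice_graph(g)))
  expect_identical(e1, e2)
})

test_that("assign_counts pools feature counts into categories", {
  events <- data.frame(
    event_id = "ev1", gene_id = "g", type = "ES", chrom = "chr1",
    strand = "+", var_start = 1L, var_end = 2L,
    inclusion_features = "j1,j2", exclusion_features = "j3",
    n_inc = 2L, n_exc = 1L, stringsAsFactors = FALSE)
  fc <- data.frame(feature_id = c("j1", "j2", "j3"),
                   sample_id = "s1", count = c(30, 50, 20))
  conds <- data.frame(sample_id = "s1", condition = "A")
  ec <- assign_counts(events, fc, conds)[["ev1"]]
  expect_equal(unname(ec$counts[1, ]), c(80, 20))
  expect_equal(ec$n_features, c(2L, 1L))

  # all features absent: zero counts plus a warning
  fc2 <- data.frame(feature_id = "other", sample_id = "s1", count = 5)
  expect_warning(ec2 <- assign_counts(events, fc2, conds)[["ev1"]],
                 "absent")
  expect_equal(unname(ec2$counts[1, ]), c(0, 0))

  # negative counts and duplicate keys are rejected
  fc_neg <- data.frame(feature_id = "j1", sample_id = "s1", count = -1)
  expect_error(assign_counts(events, fc_neg, conds), "negative")
  fc_dup <- fc[c(1, 1, 2, 3), ]
  expect_error(assign_counts(events, fc_dup, conds), "duplicate")
})

test_that("simulated feature tables reproduce the generator's ledger", {
  cfg <- sim_config(seed = 34, n_genes = 15)
  gm <- gen_gene_models(cfg)
  events <- do.call(rbind, lapply(gm$genes, function(g)
    enumerate_events(build_splice_graph(g))))
  sim <- gen_event_counts(cfg, event_ids = events$event_id,
                          n_features = as.matrix(events[c("n_inc", "n_exc")]))
  fc <- sim_feature_counts(events, sim$counts)
  conds <- data.frame(sample_id = sim$counts[[1]]$sample_id,
                      condition = sim$counts[[1]]$condition)
  ecs <- assign_counts(events, fc, conds)
  ledger <- attr(fc, "ledger")
  for (eid in events$event_id) {
    led <- ledger[ledger$event_id == eid, ]
    got <- ecs[[eid]]$counts
    expect_equal(unname(got[, 1]), led$inc[match(ecs[[eid]]$sample_id,
                                                 led$sample_id)])
    expect_equal(unname(got[, 2]), led$exc[match(ecs[[eid]]$sample_id,
                                                 led$sample_id)])
  }
})
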