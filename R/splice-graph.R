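## Splice graph and event enumeration ----------------------------------------
##
## The graph nodes are the minimal disjoint exonic segments obtained by
## cutting the union of all exons at every exon boundary. Two edge kinds
## connect segments: "adjacency" edges between contiguous segments inside one
## exon, and "junction" edges across spliced-out introns. Each transcript is
## then a path, the graph is acyclic when segments are ordered by coordinate,
## and alternative-splicing events are bubbles: pairs of internally
## node-disjoint sub-paths sharing anchor segments (or alternative terminal
## sub-paths for AFE/ALE).

#' Build the splice graph of a gene model
#'
#' @param gene A [gene_model()].
#' @return A `splice_graph`: segments (data.frame seg/start/end), per-edge
#'   table (from, to, type), and per-transcript segment paths.
#' @export
#' @examples
#' g <- gene_model("g", "chr1", "+",
#'                 list(t1 = rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)),
#'                      t2 = rbind(c(0L, 100L), c(400L, 500L))))
#' sg <- build_splice_graph(g)
#' nrow(sg$segments)
build_splice_graph <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  exons <- do.call(rbind, gene$transcripts)
  bounds <- sort(unique(c(exons[, 1L], exons[, 2L])))
  cand <- cbind(start = bounds[-length(bounds)], end = bounds[-1L])
  covered <- vapply(seq_len(nrow(cand)), function(i)
    any(exons[, 1L] <= cand[i, 1L] & exons[, 2L] >= cand[i, 2L]), NA)
  segs <- cand[covered, , drop = FALSE]
  segments <- data.frame(seg = seq_len(nrow(segs)),
                         start = segs[, 1L], end = segs[, 2L])

  seg_of <- function(ex) which(segments$start >= ex[1L] & segments$end <= ex[2L])
  paths <- lapply(gene$transcripts, function(tx) {
    path <- integer(0); etype <- character(0)
    for (i in seq_len(nrow(tx))) {
      s <- seg_of(tx[i, ])
      if (length(path)) etype <- c(etype, "junction")
      if (length(s) > 1L) etype <- c(etype, rep("adjacency", length(s) - 1L))
      path <- c(path, s)
    }
    list(path = path, etype = etype)
  })

  edges <- unique(do.call(rbind, lapply(names(paths), function(nm) {
    p <- paths[[nm]]$path
    if (length(p) < 2L) return(NULL)
    data.frame(from = p[-length(p)], to = p[-1L],
               type = paths[[nm]]$etype, transcript = nm,
               stringsAsFactors = FALSE)
  })))
  if (is.null(edges))
    edges <- data.frame(from = integer(0), to = integer(0),
                        type = character(0), transcript = character(0))
  rownames(edges) <- NULL

  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, segments = segments,
                 edges = edges,
                 tx_paths = lapply(paths, `[[`, "path")),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph %s: %d segments, %d edges, %d transcripts\n",
              x$gene_id, nrow(x$segments),
              nrow(unique(x$edges[c("from", "to", "type")])),
              length(x$tx_paths)))
  invisible(x)
}

.junction_id <- function(chrom, from_end, to_start)
  sprintf("J:%s:%d-%d", chrom, from_end, to_start)
.segment_id <- function(chrom, start, end)
  sprintf("E:%s:%d-%d", chrom, start, end)

## Junction features along a sub-path (anchors included at the open ends).
.path_junctions <- function(graph, path, etypes) {
  j <- which(etypes == "junction")
  if (!length(j)) return(character(0))
  segs <- graph$segments
  .junction_id(graph$chrom, segs$end[path[j]], segs$start[path[j + 1L]])
}

#' Enumerate alternative-splicing events from a splice graph
#'
#' Walks every pair of transcript paths, decomposes their disagreement into
#' bubbles between consecutive shared segments (plus alternative terminal
#' sub-paths), classifies each bubble structurally and strand-awarely into
#' one of ES, A5SS, A3SS, ME, IR, AFE or ALE, and pools each event's
#' discriminating features into two counting categories (inclusion first).
#' Events are deduplicated and sorted by (gene_id, type, variable-region
#' start), which also fixes the deterministic `event_id`.
#'
#' @param graph A `splice_graph`.
#' @return data.frame event catalog: event_id, gene_id, type, chrom, strand,
#'   var_start, var_end, inclusion_features, exclusion_features (comma
#'   separated), n_inc, n_exc. Zero rows for single-path graphs.
#' @export
enumerate_events <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  tx <- names(graph$tx_paths)
  out <- list()
  if (length(tx) >= 2L) {
    for (i in seq_len(length(tx) - 1L)) for (j in seq(i + 1L, length(tx))) {
      out <- c(out, .pair_bubbles(graph, tx[i], tx[j]))
    }
  }
  if (!length(out)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), var_start = integer(0),
                      var_end = integer(0), inclusion_features = character(0),
                      exclusion_features = character(0),
                      n_inc = integer(0), n_exc = integer(0)))
  }
  ev <- do.call(rbind, out)
  ev$event_id <- sprintf("%s:%s:%d-%d", ev$gene_id, ev$type,
                         ev$var_start, ev$var_end)
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  ev <- ev[order(ev$gene_id, ev$type, ev$var_start), , drop = FALSE]
  rownames(ev) <- NULL
  ev[c("event_id", "gene_id", "type", "chrom", "strand", "var_start",
       "var_end", "inclusion_features", "exclusion_features",
       "n_inc", "n_exc")]
}

## Edge types along a stored transcript path.
.path_etypes <- function(graph, nm) {
  p <- graph$tx_paths[[nm]]
  if (length(p) < 2L) return(character(0))
  e <- graph$edges[graph$edges$transcript == nm, ]
  key <- paste(e$from, e$to)
  stats::setNames(e$type, key)[paste(p[-length(p)], p[-1L])]
}

.pair_bubbles <- function(graph, nm1, nm2) {
  p <- graph$tx_paths[[nm1]]; q <- graph$tx_paths[[nm2]]
  et_p <- .path_etypes(graph, nm1); et_q <- .path_etypes(graph, nm2)
  common <- intersect(p, q)
  if (!length(common)) return(list())
  ip <- match(common, p); iq <- match(common, q)

  sub <- function(path, et, from, to) {
    ## inner segments and the edge types covering anchors -> inner -> anchor
    idx <- if (from + 1L > to - 1L) integer(0) else seq(from + 1L, to - 1L)
    list(inner = path[idx],
         etypes = if (to > from) et[seq(from, to - 1L)] else character(0),
         segs = path[seq(from, to)])
  }
  res <- list()
  emit <- function(b) res[[length(res) + 1L]] <<- b

  ## terminal-left bubble
  if (ip[1L] > 1L || iq[1L] > 1L) {
    bp <- list(inner = p[seq_len(ip[1L] - 1L)], etypes = et_p[seq_len(ip[1L] - 1L)],
               segs = p[seq_len(ip[1L])])
    bq <- list(inner = q[seq_len(iq[1L] - 1L)], etypes = et_q[seq_len(iq[1L] - 1L)],
               segs = q[seq_len(iq[1L])])
    emit(.classify_bubble(graph, bp, bq, terminal = "left"))
  }
  ## internal bubbles between consecutive anchors
  if (length(common) >= 2L) {
    for (k in seq_len(length(common) - 1L)) {
      bp <- sub(p, et_p, ip[k], ip[k + 1L])
      bq <- sub(q, et_q, iq[k], iq[k + 1L])
      if (identical(bp$inner, bq$inner)) next
      emit(.classify_bubble(graph, bp, bq, terminal = "none"))
    }
  }
  ## terminal-right bubble
  np <- length(p); nq <- length(q)
  if (ip[length(ip)] < np || iq[length(iq)] < nq) {
    bp <- list(inner = p[seq(ip[length(ip)] + 1L, length.out = np - ip[length(ip)])],
               etypes = et_p[seq(ip[length(ip)], length.out = np - ip[length(ip)])],
               segs = p[seq(ip[length(ip)], np)])
    bq <- list(inner = q[seq(iq[length(iq)] + 1L, length.out = nq - iq[length(iq)])],
               etypes = et_q[seq(iq[length(iq)], length.out = nq - iq[length(iq)])],
               segs = q[seq(iq[length(iq)], nq)])
    emit(.classify_bubble(graph, bp, bq, terminal = "right"))
  }
  res
}

.classify_bubble <- function(graph, b1, b2, terminal) {
  segs <- graph$segments
  strand <- graph$strand
  span <- function(idx) if (length(idx)) c(min(segs$start[idx]), max(segs$end[idx])) else c(NA_integer_, NA_integer_)

  if (terminal != "none") {
    type <- if (terminal == "left") {
      if (strand == "+") "AFE" else "ALE"
    } else {
      if (strand == "+") "ALE" else "AFE"
    }
    vr <- span(c(b1$inner, b2$inner))
    ## inclusion = alternative whose distinctive segments start leftmost
    s1 <- span(b1$inner)[1L]; s2 <- span(b2$inner)[1L]
    if (is.na(s1) || (!is.na(s2) && s2 < s1)) { tmp <- b1; b1 <- b2; b2 <- tmp }
  } else if (length(b1$inner) && length(b2$inner)) {
    jb <- function(b) length(b$etypes) >= 2L &&
      b$etypes[1L] == "junction" && b$etypes[length(b$etypes)] == "junction"
    type <- if (jb(b1) && jb(b2)) "ME" else "ES"  # mixed nested forms: ES tie-break
    vr <- span(c(b1$inner, b2$inner))
    if (span(b2$inner)[1L] < span(b1$inner)[1L]) { tmp <- b1; b1 <- b2; b2 <- tmp }
  } else {
    if (!length(b1$inner)) { tmp <- b1; b1 <- b2; b2 <- tmp }  # b1 = inclusion
    first <- b1$etypes[1L]; last <- b1$etypes[length(b1$etypes)]
    type <- if (first == "adjacency" && last == "adjacency") "IR"
      else if (first == "junction" && last == "junction") "ES"
      else if (first == "adjacency") { if (strand == "+") "A5SS" else "A3SS" }
      else { if (strand == "+") "A3SS" else "A5SS" }
    vr <- span(b1$inner)
  }

  feat <- function(b, other) {
    j <- setdiff(.path_junctions(graph, b$segs, b$etypes),
                 .path_junctions(graph, other$segs, other$etypes))
    if (length(j)) j else .segment_id(graph$chrom, segs$start[b$inner], segs$end[b$inner])
  }
  inc <- feat(b1, b2); exc <- feat(b2, b1)
  data.frame(gene_id = graph$gene_id, type = type, chrom = graph$chrom,
             strand = strand, var_start = vr[1L], var_end = vr[2L],
             inclusion_features = paste(inc, collapse = ","),
             exclusion_features = paste(exc, collapse = ","),
             n_inc = length(inc), n_exc = length(exc),
             stringsAsFactors = FALSE)
}

#' Per-event counts, one row per sample
#'
#' @param event_id Event identifier.
#' @param counts Matrix (samples x 2) of inclusion / exclusion category
#'   counts, non-negative integers.
#' @param sample_id Character vector of sample names.
#' @param condition Character vector of condition labels (2 levels for a
#'   testable comparison).
#' @param n_features Integer length-2 vector: number of pooled inclusion and
#'   exclusion features (used for per-junction-averaged PSI).
#' @return An `event_counts` object.
#' @export
event_counts <- function(event_id, counts, sample_id, condition,
                         n_features = c(1L, 1L)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts for event ", event_id, call. = FALSE)
  if (nrow(counts) != length(sample_id) || nrow(counts) != length(condition))
    stop("counts rows must match sample_id/condition length", call. = FALSE)
  colnames(counts) <- c("inc", "exc")
  structure(list(event_id = event_id, counts = counts,
                 sample_id = as.character(sample_id),
                 condition = as.character(condition),
                 n_features = as.integer(n_features)),
            class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("event_counts %s: %d samples, conditions: %s\n", x$event_id,
              nrow(x$counts), paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Attach feature counts to events
#'
#' Sums per-feature exon/junction counts into each event's two counting
#' categories (inclusion features first). Features missing from the table
#' are counted as zero with a warning.
#'
#' @param events Event catalog from [enumerate_events()] (or a subset).
#' @param feature_counts data.frame with columns feature_id, sample_id,
#'   count (long format).
#' @param conditions data.frame with columns sample_id, condition.
#' @return Named list of [event_counts()] objects, one per catalog row.
#' @export
assign_counts <- function(events, feature_counts, conditions) {
  .check_columns(feature_counts, c("feature_id", "sample_id", "count"),
                 "feature_counts")
  .check_columns(conditions, c("sample_id", "condition"), "conditions")
  if (any(feature_counts$count < 0))
    stop("negative counts in feature table", call. = FALSE)
  key <- paste(feature_counts$feature_id, feature_counts$sample_id)
  if (anyDuplicated(key))
    stop("duplicate (feature_id, sample_id) rows: ",
         key[anyDuplicated(key)][1L], call. = FALSE)
  samples <- conditions$sample_id
  cmat <- with(feature_counts,
               tapply(count, list(feature_id, sample_id), sum, default = 0))

  lookup <- function(features) {
    present <- intersect(features, rownames(cmat))
    missing <- setdiff(features, rownames(cmat))
    tot <- if (length(present))
      colSums(cmat[present, samples, drop = FALSE], na.rm = TRUE)
    else stats::setNames(numeric(length(samples)), samples)
    tot[is.na(tot)] <- 0
    list(tot = tot, missing = missing)
  }
  out <- lapply(seq_len(nrow(events)), function(i) {
    inc_f <- strsplit(events$inclusion_features[i], ",", fixed = TRUE)[[1L]]
    exc_f <- strsplit(events$exclusion_features[i], ",", fixed = TRUE)[[1L]]
    inc <- lookup(inc_f); exc <- lookup(exc_f)
    miss <- c(inc$missing, exc$missing)
    if (length(miss))
      warning(sprintf("event %s: %d feature(s) absent from count table, counted as 0 (%s)",
                      events$event_id[i], length(miss),
                      paste(utils::head(miss, 3L), collapse = ", ")),
              call. = FALSE)
    event_counts(events$event_id[i],
                 cbind(inc$tot, exc$tot),
                 samples, conditions$condition,
                 n_features = c(length(inc_f), length(exc_f)))
  })
  stats::setNames(out, events$event_id)
}
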