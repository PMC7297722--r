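## Synthetic gene models ------------------------------------------------------
##
## Each gene carries exactly two isoforms that differ by a known set of
## alternative-splicing units, so every generated event has a ground-truth
## type and variable region. Units are expressed first as *genomic* templates
## (which side of the variable region touches an exon edge), then labelled
## with the strand-aware event type: a donor-side extension is an A5SS on the
## plus strand but an A3SS on the minus strand, and alternative leftmost /
## rightmost terminal exons are AFE/ALE on plus and ALE/AFE on minus.

.internal_templates <- c("ES", "IR", "ME", "DONOR_EXT", "ACC_EXT")
.event_types <- c("ES", "A5SS", "A3SS", "ME", "IR", "AFE", "ALE")

.template_type <- function(template, strand) {
  switch(template,
    ES = "ES", IR = "IR", ME = "ME",
    DONOR_EXT = if (strand == "+") "A5SS" else "A3SS",
    ACC_EXT   = if (strand == "+") "A3SS" else "A5SS",
    ALT_LEFT  = if (strand == "+") "AFE" else "ALE",
    ALT_RIGHT = if (strand == "+") "ALE" else "AFE",
    stop("unknown template: ", template)
  )
}

.type_template <- function(type, strand) {
  switch(type,
    ES = "ES", IR = "IR", ME = "ME",
    A5SS = if (strand == "+") "DONOR_EXT" else "ACC_EXT",
    A3SS = if (strand == "+") "ACC_EXT" else "DONOR_EXT",
    AFE  = if (strand == "+") "ALT_LEFT" else "ALT_RIGHT",
    ALE  = if (strand == "+") "ALT_RIGHT" else "ALT_LEFT",
    stop("unknown event type: ", type)
  )
}

#' Generate synthetic two-isoform gene models with known splicing events
#'
#' Builds gene models whose two transcripts differ by
#' `config$n_events_per_gene` alternative-splicing units of known type and
#' location, covering the seven classic event classes (ES, A5SS, A3SS, ME,
#' IR, AFE, ALE). The returned truth table records, per planted unit, the
#' event type and variable region exactly as [enumerate_events()] will
#' report them, so generator and enumerator can be compared event by event.
#'
#' @param config A [sim_config()].
#' @param templates Optional character vector of event types (recycled over
#'   genes) forcing the planted unit type; only honoured when
#'   `n_events_per_gene == 1`. Default samples unit types at random.
#' @return A list with elements `genes` (list of `gene_model` objects) and
#'   `truth` (data.frame: gene_id, transcript ids, template, type,
#'   var_start, var_end, event_id). Coordinates are 0-based half-open.
#' @export
#' @examples
#' gm <- gen_gene_models(sim_config(seed = 1, n_genes = 2))
#' gm$truth$type
gen_gene_models <- function(config, templates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(templates)) {
    bad <- setdiff(templates, .event_types)
    if (length(bad))
      stop("unknown event type(s) in 'templates': ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (config$n_events_per_gene != 1L)
      stop("'templates' requires n_events_per_gene == 1", call. = FALSE)
  }
  set.seed(.module_seed(config$seed, "genes"))

  genes <- vector("list", config$n_genes)
  truth <- vector("list", config$n_genes)
  cursor <- 1000L
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("G%04d", g)
    strand <- sample(c("+", "-"), 1L)
    k <- config$n_events_per_gene
    if (!is.null(templates)) {
      type <- templates[(g - 1L) %% length(templates) + 1L]
      units <- .type_template(type, strand)
    } else {
      units <- character(k)
      for (i in seq_len(k)) {
        allowed <- .internal_templates
        if (i == 1L) allowed <- c(allowed, "ALT_LEFT")
        if (i == k && k > 1L) allowed <- c(allowed, "ALT_RIGHT")
        if (i == k && k == 1L) allowed <- c(allowed, "ALT_RIGHT")
        units[i] <- sample(allowed, 1L)
      }
    }
    built <- .build_gene(gene_id, "chr1", strand, units, cursor)
    genes[[g]] <- built$gene
    truth[[g]] <- built$truth
    cursor <- built$cursor + 10000L
  }
  truth <- do.call(rbind, truth)
  truth$event_id <- sprintf("%s:%s:%d-%d", truth$gene_id, truth$type,
                            truth$var_start, truth$var_end)
  rownames(truth) <- NULL
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  list(genes = genes, truth = truth)
}

## One gene: alternating shared constitutive exons and variable units.
.build_gene <- function(gene_id, chrom, strand, units, cursor) {
  rlen <- function() sample(80:200, 1L)
  rint <- function() sample(200:800, 1L)
  rext <- function() sample(30:60, 1L)

  t1 <- list(); t2 <- list()
  recs <- list()
  push <- function(which, start, end) {
    ex <- c(start, end)
    if (which != 2L) t1[[length(t1) + 1L]] <<- ex
    if (which != 1L) t2[[length(t2) + 1L]] <<- ex
  }
  rec <- function(template, vs, ve) {
    recs[[length(recs) + 1L]] <<- data.frame(
      gene_id = gene_id, strand = strand, template = template,
      type = .template_type(template, strand),
      var_start = vs, var_end = ve, stringsAsFactors = FALSE)
  }

  k <- length(units)
  ## leading constitutive exon unless the first unit supplies the gene start
  if (units[1L] != "ALT_LEFT") {
    l <- rlen(); push(0L, cursor, cursor + l); cursor <- cursor + l + rint()
  }
  for (i in seq_len(k)) {
    u <- units[i]
    if (u == "ALT_LEFT") {
      l1 <- rlen(); x1s <- cursor; x1e <- x1s + l1
      gap <- rint()
      l2 <- rlen(); x2s <- x1e + gap; x2e <- x2s + l2
      push(1L, x1s, x1e); push(2L, x2s, x2e)
      rec(u, x1s, x2e)
      cursor <- x2e + rint()
    } else if (u == "ALT_RIGHT") {
      l1 <- rlen(); y1s <- cursor; y1e <- y1s + l1
      gap <- rint()
      l2 <- rlen(); y2s <- y1e + gap; y2e <- y2s + l2
      push(1L, y1s, y1e); push(2L, y2s, y2e)
      rec(u, y1s, y2e)
      cursor <- y2e
      next  # terminal unit: no trailing constitutive exon
    } else if (u == "ES") {
      l <- rlen(); push(1L, cursor, cursor + l)
      rec(u, cursor, cursor + l)
      cursor <- cursor + l + rint()
    } else if (u == "ME") {
      la <- rlen(); as_ <- cursor; ae <- as_ + la
      gap <- rint()
      lb <- rlen(); bs <- ae + gap; be <- bs + lb
      push(1L, as_, ae); push(2L, bs, be)
      rec(u, as_, be)
      cursor <- be + rint()
    } else if (u == "IR") {
      la <- rlen(); as_ <- cursor; ae <- as_ + la
      gap <- rint()
      lb <- rlen(); bs <- ae + gap; be <- bs + lb
      push(1L, as_, be)          # retained: one exon spanning the intron
      push(2L, as_, ae); push(2L, bs, be)
      rec(u, ae, bs)
      cursor <- be + rint()
    } else if (u == "DONOR_EXT") {
      l <- rlen(); e <- rext()
      push(1L, cursor, cursor + l + e)  # extended donor side
      push(2L, cursor, cursor + l)
      rec(u, cursor + l, cursor + l + e)
      cursor <- cursor + l + e + rint()
    } else if (u == "ACC_EXT") {
      l <- rlen(); e <- rext()
      push(1L, cursor, cursor + e + l)  # extended acceptor side
      push(2L, cursor + e, cursor + e + l)
      rec(u, cursor, cursor + e)
      cursor <- cursor + e + l + rint()
    } else stop("unknown template: ", u)
    ## trailing constitutive exon after every internal unit
    l <- rlen(); push(0L, cursor, cursor + l)
    if (i < k) cursor <- cursor + l + rint() else cursor <- cursor + l
  }

  gene <- gene_model(
    gene_id = gene_id, chrom = chrom, strand = strand,
    transcripts = stats::setNames(
      list(do.call(rbind, t1), do.call(rbind, t2)),
      paste0(gene_id, c(".t1", ".t2"))))
  list(gene = gene, truth = do.call(rbind, recs), cursor = cursor)
}

#' Construct a gene model
#'
#' @param gene_id,chrom,strand Identifiers; strand is `"+"` or `"-"`.
#' @param transcripts Named list; each element a 2-column matrix of exon
#'   `(start, end)` in 0-based half-open coordinates, rows sorted by start,
#'   exons non-overlapping.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  if (!strand %in% c("+", "-"))
    stop("'strand' must be '+' or '-'", call. = FALSE)
  if (!length(transcripts) || is.null(names(transcripts)))
    stop("'transcripts' must be a non-empty named list", call. = FALSE)
  transcripts <- lapply(transcripts, function(ex) {
    ex <- matrix(as.integer(ex), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 2L] <= ex[, 1L]))
      stop("exon with end <= start in gene ", gene_id, call. = FALSE)
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("overlapping exons within a transcript of gene ", gene_id,
           call. = FALSE)
    ex
  })
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  for (nm in names(x$transcripts))
    cat(sprintf("  %s: %d exon(s)\n", nm, nrow(x$transcripts[[nm]])))
  invisible(x)
}

#' Mirror a gene model
#'
#' Reflects all exon coordinates through a fixed origin while keeping the
#' strand label, i.e. a pure geometric reflection of the locus. Because
#' classification of donor/acceptor-side and first/last-exon events depends
#' on the genomic side *interpreted through the strand*, mirroring swaps
#' A5SS with A3SS and AFE with ALE while leaving ES, ME and IR unchanged —
#' a direct probe of strand-aware classification.
#'
#' @param gene A `gene_model`.
#' @param origin Reflection reference coordinate (default: total span end).
#' @return The reflected `gene_model` (same strand label).
#' @export
mirror_gene <- function(gene, origin = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  if (is.null(origin))
    origin <- max(vapply(gene$transcripts, function(e) max(e[, 2L]), 0)) + 1000L
  tx <- lapply(gene$transcripts, function(ex)
    cbind(start = origin - ex[, 2L], end = origin - ex[, 1L]))
  gene_model(gene$gene_id, gene$chrom, gene$strand, tx)
}
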