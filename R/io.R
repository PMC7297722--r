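## File dialects ---------------------------------------------------------------
##
## All tabular IO is strict headered TSV with stable column order, so a rerun
## with the same config is byte-identical. GTF handling goes through
## rtracklayer; exon records carry gene_id and transcript_id attributes and
## are converted between the GTF's 1-based inclusive coordinates and the
## package-internal 0-based half-open convention on read/write.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, cols, what, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, cols, paste0(what, " (", path, ")"))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v) & !is.na(df[[cc]])))
      stop(sprintf("%s: non-numeric value in column '%s' (row %d)",
                   path, cc, which(is.na(v) & !is.na(df[[cc]]))[1L]),
           call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' Write gene models as GTF
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  recs <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(names(g$transcripts), function(tx) {
      ex <- g$transcripts[[tx]]
      data.frame(chrom = g$chrom, start0 = ex[, 1L], end0 = ex[, 2L],
                 strand = g$strand, gene_id = g$gene_id, transcript_id = tx,
                 stringsAsFactors = FALSE)
    }))
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = recs$chrom,
    ranges = IRanges::IRanges(start = recs$start0 + 1L, end = recs$end0),
    strand = recs$strand)
  S4Vectors::mcols(gr)$source <- "spliceKey"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- recs$gene_id
  S4Vectors::mcols(gr)$transcript_id <- recs$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Exon features are grouped into transcripts by `transcript_id` and into
#' genes by `gene_id`; 1-based inclusive coordinates become 0-based
#' half-open.
#'
#' @param path GTF file with exon rows carrying gene_id and transcript_id.
#' @return Named list of [gene_model()] objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[mc$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id) ||
      any(is.na(mc$gene_id)) || any(is.na(mc$transcript_id)))
    stop("GTF parse error: exon without gene_id/transcript_id attribute in ",
         path, call. = FALSE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = mc$gene_id, transcript_id = mc$transcript_id,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$gene_id), function(gd) {
    tx <- lapply(split(gd, gd$transcript_id), function(td)
      cbind(start = td$start0, end = td$end0))
    gene_model(gd$gene_id[1L], gd$chrom[1L], gd$strand[1L], tx)
  })
  out[order(names(out))]
}

#' Read a per-feature count table
#'
#' @param path TSV with columns feature_id, sample_id, count.
#' @return Validated data.frame; duplicate (feature, sample) keys are
#'   rejected.
#' @export
read_counts <- function(path) {
  df <- .read_tsv(path, c("feature_id", "sample_id", "count"),
                  "count table", "count")
  if (any(df$count < 0))
    stop(path, ": negative count (row ", which(df$count < 0)[1L], ")",
         call. = FALSE)
  key <- paste(df$feature_id, df$sample_id)
  if (anyDuplicated(key))
    stop(path, ": duplicate (feature_id, sample_id) key: ",
         key[anyDuplicated(key)][1L], call. = FALSE)
  df
}

#' Read a differential-expression table
#'
#' @param path TSV with columns gene_id, log2FC, q, expressed.
#' @return Validated data.frame (`expressed` coerced to logical).
#' @export
read_deg <- function(path) {
  df <- .read_tsv(path, c("gene_id", "log2FC", "q", "expressed"),
                  "DEG table", c("log2FC", "q"))
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicate gene_id: ",
         df$gene_id[anyDuplicated(df$gene_id)][1L], call. = FALSE)
  df$expressed <- as.logical(df$expressed)
  df
}

#' Read dataset design metadata
#'
#' Local replacement for an SRA RunInfo export: one row per comparison with
#' spots (total reads), per-mate read length, library layout and sample
#' count. The effective read length `L` is derived on read.
#'
#' @param path TSV with columns comparison_id, spots, read_length, layout,
#'   n_samples.
#' @return Validated data.frame with an added `L` column.
#' @export
read_meta <- function(path) {
  df <- .read_tsv(path, c("comparison_id", "spots", "read_length", "layout",
                          "n_samples"),
                  "design metadata", c("spots", "read_length", "n_samples"))
  if (anyDuplicated(df$comparison_id))
    stop(path, ": duplicate comparison_id", call. = FALSE)
  df$L <- effective_read_length(df$layout, df$read_length)
  df
}

#' Read a signed signature table
#'
#' @param path TSV with columns id, state (`+`, `-` or `0`).
#' @param comparison_id Identifier to attach.
#' @return A `splicing_signature` over the listed ids.
#' @export
read_signature <- function(path, comparison_id = basename(path)) {
  df <- .read_tsv(path, c("id", "state"), "signature table")
  if (anyDuplicated(df$id))
    stop(path, ": duplicate id", call. = FALSE)
  bad <- setdiff(unique(df$state), c("+", "-", "0"))
  if (length(bad))
    stop(path, ": invalid state value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(comparison_id = comparison_id,
                 states = stats::setNames(as.character(df$state), df$id),
                 universe = df$id),
            class = "splicing_signature")
}

#' Write a splicing signature as TSV
#' @param sig A `splicing_signature`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  .write_tsv(data.frame(id = sig$universe,
                        state = unname(sig$states[sig$universe])), path)
}
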