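#' Gene model for one paralog
#'
#' Describes the exon/intron architecture of a gene on a contig. All
#' coordinates are 0-based half-open contig coordinates. The 3' UTR is the
#' terminal gene segment downstream of the last exon (in transcription
#' order). On the minus strand exon 1 is the rightmost exon.
#'
#' @param name gene label.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon in genomic (left-to-right) order.
#' @param utr3 length-2 integer vector, the 3' UTR interval.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, exons, utr3, strand = "+") {
  stop_if(!strand %in% c("+", "-"), "strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stop_if(nrow(exons) < 1L, "gene model needs at least one exon")
  stop_if(any(exons[, "end"] <= exons[, "start"]), "empty exon interval")
  if (is.unsorted(exons[, "start"], strictly = TRUE))
    stop("exons must be sorted by start", call. = FALSE)
  stop_if(any(exons[-1L, "start"] < exons[-nrow(exons), "end"]),
          "exons must be disjoint")
  utr3 <- as.integer(utr3)
  gene_start <- min(exons[, "start"], utr3[1])
  gene_end <- max(exons[, "end"], utr3[2])
  structure(list(name = name, strand = strand, exons = exons, utr3 = utr3,
                 gene_start = gene_start, gene_end = gene_end),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s): %d exons, span [%d, %d), 3'UTR [%d, %d)\n",
              x$name, x$strand, nrow(x$exons), x$gene_start, x$gene_end,
              x$utr3[1], x$utr3[2]))
  invisible(x)
}

gene_length <- function(model) model$gene_end - model$gene_start

n_exons <- function(model) nrow(model$exons)

# Exon index in transcription order for genomic exon row i.
tx_exon_index <- function(model, i) {
  if (model$strand == "+") i else nrow(model$exons) + 1L - i
}

#' Segment labels of the gene model as an interval table
#'
#' Partitions the gene body into `exon<k>`, `intron<k>` and `utr3` intervals
#' (contig coordinates), with exon/intron numbering in transcription order.
#'
#' @param model a [gene_model()].
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
gene_segments <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  out <- list()
  for (i in seq_len(n)) {
    out[[length(out) + 1L]] <-
      data.frame(label = paste0("exon", tx_exon_index(model, i)),
                 start = ex[i, "start"], end = ex[i, "end"])
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      # intron between genomic exon i and i+1; numbered after the upstream
      # (transcription-order) exon
      k <- if (model$strand == "+") i else n - i
      out[[length(out) + 1L]] <-
        data.frame(label = paste0("intron", k),
                   start = ex[i, "end"], end = ex[i + 1L, "start"])
    }
  }
  out[[length(out) + 1L]] <-
    data.frame(label = "utr3", start = model$utr3[1], end = model$utr3[2])
  seg <- do.call(rbind, out)
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# Label of the segment containing contig position `pos` (vectorized).
# Positions inside the gene but outside every labelled segment (should not
# occur for contiguous models) and positions outside the gene give NA.
segment_at <- function(model, pos) {
  seg <- gene_segments(model)
  idx <- findInterval(pos, seg$start)
  lab <- rep(NA_character_, length(pos))
  ok <- idx >= 1L & idx <= nrow(seg)
  ok[ok] <- pos[ok] < seg$end[idx[ok]]
  lab[ok] <- seg$label[idx[ok]]
  lab
}

# Convert a gene-frame offset (0-based along the gene in genomic
# left-to-right order) to a contig position for this model.
frame_to_contig <- function(model, offset) model$gene_start + offset

# Segment label at a gene-frame offset.
segment_at_offset <- function(model, offset) {
  segment_at(model, frame_to_contig(model, offset))
}

# Interval (gene-frame, half-open) of a named segment, e.g. "intron1".
segment_interval <- function(model, label) {
  seg <- gene_segments(model)
  row <- seg[seg$label == label, , drop = FALSE]
  stop_if(nrow(row) == 0L, "segment '", label, "' not in gene model")
  c(start = row$start[1] - model$gene_start,
    end = row$end[1] - model$gene_start)
}
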