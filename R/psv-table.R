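#' Globally align two paralog sequences
#'
#' Affine-gap global (Needleman-Wunsch) alignment of the two paralogs,
#' the prerequisite for identifying paralog-specific variants. Alignment
#' parameters are fixed and recorded in the result for reproducibility.
#'
#' @param seq_a,seq_b paralog sequences (character or `DNAString`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return object of class `paralog_alignment`: the aligned strings for
#'   both sequences, the underlying `PairwiseAlignments` object and the
#'   scoring parameters.
#' @export
align_paralogs <- function(seq_a, seq_b, match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2) {
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  stop_if(nchar(seq_a) == 0 || nchar(seq_b) == 0,
          "paralog sequences must be non-empty")
  ratio <- nchar(seq_a) / nchar(seq_b)
  stop_if(ratio > 2 || ratio < 0.5,
          "sequences differ more than two-fold in length; not paralogous")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq_a),
                                      Biostrings::DNAString(seq_b),
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      type = "global")
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(al)),
                 aligned_b = as.character(Biostrings::alignedSubject(al)),
                 alignment = al,
                 params = list(match = match, mismatch = mismatch,
                               gap_open = gap_open,
                               gap_extend = gap_extend)),
            class = "paralog_alignment")
}

#' @export
print.paralog_alignment <- function(x, ...) {
  cat(sprintf("paralog_alignment: %d columns, %d mismatches, score %.1f\n",
              nchar(x$aligned_a), Biostrings::nmismatch(x$alignment),
              Biostrings::score(x$alignment)))
  invisible(x)
}

#' Build the paralog-specific-variant table
#'
#' One entry per substitution column of the paralog alignment; indel
#' columns are excluded (per-read indel calls are unreliable at long-read
#' error rates, and switch-point logic needs only discriminating bases).
#' Positions are reported on the shared gene frame = paralog A's
#' coordinates, with B projected through the alignment. Each entry is
#' annotated with the gene-model segment containing it.
#'
#' @param alignment an [align_paralogs()] result.
#' @param model_a,model_b [gene_model()]s for the two paralogs (contig
#'   coordinates; the gene frame is taken relative to each gene's start).
#' @return object of class `psv_table`: data.frame `entries` (`offset` in
#'   the shared gene frame, `base_a`, `base_b`, `segment`), the gene
#'   models, and the alignment parameters.
#' @export
build_psv_table <- function(alignment, model_a, model_b) {
  stopifnot(inherits(alignment, "paralog_alignment"))
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  is_gap_a <- ca == "-"
  offset_a <- cumsum(!is_gap_a) - 1L   # A-frame offset of each column
  keep <- !is_gap_a & cb != "-" & ca != cb
  stop_if(!any(keep),
          "no PSVs: paralogs are indistinguishable, inference impossible")
  entries <- data.frame(offset = offset_a[keep], base_a = ca[keep],
                        base_b = cb[keep], stringsAsFactors = FALSE)
  entries <- entries[order(entries$offset), ]
  rownames(entries) <- NULL
  entries$segment <- segment_at_offset(model_a, entries$offset)
  structure(list(entries = entries, model_a = model_a, model_b = model_b,
                 params = alignment$params),
            class = "psv_table")
}

#' @export
print.psv_table <- function(x, ...) {
  cat(sprintf("psv_table: %d PSVs over %d bp gene frame\n",
              nrow(x$entries), gene_length(x$model_a)))
  print(head(x$entries, 4))
  invisible(x)
}

#' Subset a PSV table to a gene-frame interval
#'
#' @param table a [build_psv_table()] result.
#' @param start,end half-open gene-frame interval.
#' @return a `psv_table` restricted to entries with
#'   `start <= offset < end`, order preserved.
#' @export
psv_window <- function(table, start, end) {
  stopifnot(inherits(table, "psv_table"))
  out <- table
  out$entries <- table$entries[table$entries$offset >= start &
                                 table$entries$offset < end, , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

#' Write / read a PSV table as TSV
#'
#' Columns: `offset`, `base_a`, `base_b`, `segment`. A `# params:` header
#' line records the alignment scoring used to build the table.
#'
#' @param table a `psv_table`.
#' @param path output file.
#' @export
write_psv_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# params: match=%g mismatch=%g gap_open=%g gap_extend=%g",
                     table$params$match, table$params$mismatch,
                     table$params$gap_open, table$params$gap_extend), con)
  write.table(table$entries, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_psv_tsv
#' @export
read_psv_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a BED-like exon table into gene models
#'
#' Expected columns: `gene`, `exon_index`, `start`, `end`, `strand`
#' (0-based half-open contig coordinates). The 3' UTR of each gene is taken
#' as the terminal interval downstream (in transcription direction) of the
#' last exon, up to `gene_end` if supplied per gene via attribute rows with
#' `exon_index == "utr3"`.
#'
#' @param path TSV file.
#' @return named list of [gene_model()]s.
#' @export
read_exon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("gene", "exon_index", "start", "end", "strand") %in%
                 names(df)), "exon table needs gene/exon_index/start/end/strand")
  lapply(split(df, df$gene), function(g) {
    ex <- g[g$exon_index != "utr3", , drop = FALSE]
    ex <- ex[order(ex$start), ]
    utr <- g[g$exon_index == "utr3", , drop = FALSE]
    stop_if(nrow(utr) != 1L, "exon table needs one utr3 row per gene")
    gene_model(g$gene[1], cbind(ex$start, ex$end),
               c(utr$start[1], utr$end[1]), g$strand[1])
  })
}
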