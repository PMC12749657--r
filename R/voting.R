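#' Gene-body placements of simulated reads
#'
#' Converts truth read coordinates (haplotype frame) into per-gene-instance
#' placements in the shared gene frame, the form consumed by
#' [vote_read()]. In real data this role is played by an external aligner's
#' coordinates; the package deliberately implements no genome-scale
#' aligner.
#'
#' A read contributes one placement per gene instance it overlaps (a
#' wild-type haplotype has two instances, one per paralog; a hybrid
#' haplotype has a single fused instance; a duplication has one instance
#' per tandem copy).
#'
#' @param read_set a [simulate_long_reads()] result.
#' @param diplotype the [build_diplotype_sequences()] result the reads were
#'   drawn from.
#' @return data.frame: `read_id`, `hap`, `instance` (index within the
#'   haplotype's instance list), `frame_start` (gene-frame offset of the
#'   first overlapped base), `read_from` (0-based offset within the read),
#'   `span` (overlap length).
#' @export
truth_placements <- function(read_set, diplotype) {
  stopifnot(inherits(read_set, "sim_read_set"),
            inherits(diplotype, "sim_diplotype"))
  reads <- read_set$reads
  out <- list()
  for (h in seq_along(diplotype$structures)) {
    inst <- diplotype$structures[[h]]$instances
    sel <- which(reads$hap == h)
    for (k in seq_along(inst)) {
      g0 <- inst[[k]]$hap_start
      g1 <- g0 + inst[[k]]$len
      lo <- pmax(reads$start[sel], g0)
      hi <- pmin(reads$start[sel] + reads$length[sel], g1)
      keep <- hi > lo
      if (any(keep))
        out[[length(out) + 1L]] <-
          fast_df(list(read_id = reads$read_id[sel][keep],
                       hap = rep(h, sum(keep)),
                       instance = rep(k, sum(keep)),
                       frame_start = lo[keep] - g0,
                       read_from = lo[keep] - reads$start[sel][keep],
                       span = hi[keep] - lo[keep]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), hap = integer(),
                      instance = integer(), frame_start = integer(),
                      read_from = integer(), span = integer()))
  res <- do.call(rbind, out)
  res[order(res$read_id, res$instance), , drop = FALSE]
}

#' Vote one read placement against the PSV table
#'
#' At every PSV overlapped by the placement, the observed read base is
#' compared with the two discriminating bases: matching paralog A's base
#' votes `A`, matching paralog B's base votes `B`, matching neither is
#' recorded as `neither` (sequencing error).
#'
#' @param read_seq the read sequence (character).
#' @param placement list or one-row data.frame with `frame_start`,
#'   `read_from`, `span` as produced by [truth_placements()] (or an
#'   external aligner).
#' @param psv a [build_psv_table()] result.
#' @param read_id optional identifier carried through.
#' @return object of class `vote_vector`: data.frame `votes` (`offset`,
#'   `observed`, `vote`), plus `read_id`, the frame span, and
#'   `informative` (number of A/B votes).
#' @export
vote_read <- function(read_seq, placement, psv, read_id = NA_character_) {
  stopifnot(inherits(psv, "psv_table"))
  f0 <- placement$frame_start
  f1 <- f0 + placement$span
  e <- psv$entries
  hit <- which(e$offset >= f0 & e$offset < f1)
  if (length(hit) == 0L) {
    v <- fast_df(list(offset = integer(), observed = character(),
                      vote = character()))
  } else {
    off <- e$offset[hit]
    rpos <- off - f0 + placement$read_from + 1L  # 1-based in read
    obs <- substring(read_seq, rpos, rpos)
    vote <- rep("neither", length(hit))
    vote[obs == e$base_a[hit]] <- "A"
    vote[obs == e$base_b[hit]] <- "B"
    v <- fast_df(list(offset = off, observed = obs, vote = vote))
  }
  structure(list(votes = v, read_id = read_id, span = c(f0, f1),
                 read_from = placement$read_from, read_seq = read_seq,
                 informative = sum(v$vote != "neither")),
            class = "vote_vector")
}

#' @export
print.vote_vector <- function(x, ...) {
  cat(sprintf("vote_vector %s: %d PSVs (%d informative): %s\n",
              x$read_id, nrow(x$votes), x$informative,
              paste(head(x$votes$vote, 25), collapse = "")))
  invisible(x)
}

# Vote all placements of a read set; returns a list of vote_vector.
vote_read_set <- function(read_set, placements, psv) {
  reads <- read_set$reads
  seqs <- stats::setNames(reads$sequence, reads$read_id)
  lapply(seq_len(nrow(placements)), function(i) {
    p <- placements[i, ]
    vote_read(seqs[[p$read_id]], p, psv,
              read_id = paste0(p$read_id, "/", p$instance))
  })
}

#' Re-align an ambiguous read terminus against both paralogs
#'
#' Local (Smith-Waterman) alignment of a read terminus against both
#' paralog references, keeping the higher-identity placement — the
#' BLAT-style rescue used to resolve read ends that standard alignment
#' places ambiguously between near-identical paralogs.
#'
#' @param terminus terminus sequence (character), at least `min_len` bp.
#' @param seq_a,seq_b the two paralog reference sequences.
#' @param min_len minimum terminus length considered informative.
#' @param min_identity placements below this identity are reported
#'   unplaced.
#' @return list: `placed` (logical), `paralog` (`"A"`/`"B"`), `identity`,
#'   `ref_start`, `ref_end` (0-based half-open on the winning reference).
#' @export
realign_terminus <- function(terminus, seq_a, seq_b, min_len = 500L,
                             min_identity = 0.8) {
  terminus <- as.character(terminus)
  stop_if(nchar(terminus) < min_len,
          "terminus shorter than min_len (", min_len, " bp)")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  hit <- function(ref) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(terminus),
                                        Biostrings::DNAString(ref),
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2,
                                        type = "local")
    list(identity = Biostrings::pid(al, type = "PID1") / 100,
         start = Biostrings::start(Biostrings::subject(al)) - 1L,
         end = Biostrings::end(Biostrings::subject(al)),
         nmatch = Biostrings::nmatch(al))
  }
  ha <- hit(seq_a); hb <- hit(seq_b)
  # identity alone is gameable by micro-alignments; require the match to
  # cover most of the terminus as well
  score <- function(h) h$nmatch
  best <- if (score(ha) >= score(hb)) c(list(paralog = "A"), ha)
          else c(list(paralog = "B"), hb)
  cov <- (best$end - best$start) / nchar(terminus)
  if (best$identity < min_identity || cov < 0.5)
    return(list(placed = FALSE, paralog = NA_character_,
                identity = best$identity, ref_start = NA, ref_end = NA))
  list(placed = TRUE, paralog = best$paralog, identity = best$identity,
       ref_start = best$start, ref_end = best$end)
}
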