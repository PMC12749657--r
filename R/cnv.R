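#' Segment a depth profile into integer copy-number states
#'
#' Each window's normalized copy number is rounded to the nearest integer
#' state in 0..4; runs shorter than `min_windows` are merged into the
#' dominant (longer) neighbor; a segment whose mean normalized CN deviates
#' from its integer state by more than the guard band is flagged
#' low-confidence rather than silently rounded.
#'
#' @param profile a [simulate_depth_profile()] result, or any object with
#'   `windows` (`start`, `end`, `cn_norm`) and `baseline`.
#' @param min_windows minimum run length for a state segment.
#' @param guard guard band around integer states (CN units).
#' @return data.frame of segments: `start`, `end`, `state`, `mean_cn`,
#'   `n_windows`, `low_confidence`.
#' @export
segment_depth <- function(profile, min_windows = 5L, guard = 0.35) {
  w <- profile$windows
  stop_if(is.null(profile$baseline) || !is.finite(profile$baseline) ||
            profile$baseline <= 0, "diploid baseline depth is zero")
  stop_if(nrow(w) < min_windows, "fewer windows than min_windows")
  state <- pmin(pmax(round_half_up(w$cn_norm), 0L), 4L)
  # absorb runs shorter than min_windows into the neighboring state whose
  # integer value is closest to the run's own mean CN (boundary windows
  # then join the segment they actually resemble)
  repeat {
    r <- rle(state)
    if (length(r$lengths) == 1L || all(r$lengths >= min_windows)) break
    k <- which(r$lengths < min_windows)[1]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1L):ends[k]
    m <- mean(w$cn_norm[idx])
    left <- if (k > 1L) r$values[k - 1L] else NA
    right <- if (k < length(r$values)) r$values[k + 1L] else NA
    pick <- if (is.na(left)) right
            else if (is.na(right)) left
            else if (abs(m - left) <= abs(m - right)) left else right
    state[idx] <- pick
  }
  r <- rle(state)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  seg <- data.frame(
    start = w$start[idx_start], end = w$end[idx_end],
    state = r$values,
    mean_cn = vapply(seq_along(r$values), function(k)
      mean(w$cn_norm[idx_start[k]:idx_end[k]]), 0),
    n_windows = r$lengths)
  seg$low_confidence <- abs(seg$mean_cn - seg$state) > guard
  seg
}

# Expected per-window integer CN for a hypothesized pair of alleles.
# Hybrid junction positions are taken at the SP interval midpoint (the
# junction itself is unobservable); windows straddling an expected
# breakpoint are excluded from agreement scoring by the caller.
expected_cn_profile <- function(alleles, pair, starts, ends) {
  clen <- nchar(pair$contig)
  ga0 <- pair$model_a$gene_start
  gb0 <- pair$model_b$gene_start
  left0 <- min(ga0, gb0); right0 <- max(ga0, gb0)
  cn <- rep(0, length(starts))
  breaks <- numeric()
  for (a in alleles) {
    v <- rep(1, length(starts))
    if (a$kind == "hybrid") {
      j <- if (!is.na(a$junction)) a$junction
           else floor(mean(a$sp_interval))
      d0 <- left0 + j; d1 <- right0 + j
      v[starts >= d0 & ends <= d1] <- 0
      breaks <- c(breaks, d0, d1)
    } else if (a$kind == "whole_deletion") {
      d0 <- gb0; d1 <- gb0 + gene_length(pair$model_b)
      v[starts >= d0 & ends <= d1] <- 0
      breaks <- c(breaks, d0, d1)
    } else if (a$kind == "duplication") {
      d0 <- gb0; d1 <- gb0 + gene_length(pair$model_b)
      v[starts >= d0 & ends <= d1] <- a$copy_count
      breaks <- c(breaks, d0, d1)
    }
    cn <- cn + v
  }
  list(cn = cn, breaks = breaks)
}

# All allele-pair hypotheses compatible with the observed hybrid
# candidates: every supported candidate must appear in at least one
# allele; the remaining slots draw from wild-type / whole deletion /
# duplication (the latter only if the depth shows a gain).
hypothesis_pairs <- function(candidates, max_state_gene_b) {
  base <- list(allele_structure("wild_type"),
               allele_structure("whole_deletion", cn_status = "deleted",
                                copy_count = 0L))
  if (max_state_gene_b >= 3L)
    base <- c(base, list(allele_structure("duplication",
                                          cn_status = "duplicated",
                                          copy_count = max_state_gene_b - 1L)))
  pool <- c(candidates, base)
  pairs <- list()
  for (i in seq_along(pool)) for (k in seq(i, length(pool))) {
    pick <- list(pool[[i]], pool[[k]])
    uses_all <- all(vapply(candidates, function(cand)
      any(vapply(pick, same_allele_class, TRUE, b = cand)), TRUE))
    if (uses_all) pairs[[length(pairs) + 1L]] <- pick
  }
  pairs
}

#' Integrate allele candidates with copy-number segments into a diplotype
#'
#' Read-level switch evidence alone cannot phase deletions, duplications
#' or homozygous hybrids; depth alone cannot see junctions. This step
#' enumerates allele-pair hypotheses that use every supported hybrid
#' candidate, predicts each hypothesis's integer CN profile over the
#' locus, and keeps the hypothesis that agrees with the observed segments
#' (CN 0 over the downstream gene implies loss on both alleles, CN 1
#' exactly one altered allele, CN >= 3 a duplication on one allele).
#'
#' @param clusters an [cluster_alleles()] result.
#' @param segments a [segment_depth()] result.
#' @param pair the [generate_paralog_pair()] locus (gene models + contig).
#' @param profile the depth profile used for `segments` (window grid).
#' @param min_agreement minimum fraction of windows (outside expected
#'   breakpoint windows) whose state must match the hypothesis.
#' @return object of class `diplotype`: `allele1`, `allele2`
#'   ([allele_structure()]), `functional_class`, `agreement`, `flags`, and
#'   the segment table.
#' @export
integrate_diplotype <- function(clusters, segments, pair, profile,
                                min_agreement = 0.9) {
  stopifnot(inherits(clusters, "allele_clusters"))
  w <- profile$windows
  state_w <- rep(segments$state,
                 times = vapply(seq_len(nrow(segments)), function(k)
                   sum(w$start >= segments$start[k] & w$end <= segments$end[k]),
                   0L))
  stop_if(length(state_w) != nrow(w), "segments do not tile the windows")
  gb0 <- pair$model_b$gene_start
  gb1 <- gb0 + gene_length(pair$model_b)
  in_b <- w$start >= gb0 & w$end <= gb1
  max_state_b <- if (any(in_b)) max(state_w[in_b]) else 2L

  pairs <- hypothesis_pairs(clusters$candidates, max_state_b)
  # read-evidence feasibility: a biallelic whole deletion leaves nothing
  # to produce paralog-B votes, so supported pure-B reads rule it out
  if (clusters$counts[["pure_b"]] >= 3L)
    pairs <- Filter(function(h)
      !all(vapply(h, function(a) a$kind == "whole_deletion", TRUE)), pairs)
  win <- profile$window
  score_one <- function(hyp) {
    exp_ <- expected_cn_profile(hyp, pair, w$start, w$end)
    near_break <- rep(FALSE, nrow(w))
    for (b in exp_$breaks)
      near_break <- near_break | (w$start < b + win & w$end > b - win)
    use <- !near_break
    if (!any(use)) return(0)
    mean(exp_$cn[use] == state_w[use])
  }
  agree <- vapply(pairs, score_one, 0)
  n_sv <- vapply(pairs, function(h)
    sum(vapply(h, function(a) a$kind != "wild_type", TRUE)), 0L)
  ord <- order(-agree, n_sv)
  best <- ord[1]
  tie <- abs(agree - agree[best]) < 1e-12 & n_sv == n_sv[best]
  flags <- character()
  if (sum(tie) > 1L) flags <- c(flags, "ambiguous_hypothesis_tie")
  stop_if(agree[best] < min_agreement,
          "inconsistent evidence: best hypothesis explains only ",
          sprintf("%.0f%%", 100 * agree[best]), " of depth windows")
  if (any(segments$low_confidence)) flags <- c(flags, "low_confidence_cn")
  alleles <- pairs[[best]]
  dip <- structure(list(allele1 = alleles[[1]], allele2 = alleles[[2]],
                        functional_class = NA_character_,
                        agreement = agree[best], flags = flags,
                        segments = segments),
                   class = "diplotype")
  dip$functional_class <- classify_functional(dip)
  dip
}

#' @export
print.diplotype <- function(x, ...) {
  cat(sprintf("diplotype: %s / %s\n  class: %s (depth agreement %.2f)%s\n",
              x$allele1$name, x$allele2$name, x$functional_class,
              x$agreement,
              if (length(x$flags)) paste0("\n  flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

# An allele is "intact" when the full downstream-gene coding span derives
# from the downstream paralog with no deletion; small variants never
# change this call.
allele_intact <- function(a) {
  a$kind %in% c("wild_type", "duplication")
}

#' Classify a diplotype as deletion or retained type
#'
#' Retained: at least one allele carries an intact downstream gene
#' (wild-type or duplication of the intact gene). Deletion: a deletion or
#' hybrid on both alleles. An unresolved allele yields `"unclassifiable"`,
#' never a silent default.
#'
#' @param diplotype a [integrate_diplotype()] result, or a list with
#'   `allele1`/`allele2`.
#' @return `"retained"`, `"deletion"` or `"unclassifiable"`.
#' @export
classify_functional <- function(diplotype) {
  a1 <- diplotype$allele1; a2 <- diplotype$allele2
  if (is.null(a1) || is.null(a2) || !inherits(a1, "allele_structure") ||
      !inherits(a2, "allele_structure"))
    return("unclassifiable")
  if (allele_intact(a1) || allele_intact(a2)) "retained" else "deletion"
}

#' Parse a printed allele-structure string
#'
#' Accepts the controlled vocabulary used in the cohort tables:
#' `Wild-type::Wild-type`, `Wild-type::Dup`, `IGR::IGR` (whole deletion
#' spanning the intergenic region), `3'UTR::3'UTR` (coding-deletion hybrid
#' with the junction in the 3' UTRs) and `int<k>::int<k>` (hybrid with the
#' junction in intron k). Unicode prime and stray spaces are tolerated.
#'
#' @param s allele string.
#' @return an [allele_structure()].
#' @export
parse_allele_string <- function(s) {
  x <- gsub("\u2032", "'", trimws(s))
  x <- gsub("\\s+", "", x)
  if (x %in% c("Wild-type::Wild-type", "WT::WT"))
    return(allele_structure("wild_type"))
  if (x == "Wild-type::Dup")
    return(allele_structure("duplication", cn_status = "duplicated",
                            copy_count = 2L))
  if (x == "IGR::IGR")
    return(allele_structure("whole_deletion", cn_status = "deleted",
                            copy_count = 0L))
  if (x %in% c("3'UTR::3'UTR", "3UTR::3UTR"))
    return(allele_structure("hybrid", switch_segment = "utr3",
                            cn_status = "deleted", copy_count = 0L))
  m <- regmatches(x, regexec("^int([0-9]+)::int([0-9]+)$", x))[[1]]
  if (length(m) == 3L && m[2] == m[3])
    return(allele_structure("hybrid",
                            switch_segment = paste0("intron", m[2]),
                            cn_status = "deleted", copy_count = 0L))
  stop("unrecognized allele string: '", s, "'", call. = FALSE)
}

# Expected integer CN of each coding exon of the downstream gene under a
# pair of alleles (n_exons exons), used to audit a gene-level CNV value.
expected_exon_cn <- function(a1, a2, n_exons = 9L) {
  one <- function(a) {
    if (a$kind == "wild_type") rep(1L, n_exons)
    else if (a$kind == "duplication") rep(a$copy_count, n_exons)
    else if (a$kind == "whole_deletion") rep(0L, n_exons)
    else if (identical(a$switch_segment, "utr3")) rep(0L, n_exons)
    else {
      k <- as.integer(sub("^intron", "", a$switch_segment))
      c(rep(0L, k), rep(1L, n_exons - k))
    }
  }
  one(a1) + one(a2)
}
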