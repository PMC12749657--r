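# Penalized two-state changepoint segmentation of an A/B vote sequence.
# Objective: (# votes disagreeing with their segment state)
#            + (penalty + tie_eps) * (# changepoints),
# minimized exactly by dynamic programming over the two paralog states.
# tie_eps breaks cost ties toward fewer changepoints, making the optimum
# objective unique in value and comparable against exhaustive enumeration.
segment_votes_dp <- function(vote, penalty, tie_eps = 1e-9) {
  n <- length(vote)
  pen <- penalty + tie_eps
  mis_a <- as.numeric(vote != "A")
  mis_b <- as.numeric(vote != "B")
  cost_a <- numeric(n); cost_b <- numeric(n)
  from_a <- integer(n); from_b <- integer(n)   # 1 = stayed, 2 = switched
  cost_a[1] <- mis_a[1]; cost_b[1] <- mis_b[1]
  for (i in seq_len(n)[-1]) {
    stay <- cost_a[i - 1]; sw <- cost_b[i - 1] + pen
    if (stay <= sw) { cost_a[i] <- stay + mis_a[i]; from_a[i] <- 1L }
    else { cost_a[i] <- sw + mis_a[i]; from_a[i] <- 2L }
    stay <- cost_b[i - 1]; sw <- cost_a[i - 1] + pen
    if (stay <= sw) { cost_b[i] <- stay + mis_b[i]; from_b[i] <- 1L }
    else { cost_b[i] <- sw + mis_b[i]; from_b[i] <- 2L }
  }
  states <- character(n)
  states[n] <- if (cost_a[n] <= cost_b[n]) "A" else "B"
  for (i in rev(seq_len(n)[-1])) {
    switched <- if (states[i] == "A") from_a[i] == 2L else from_b[i] == 2L
    states[i - 1] <- if (switched) setdiff(c("A", "B"), states[i])
                     else states[i]
  }
  list(states = states, objective = min(cost_a[n], cost_b[n]),
       n_changes = sum(states[-1] != states[-n]))
}

#' Detect switch points in a read's PSV vote vector
#'
#' Minimal-changepoint segmentation of the A/B votes (ignoring `neither`
#' votes), with each changepoint penalized. A switch is emitted only if at
#' least `min_flank` votes consistent with the segment state lie on each
#' side; the default penalty guarantees that a single sequencing error can
#' never create a switch. The switch position is reported as the interval
#' between the flanking discordant PSVs — between near-identical paralogs
#' the junction is unidentifiable inside a PSV-free stretch, so a base
#' position is never claimed.
#'
#' @param votes a [vote_read()] result.
#' @param penalty changepoint penalty (mismatch units).
#' @param min_flank minimum consistent votes required on each side of a
#'   switch.
#' @return object of class `switch_calls`: data.frame `switches` (`lo`,
#'   `hi` gene-frame offsets of the flanking PSVs, `orientation`
#'   `"A->B"`/`"B->A"`), logical flags `uninformative` and `ambiguous`,
#'   and the DP diagnostics (`states`, `objective`, `n_changes`).
#' @export
detect_switch <- function(votes, penalty = 2, min_flank = 3L) {
  stopifnot(inherits(votes, "vote_vector"))
  keep <- votes$votes$vote != "neither"
  v <- votes$votes$vote[keep]
  off <- votes$votes$offset[keep]
  empty <- fast_df(list(lo = numeric(), hi = numeric(),
                        orientation = character()))
  if (length(v) < 2L) {
    return(structure(list(switches = empty, uninformative = TRUE,
                          ambiguous = FALSE, states = v, offsets = off,
                          objective = 0, n_changes = 0L,
                          read_id = votes$read_id),
                     class = "switch_calls"))
  }
  dp <- segment_votes_dp(v, penalty)
  states <- dp$states
  cp <- which(states[-1] != states[-length(states)])  # change after index cp
  # a chimeric/noisy read leaves many votes unexplained by the best
  # two-state segmentation; flag it rather than trusting the calls
  mismatch_frac <- (dp$objective - (penalty + 1e-9) * dp$n_changes) / length(v)
  ambiguous <- mismatch_frac > 0.2
  # enforce the flank requirement; dropping a changepoint merges segments,
  # so re-check until stable
  repeat {
    if (length(cp) == 0L) break
    bounds <- c(0L, cp, length(v))
    ok <- vapply(seq_along(cp), function(k) {
      li <- (bounds[k] + 1L):cp[k]
      ri <- (cp[k] + 1L):bounds[k + 2L]
      sum(v[li] == states[cp[k]]) >= min_flank &&
        sum(v[ri] == states[cp[k] + 1L]) >= min_flank
    }, TRUE)
    if (all(ok)) break
    ambiguous <- TRUE
    drop_k <- which(!ok)[1]
    # merge: re-label the shorter side with the longer side's state
    cp <- cp[-drop_k]
    bounds <- c(0L, cp, length(v))
    for (k in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[k] + 1L):bounds[k + 1L]
      maj <- names(which.max(table(v[seg])))
      states[seg] <- maj
    }
    cp <- which(states[-1] != states[-length(states)])
  }
  if (length(cp) > 0L) {
    sw <- fast_df(list(lo = off[cp], hi = off[cp + 1L],
                       orientation = paste0(states[cp], "->",
                                            states[cp + 1L])))
  } else sw <- empty
  structure(list(switches = sw, uninformative = FALSE,
                 ambiguous = ambiguous, states = states, offsets = off,
                 objective = dp$objective, n_changes = dp$n_changes,
                 read_id = votes$read_id),
            class = "switch_calls")
}

#' @export
print.switch_calls <- function(x, ...) {
  cat(sprintf("switch_calls %s: %d switch(es)%s\n", x$read_id,
              nrow(x$switches),
              if (x$ambiguous) " [ambiguous]"
              else if (x$uninformative) " [uninformative]" else ""))
  if (nrow(x$switches)) print(x$switches)
  invisible(x)
}

# Terminus-realignment rescue for junctions close to a gene end. The
# flank rule (>= min_flank concordant votes each side) cannot be met when
# fewer PSVs remain between the junction and the gene boundary — the
# situation of 3'UTR-junction hybrids, whose downstream discriminating
# stretch is the short UTR remainder. A read with a long concordant
# prefix and a short discordant tail (or head) at its terminus gets that
# terminus locally re-aligned against both paralog references; a
# confirmed opposite-paralog placement supplies the switch call. Two
# discordant votes are required, so a single sequencing error still
# cannot create a switch.
rescue_terminal_switch <- function(vv, maj, pair, min_flank,
                                   rescue_min = 2L, min_identity = 0.9) {
  keep <- vv$votes$vote != "neither"
  v <- vv$votes$vote[keep]
  off <- vv$votes$offset[keep]
  n <- length(v)
  opp <- if (maj == "A") "B" else "A"
  f0 <- vv$span[1]; f1 <- vv$span[2]
  try_realign <- function(r_start, r_end) {
    if (r_end - r_start + 1L < 30L) return(FALSE)
    term <- substr(vv$read_seq, r_start, r_end)
    hit <- tryCatch(realign_terminus(term, pair$seq_a, pair$seq_b,
                                     min_len = 30L,
                                     min_identity = min_identity),
                    error = function(e) list(placed = FALSE))
    isTRUE(hit$placed) && identical(hit$paralog, opp)
  }
  # trailing discordant run
  t_run <- 0L
  while (t_run < n && v[n - t_run] == opp) t_run <- t_run + 1L
  if (t_run >= rescue_min && t_run < min_flank &&
      sum(v[seq_len(n - t_run)] == maj) >= min_flank) {
    o_last <- off[n - t_run]
    r_start <- (o_last + 1L) - f0 + vv$read_from + 1L
    r_end <- vv$read_from + (f1 - f0)
    if (try_realign(r_start, r_end))
      return(list(lo = o_last, hi = off[n - t_run + 1L],
                  orientation = paste0(maj, "->", opp)))
  }
  # leading discordant run
  l_run <- 0L
  while (l_run < n && v[l_run + 1L] == opp) l_run <- l_run + 1L
  if (l_run >= rescue_min && l_run < min_flank &&
      sum(v[(l_run + 1L):n] == maj) >= min_flank) {
    o_first <- off[l_run + 1L]
    r_start <- vv$read_from + 1L
    r_end <- (o_first - 1L) - f0 + vv$read_from + 1L
    if (try_realign(r_start, r_end))
      return(list(lo = off[l_run], hi = o_first,
                  orientation = paste0(opp, "->", maj)))
  }
  NULL
}

# Segment label for a switch interval: the label shared by both flanking
# PSVs, else the label at the interval midpoint.
switch_label <- function(lo, hi, model) {
  la <- segment_at_offset(model, lo)
  lb <- segment_at_offset(model, hi)
  if (!is.na(la) && identical(la, lb)) la
  else segment_at_offset(model, floor((lo + hi) / 2))
}

#' Cluster per-read switch calls into allele candidates
#'
#' Reads (gene-instance placements) are grouped by their switch-point
#' signature: no switch (pure paralog A or B) or a single switch keyed by
#' segment label and orientation. The supported switch groups become
#' hybrid allele candidates; reads with unresolvable (ambiguous/chimeric)
#' vote patterns and groups below the support threshold are discarded as
#' noise. More than two well-supported switch groups is an error
#' (contamination or unmodelled copy number).
#'
#' @param vote_list list of [vote_read()] results (one per read placement).
#' @param psv the [build_psv_table()] used for voting (provides the gene
#'   model for segment labels).
#' @param min_reads minimum informative placements required.
#' @param min_support minimum reads for a switch group to become a
#'   candidate.
#' @param penalty,min_flank passed to [detect_switch()].
#' @param pair optional [generate_paralog_pair()] locus; when supplied,
#'   no-switch reads with a short discordant run (>= 2 votes) at a
#'   terminus are rescued by re-aligning that terminus against both
#'   paralogs ([realign_terminus()]), recovering junctions too close to
#'   a gene end to satisfy the flank rule (3'UTR hybrids).
#' @return object of class `allele_clusters`: `candidates` (list of hybrid
#'   [allele_structure()]s with consensus SP intervals and support),
#'   `counts` (pure_a, pure_b, uninformative, ambiguous, discarded),
#'   `assignment` data.frame (read id, group).
#' @export
cluster_alleles <- function(vote_list, psv, min_reads = 10L,
                            min_support = 3L, penalty = 2, min_flank = 3L,
                            pair = NULL) {
  stopifnot(inherits(psv, "psv_table"))
  calls <- lapply(vote_list, detect_switch, penalty = penalty,
                  min_flank = min_flank)
  group <- character(length(calls))
  lo <- hi <- rep(NA_real_, length(calls))
  for (i in seq_along(calls)) {
    s <- calls[[i]]
    if (s$uninformative) { group[i] <- "uninformative"; next }
    if (s$ambiguous) { group[i] <- "ambiguous"; next }
    if (nrow(s$switches) == 0L) {
      maj <- if (sum(s$states == "A") >= sum(s$states == "B")) "A" else "B"
      resc <- if (!is.null(pair) && !is.null(vote_list[[i]]$read_seq))
        rescue_terminal_switch(vote_list[[i]], maj, pair, min_flank)
      else NULL
      if (!is.null(resc)) {
        lab <- switch_label(resc$lo, resc$hi, psv$model_a)
        group[i] <- paste0("SP:", lab, ":", resc$orientation)
        lo[i] <- resc$lo; hi[i] <- resc$hi
        next
      }
      group[i] <- paste0("pure", maj)
    } else if (nrow(s$switches) == 1L) {
      lab <- switch_label(s$switches$lo[1], s$switches$hi[1], psv$model_a)
      group[i] <- paste0("SP:", lab, ":", s$switches$orientation[1])
      lo[i] <- s$switches$lo[1]; hi[i] <- s$switches$hi[1]
    } else {
      group[i] <- "ambiguous"
    }
  }
  informative <- sum(!group %in% c("uninformative"))
  stop_if(informative < min_reads, "only ", informative,
          " informative read placements (< min_reads = ", min_reads, ")")
  sp_groups <- grep("^SP:", unique(group), value = TRUE)
  support <- vapply(sp_groups, function(g) sum(group == g), 0L)
  keep <- sp_groups[support >= min_support]
  discarded <- sum(support[!sp_groups %in% keep])
  stop_if(length(keep) > 2L,
          "more than two well-supported alleles; check contamination or CN")
  candidates <- lapply(keep, function(g) {
    idx <- which(group == g)
    # the true junction lies inside every supporting read's interval, so
    # the intersection is the tightest consistent bound
    clo <- max(lo[idx]); chi <- min(hi[idx])
    if (chi < clo) { clo <- median(lo[idx]); chi <- median(hi[idx]) }
    lab <- switch_label(clo, chi, psv$model_a)
    st <- allele_structure("hybrid", switch_segment = lab,
                           sp_interval = c(clo, chi),
                           cn_status = "deleted", copy_count = 0L,
                           support = length(idx))
    st$orientation <- sub("^SP:[^:]+:", "", g)
    st
  })
  structure(list(candidates = candidates,
                 counts = c(pure_a = sum(group == "pureA"),
                            pure_b = sum(group == "pureB"),
                            uninformative = sum(group == "uninformative"),
                            ambiguous = sum(group == "ambiguous"),
                            discarded = discarded),
                 assignment = data.frame(
                   read_id = vapply(vote_list, function(v)
                     v$read_id %||% NA_character_, ""),
                   group = group, stringsAsFactors = FALSE)),
            class = "allele_clusters")
}

#' @export
print.allele_clusters <- function(x, ...) {
  cat(sprintf("allele_clusters: %d hybrid candidate(s); pureA=%d pureB=%d ambiguous=%d\n",
              length(x$candidates), x$counts["pure_a"], x$counts["pure_b"],
              x$counts["ambiguous"]))
  for (c_ in x$candidates)
    cat(sprintf("  %s [support %d, SP interval (%g, %g]]\n", c_$name,
                c_$support, c_$sp_interval[1], c_$sp_interval[2]))
  invisible(x)
}

#' PharmVar-style name of an allele structure
#'
#' Hybrid alleles with the switch position in intron k are named for the
#' exons retained from the upstream paralog
#' (`SV:CYP2A7::CYP2A6 hybrid (exons 1-k from CYP2A7)`); the known
#' 3'UTR-junction hybrid deleting the whole CYP2A6 coding region is the
#' *4-like deletion.
#'
#' @param structure an [allele_structure()].
#' @return a character name, a pure function of the structure.
#' @export
name_allele <- function(structure) {
  k <- structure$kind
  if (k == "wild_type") return("wild-type")
  if (k == "whole_deletion") return("CYP2A6 whole-gene deletion (*4-like)")
  if (k == "duplication")
    return(sprintf("CYP2A6 duplication (x%d)", structure$copy_count))
  seg <- structure$switch_segment
  if (identical(seg, "utr3"))
    return("CYP2A6*4-like deletion (CYP2A7::CYP2A6 3'UTR junction)")
  n <- as.integer(sub("^intron", "", seg))
  stop_if(is.na(n), "cannot name hybrid with switch segment '", seg, "'")
  if (n == 1L) "SV:CYP2A7::CYP2A6 hybrid (exon 1 from CYP2A7)"
  else sprintf("SV:CYP2A7::CYP2A6 hybrid (exons 1\u2013%d from CYP2A7)", n)
}
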