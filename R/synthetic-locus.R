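#' Specification of a synthetic paralog pair
#'
#' Parameters for a two-gene locus modelled on CYP2A7/CYP2A6: two paralogs
#' of equal length and shared exon structure on one synthetic contig
#' (upstream flank, gene A = CYP2A7 analog, intergenic gap, gene B = CYP2A6
#' analog, downstream flank), differing only at substitution sites
#' (paralog-specific variants, PSVs).
#'
#' `psv_rate` defaults to `1 - identity`; supplying both with a discrepancy
#' above one percentage point is rejected as inconsistent.
#'
#' @param length paralog length in bp.
#' @param identity target pairwise identity of the two paralogs, in (0,1).
#'   The locus mimics loci with >90\% inter-paralog identity.
#' @param n_exons number of exons (>= 2) shared by the two gene models.
#' @param psv_rate per-bp substitution probability between the paralogs.
#' @param intergenic_gap bp between gene A end and gene B start.
#' @param flank bp of flanking sequence on each side of the gene pair; the
#'   left flank doubles as the diploid depth-normalization control region.
#' @param seed integer seed; every generator derived from the spec is a
#'   pure function of (spec, seed).
#' @return an object of class `paralog_pair_spec`.
#' @export
paralog_pair_spec <- function(length = 6000L, identity = 0.95, n_exons = 9L,
                              psv_rate = 1 - identity,
                              intergenic_gap = 4000L, flank = 2000L,
                              seed = 1L) {
  stop_if(identity <= 0 || identity >= 1, "identity must be in (0,1)")
  stop_if(n_exons < 2L, "n_exons must be >= 2")
  stop_if(length < 50L * n_exons, "length too short for n_exons")
  stop_if(abs(psv_rate - (1 - identity)) > 0.01,
          "identity/psv_rate inconsistent: psv_rate = ", psv_rate,
          " but 1 - identity = ", 1 - identity)
  structure(list(length = as.integer(length), identity = identity,
                 n_exons = as.integer(n_exons), psv_rate = psv_rate,
                 intergenic_gap = as.integer(intergenic_gap),
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "paralog_pair_spec")
}

# Shared within-gene layout (gene-frame offsets): exon1, intron1, ...,
# exonN, 3'UTR filling the gene to exactly `length` bp.
gene_layout <- function(length, n_exons) {
  exon_len <- max(60L, as.integer(round(0.025 * length)))
  utr3_len <- max(150L, as.integer(round(0.04 * length)))
  intron_space <- length - n_exons * exon_len - utr3_len
  stop_if(intron_space < (n_exons - 1L) * 50L,
          "length too short for n_exons with minimum intron size")
  intron_len <- intron_space %/% (n_exons - 1L)
  starts <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    pos <- pos + exon_len + if (i < n_exons) intron_len else 0L
  }
  exons <- cbind(start = starts, end = starts + exon_len)
  utr3 <- c(exons[n_exons, "end"], length)
  list(exons = exons, utr3 = utr3)
}

#' Generate a synthetic paralog pair with truth PSV list
#'
#' Gene A is drawn uniformly at random; gene B is gene A with independent
#' Bernoulli(`psv_rate`) substitutions (no indels, so the two paralogs
#' share one coordinate frame). The full contig is
#' flank | gene A | intergenic gap | gene B | flank.
#'
#' @param spec a [paralog_pair_spec()].
#' @return an object of class `paralog_pair` with elements `seq_a`, `seq_b`
#'   (character), `model_a`, `model_b` ([gene_model()] in contig
#'   coordinates), `contig`, and `psv_truth` (data.frame: gene-frame
#'   `offset`, `base_a`, `base_b`, contig positions `pos_a`, `pos_b`,
#'   `segment` label).
#' @export
generate_paralog_pair <- function(spec) {
  stopifnot(inherits(spec, "paralog_pair_spec"))
  local_seed(spec$seed, {
    L <- spec$length
    a <- sample(DNA, L, replace = TRUE)
    idx <- which(runif(L) < spec$psv_rate)
    b <- substitute_bases(a, idx)
    flankL <- sample(DNA, spec$flank, replace = TRUE)
    gap <- sample(DNA, spec$intergenic_gap, replace = TRUE)
    flankR <- sample(DNA, spec$flank, replace = TRUE)

    lay <- gene_layout(L, spec$n_exons)
    ga0 <- spec$flank
    gb0 <- spec$flank + L + spec$intergenic_gap
    model_a <- gene_model("geneA", lay$exons + ga0, lay$utr3 + ga0, "+")
    model_b <- gene_model("geneB", lay$exons + gb0, lay$utr3 + gb0, "+")

    psv <- data.frame(offset = idx - 1L, base_a = a[idx], base_b = b[idx],
                      stringsAsFactors = FALSE)
    psv$pos_a <- ga0 + psv$offset
    psv$pos_b <- gb0 + psv$offset
    psv$segment <- segment_at_offset(model_a, psv$offset)

    structure(list(spec = spec,
                   seq_a = paste(a, collapse = ""),
                   seq_b = paste(b, collapse = ""),
                   model_a = model_a, model_b = model_b,
                   contig = paste0(paste(flankL, collapse = ""),
                                   paste(a, collapse = ""),
                                   paste(gap, collapse = ""),
                                   paste(b, collapse = ""),
                                   paste(flankR, collapse = "")),
                   psv_truth = psv),
              class = "paralog_pair")
  })
}

#' @export
print.paralog_pair <- function(x, ...) {
  cat(sprintf(paste0("paralog_pair: 2 x %d bp genes (identity %.3f realized),",
                     " contig %d bp, %d truth PSVs\n"),
              x$spec$length, 1 - nrow(x$psv_truth) / x$spec$length,
              nchar(x$contig), nrow(x$psv_truth)))
  invisible(x)
}

gene_starts <- function(pair) {
  c(a = pair$model_a$gene_start, b = pair$model_b$gene_start)
}

#' Reverse-complement a paralog pair
#'
#' Mirrors the whole locus to the minus strand: the contig and both paralog
#' sequences are reverse-complemented, gene models get mirrored coordinates
#' with flipped strand (so exon numbering in transcription order is
#' preserved), and the truth PSV list is re-expressed in the mirrored
#' frame. Used to check that calling is strand-safe.
#'
#' @param pair a [generate_paralog_pair()] result.
#' @return a `paralog_pair` on the opposite strand.
#' @export
flip_pair <- function(pair) {
  clen <- nchar(pair$contig)
  L <- pair$spec$length
  mirror_model <- function(m, name) {
    ex <- cbind(start = clen - m$exons[, "end"], end = clen - m$exons[, "start"])
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    utr3 <- c(clen - m$utr3[2], clen - m$utr3[1])
    gene_model(name, ex, utr3, if (m$strand == "+") "-" else "+")
  }
  comp <- function(x) chartr("ACGT", "TGCA", x)
  psv <- pair$psv_truth
  psv2 <- data.frame(offset = L - 1L - psv$offset,
                     base_a = comp(psv$base_a), base_b = comp(psv$base_b),
                     pos_a = clen - 1L - psv$pos_a,
                     pos_b = clen - 1L - psv$pos_b,
                     segment = psv$segment, stringsAsFactors = FALSE)
  psv2 <- psv2[order(psv2$offset), ]
  rownames(psv2) <- NULL
  out <- pair
  out$seq_a <- revcomp_chr(pair$seq_a)
  out$seq_b <- revcomp_chr(pair$seq_b)
  out$contig <- revcomp_chr(pair$contig)
  out$model_a <- mirror_model(pair$model_a, pair$model_a$name)
  out$model_b <- mirror_model(pair$model_b, pair$model_b$name)
  out$psv_truth <- psv2
  out
}

#' Specification of one simulated allele
#'
#' @param kind `"wild_type"`, `"whole_deletion"`, `"duplication"` or
#'   `"hybrid"`.
#' @param switch_segment for hybrids: the intron label (e.g. `"intron1"`)
#'   or `"utr3"` containing the junction.
#' @param copy_count for duplications: total tandem copies of gene B
#'   (>= 2).
#' @return an object of class `sim_allele_spec`.
#' @export
allele_spec <- function(kind, switch_segment = NULL, copy_count = NULL) {
  stop_if(!kind %in% c("wild_type", "whole_deletion", "duplication", "hybrid"),
          "unknown allele kind: ", kind)
  stop_if(kind == "hybrid" && is.null(switch_segment),
          "hybrid allele requires switch_segment")
  stop_if(kind == "duplication" && (is.null(copy_count) || copy_count < 2L),
          "duplication requires copy_count >= 2")
  structure(list(kind = kind,
                 switch_segment = if (is.null(switch_segment)) NA_character_
                                  else switch_segment,
                 copy_count = if (is.null(copy_count)) {
                   if (kind %in% c("whole_deletion", "hybrid")) 0L else 1L
                 } else as.integer(copy_count)),
            class = "sim_allele_spec")
}

# Junction offset (gene frame) for a hybrid allele: midpoint of the chosen
# segment. The base-level junction is unobservable between PSV-free bases,
# so the midpoint is a truth-metadata convention, not an inference claim.
junction_offset <- function(pair, switch_segment) {
  iv <- segment_interval(pair$model_a, switch_segment)
  as.integer(floor((iv["start"] + iv["end"]) / 2))
}

# Truth SP interval: flanking PSV offsets around the junction.
truth_sp_interval <- function(pair, j) {
  off <- pair$psv_truth$offset
  lo <- max(off[off < j], -Inf)
  hi <- min(off[off >= j], Inf)
  c(lo, hi)
}

# Build one haplotype (sequence + truth structure) from an allele spec.
# The hybrid joins the genomically-left gene's start through its junction
# point to the right gene from its junction point on, removing the
# intervening copy: a single fused gene (deletion-type hybrid).
build_haplotype <- function(spec, pair) {
  stopifnot(inherits(spec, "sim_allele_spec"))
  contig <- pair$contig
  clen <- nchar(contig)
  L <- pair$spec$length
  ga0 <- pair$model_a$gene_start
  gb0 <- pair$model_b$gene_start
  left0 <- min(ga0, gb0)   # genomically left gene start (B when flipped)
  right0 <- max(ga0, gb0)

  if (spec$kind == "wild_type") {
    seq <- contig
    structure_ <- allele_structure("wild_type")
    instances <- list(
      list(hap_start = ga0, len = L, type = "A", junction = NA),
      list(hap_start = gb0, len = L, type = "B", junction = NA))
    cn <- NULL            # 1x everywhere
  } else if (spec$kind == "hybrid") {
    seg <- segment_interval(pair$model_a, spec$switch_segment)  # validates
    j <- junction_offset(pair, spec$switch_segment)
    d0 <- left0 + j
    d1 <- right0 + j
    seq <- paste0(substr(contig, 1L, d0), substr(contig, d1 + 1L, clen))
    structure_ <- allele_structure("hybrid",
                                   switch_segment = spec$switch_segment,
                                   junction = j,
                                   sp_interval = truth_sp_interval(pair, j),
                                   cn_status = "deleted", copy_count = 0L)
    instances <- list(list(hap_start = left0, len = L, type = "fused",
                           junction = j))
    cn <- list(list(start = d0, end = d1, copy = 0L))
  } else if (spec$kind == "whole_deletion") {
    seq <- paste0(substr(contig, 1L, gb0), substr(contig, gb0 + L + 1L, clen))
    structure_ <- allele_structure("whole_deletion", cn_status = "deleted",
                                   copy_count = 0L)
    # on a flipped locus gene B lies left of gene A, shifting A's
    # haplotype position by the deleted length
    a_start <- if (ga0 > gb0) ga0 - L else ga0
    instances <- list(list(hap_start = a_start, len = L, type = "A",
                           junction = NA))
    cn <- list(list(start = gb0, end = gb0 + L, copy = 0L))
  } else {                # duplication
    cc <- spec$copy_count
    geneB <- substr(contig, gb0 + 1L, gb0 + L)
    seq <- paste0(substr(contig, 1L, gb0 + L),
                  paste(rep(geneB, cc - 1L), collapse = ""),
                  substr(contig, gb0 + L + 1L, clen))
    structure_ <- allele_structure("duplication", cn_status = "duplicated",
                                   copy_count = cc)
    a_start <- if (ga0 > gb0) ga0 + (cc - 1L) * L else ga0
    instances <- c(list(list(hap_start = a_start, len = L, type = "A",
                             junction = NA)),
                   lapply(seq_len(cc) - 1L, function(k)
                     list(hap_start = gb0 + k * L, len = L, type = "B",
                          junction = NA)))
    cn <- list(list(start = gb0, end = gb0 + L, copy = cc))
  }
  structure_$instances <- instances
  structure_$cn_intervals <- cn
  list(seq = seq, structure = structure_)
}

#' Build the two haplotype sequences of a diplotype
#'
#' @param allele1,allele2 [allele_spec()] objects.
#' @param pair a [generate_paralog_pair()] result.
#' @return an object of class `sim_diplotype`: `haplotypes` (character
#'   vector of length 2) and `structures` (list of two truth
#'   [allele_structure()]s, each carrying its gene-instance map and CN
#'   intervals).
#' @export
build_diplotype_sequences <- function(allele1, allele2, pair) {
  h1 <- build_haplotype(allele1, pair)
  h2 <- build_haplotype(allele2, pair)
  structure(list(haplotypes = c(h1$seq, h2$seq),
                 structures = list(h1$structure, h2$structure),
                 pair = pair),
            class = "sim_diplotype")
}

#' @export
print.sim_diplotype <- function(x, ...) {
  cat(sprintf("sim_diplotype: %s / %s\n",
              x$structures[[1]]$name, x$structures[[2]]$name))
  invisible(x)
}

#' Simulate long reads from haplotypes with truth labels
#'
#' Read starts are uniform over each haplotype; lengths are normal with the
#' given mean/sd, truncated to `[min_len, haplotype length]`; sequencing
#' errors are i.i.d. substitutions (no indels, matching the PSV-voting
#' model downstream).
#'
#' @param diplotype a [build_diplotype_sequences()] result, or a character
#'   vector of haplotype sequences.
#' @param mean_len,len_sd read length distribution in bp (defaults mirror a
#'   kilobase-scale synthetic long-read regime, 4700 +/- 2900 bp).
#' @param per_base_error substitution error rate per base.
#' @param depth fold coverage per haplotype.
#' @param seed integer seed.
#' @param min_len minimum read length after truncation.
#' @return object of class `sim_read_set`: data.frame `reads` (read_id,
#'   hap, start, length, sequence) plus the simulation parameters.
#' @export
simulate_long_reads <- function(diplotype, mean_len = 4700, len_sd = 2900,
                                per_base_error = 0.01, depth = 30,
                                seed = 1L, min_len = 300L) {
  haps <- if (inherits(diplotype, "sim_diplotype")) diplotype$haplotypes
          else as.character(diplotype)
  stop_if(depth <= 0, "depth must be > 0")
  hlens <- nchar(haps)
  stop_if(mean_len > min(hlens),
          "mean_len exceeds haplotype length (", min(hlens), " bp)")
  local_seed(seed, {
    rows <- list()
    for (h in seq_along(haps)) {
      n <- as.integer(round(depth * hlens[h] / mean_len))
      len <- as.integer(pmin(pmax(round(rnorm(n, mean_len, len_sd)), min_len),
                             hlens[h]))
      start <- as.integer(floor(runif(n, 0, hlens[h] - len + 1)))
      seqs <- substring(haps[h], start + 1L, start + len)
      if (per_base_error > 0) {
        seqs <- vapply(seqs, function(s) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ne <- rbinom(1L, length(ch), per_base_error)
          if (ne > 0L)
            ch <- substitute_bases(ch, sample.int(length(ch), ne))
          paste(ch, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      rows[[h]] <- data.frame(hap = h, start = start, length = len,
                              sequence = seqs, stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, rows)
    reads <- cbind(read_id = sprintf("read_%04d", seq_len(nrow(reads))),
                   reads)
    structure(list(reads = reads, mean_len = mean_len, len_sd = len_sd,
                   per_base_error = per_base_error, depth = depth,
                   seed = seed),
              class = "sim_read_set")
  })
}

#' @export
print.sim_read_set <- function(x, ...) {
  cat(sprintf("sim_read_set: %d reads, mean length %.0f bp (target %.0f), error %.3f\n",
              nrow(x$reads), mean(x$reads$length), x$mean_len,
              x$per_base_error))
  invisible(x)
}

# Per-base true copy number over the contig implied by two truth
# structures (sums each allele's contribution).
true_cn_vector <- function(diplotype) {
  clen <- nchar(diplotype$pair$contig)
  cn <- rep(0L, clen)
  for (s in diplotype$structures) {
    v <- rep(1L, clen)
    for (iv in s$cn_intervals %||% list())
      v[(iv$start + 1L):iv$end] <- iv$copy
    cn <- cn + v
  }
  cn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a windowed short-read depth profile
#'
#' Expected depth per window is proportional to the true copy count under
#' the diplotype, with multiplicative lognormal noise of the given
#' coefficient of variation. Depth is normalized to copy-number units
#' against the median depth of the diploid control region (the left flank).
#'
#' @param diplotype a [build_diplotype_sequences()] result.
#' @param window window width in bp (>= 50).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param base_depth haploid-equivalent sequencing depth at CN 2.
#' @param seed integer seed.
#' @return object of class `depth_profile`: `windows` data.frame (start,
#'   end, depth, cn_true, cn_norm), `baseline` (median control depth) and
#'   the control interval.
#' @export
simulate_depth_profile <- function(diplotype, window = 100L, noise_cv = 0.1,
                                   base_depth = 30, seed = 1L) {
  stop_if(window < 50L, "window must be >= 50 bp")
  stopifnot(inherits(diplotype, "sim_diplotype"))
  clen <- nchar(diplotype$pair$contig)
  cn <- true_cn_vector(diplotype)
  starts <- seq(0L, clen - window, by = window)
  ends <- starts + window
  cn_true <- vapply(seq_along(starts), function(i)
    mean(cn[(starts[i] + 1L):ends[i]]), 0)
  local_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- rlnorm(length(starts), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    depth <- base_depth / 2 * cn_true * noise
  })
  control <- c(0L, diplotype$pair$spec$flank)
  in_ctl <- starts >= control[1] & ends <= control[2]
  baseline <- median(depth[in_ctl])
  windows <- data.frame(start = starts, end = ends, depth = depth,
                        cn_true = cn_true,
                        cn_norm = if (baseline > 0) 2 * depth / baseline
                                  else NA_real_)
  structure(list(windows = windows, baseline = baseline, window = window,
                 control = control, noise_cv = noise_cv),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d windows of %d bp, baseline %.2f\n",
              nrow(x$windows), x$window, x$baseline))
  invisible(x)
}
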