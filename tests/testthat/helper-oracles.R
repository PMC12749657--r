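# Independent oracles used across tests. These deliberately avoid the
# code paths they check.

# Exhaustive minimal-changepoint enumeration: minimum over all 2^n state
# paths of (#mismatches) + (penalty + eps) * (#changes). Plain loops.
brute_force_segmentation <- function(votes, penalty = 2, eps = 1e-9) {
  n <- length(votes)
  best <- Inf
  best_changes <- NA_integer_
  for (mask in 0:(2^n - 1)) {
    states <- ifelse(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L, "B", "A")
    changes <- sum(states[-1] != states[-n])
    obj <- sum(states != votes) + (penalty + eps) * changes
    if (obj < best) { best <- obj; best_changes <- changes }
  }
  list(objective = best, n_changes = best_changes)
}

# Vectorized exhaustive enumeration over many patterns at once: for each
# pattern (rows of 0/1 matrix X), the minimum objective over all state
# paths. Mismatch counts come from one matrix product; the tie-breaking
# epsilon makes the optimum objective unique.
brute_force_all_patterns <- function(n, penalty = 2, eps = 1e-4,
                                     chunk = 2048L) {
  codes <- 0:(2^n - 1)
  bits <- function(v) t(vapply(v, function(m)
    as.integer(bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L)), integer(n)))
  P <- bits(codes)                      # all state paths (0 = A, 1 = B)
  path_changes <- rowSums(abs(P[, -1, drop = FALSE] -
                                P[, -n, drop = FALSE]))
  # mismatches(x, p) = sum(x) + sum(p) - 2 * x . p, so with the per-path
  # constant c = sum(p) + pen(p) folded into an extra matrix column the
  # whole objective (minus the per-pattern constant sum(x)) is one
  # matrix product
  c_path <- rowSums(P) + (penalty + eps) * path_changes
  P_aug <- cbind(-2 * P, c_path)
  out_obj <- numeric(length(codes))
  for (lo in seq(1L, length(codes), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(codes))
    X <- bits(codes[lo:hi])
    obj <- tcrossprod(cbind(X, 1), P_aug)  # obj[i,j] = c_j - 2 x_i . p_j
    # ties.method = "first" compares exactly; the default "random" uses a
    # relative fuzz that would blur the tie-breaking epsilon
    best <- max.col(-obj, ties.method = "first")
    out_obj[lo:hi] <- rowSums(X) + obj[cbind(seq_len(nrow(obj)), best)]
  }
  out_obj
}

# Welch's t-test from the textbook formulas.
welch_direct <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-signature non-negative fit by grid search over the first weight.
grid_search_two_sig <- function(v, S, step = 0.01) {
  ws <- seq(0, 1, by = step)
  rss <- vapply(ws, function(w) {
    x <- c(w, 1 - w)
    sum((as.numeric(S %*% x) - v)^2)
  }, 0)
  ws[which.min(rss)]
}

# Small fast locus used throughout the unit tests (alignment stays well
# under a second).
small_spec <- function(seed = 1L, ...) {
  paralog_pair_spec(length = 2500L, identity = 0.95, n_exons = 9L,
                    intergenic_gap = 1200L, flank = 600L, seed = seed, ...)
}

small_sim <- function(allele1, allele2, seed = 1L, per_base_error = 0.01,
                      depth = 30, mean_len = 1800, len_sd = 700) {
  pair <- generate_paralog_pair(small_spec(seed))
  dip <- build_diplotype_sequences(allele1, allele2, pair)
  reads <- simulate_long_reads(dip, mean_len = mean_len, len_sd = len_sd,
                               per_base_error = per_base_error,
                               depth = depth, seed = seed + 100L)
  profile <- simulate_depth_profile(dip, seed = seed + 200L)
  list(pair = pair, diplotype = dip, reads = reads, profile = profile)
}

small_config <- function(seed = 1L) {
  pipeline_config(seed = seed, pair_spec = small_spec(seed),
                  mean_len = 1800, len_sd = 700)
}

psv_of <- function(pair) {
  build_psv_table(align_paralogs(pair$seq_a, pair$seq_b),
                  pair$model_a, pair$model_b)
}

# vote_vector constructed directly from a vote string like "AABB" with
# PSV offsets supplied (for changepoint tests that bypass reads).
make_votes <- function(pattern, offsets = NULL) {
  v <- strsplit(pattern, "", fixed = TRUE)[[1]]
  v[v == "N"] <- "neither"
  if (is.null(offsets)) offsets <- seq(10, by = 10, length.out = length(v))
  structure(list(votes = data.frame(offset = offsets,
                                    observed = rep("N", length(v)),
                                    vote = v, stringsAsFactors = FALSE),
                 read_id = "synthetic", span = range(offsets),
                 informative = sum(v != "neither")),
            class = "vote_vector")
}
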