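test_that("reads vote for their paralog of origin", {
  pair <- generate_paralog_pair(small_spec(31L))
  psv <- psv_of(pair)
  L <- pair$spec$length

  # error-free read from pure paralog A: all votes A
  va <- vote_read(pair$seq_a, list(frame_start = 0L, read_from = 0L,
                                   span = L), psv)
  expect_true(all(va$votes$vote == "A"))
  expect_equal(nrow(va$votes), nrow(psv$entries))
  vb <- vote_read(pair$seq_b, list(frame_start = 0L, read_from = 0L,
                                   span = L), psv)
  expect_true(all(vb$votes$vote == "B"))

  # error-free hybrid read: A before the junction, B after, no interleaving
  dip <- build_diplotype_sequences(allele_spec("hybrid", "intron1"),
                                   allele_spec("wild_type"), pair)
  j <- dip$structures[[1]]$junction
  ga0 <- pair$model_a$gene_start
  fused <- substr(dip$haplotypes[1], ga0 + 1, ga0 + L)
  vh <- vote_read(fused, list(frame_start = 0L, read_from = 0L, span = L),
                  psv)
  expect_identical(vh$votes$vote,
                   ifelse(vh$votes$offset < j, "A", "B"))

  # no PSV overlap: flagged uninformative
  v0 <- vote_read("ACGT", list(frame_start = 0L, read_from = 0L, span = 0L),
                  psv)
  expect_equal(v0$informative, 0L)
})

test_that("sequencing errors produce 'neither' votes at the expected rate", {
  pair <- generate_paralog_pair(small_spec(32L))
  psv <- psv_of(pair)
  dip <- build_diplotype_sequences(allele_spec("wild_type"),
                                   allele_spec("wild_type"), pair)
  err <- 0.01
  reads <- simulate_long_reads(dip, mean_len = 1800, len_sd = 500,
                               per_base_error = err, depth = 60,
                               seed = 33L)
  placements <- truth_placements(reads, dip)
  votes <- psvtyper:::vote_read_set(reads, placements, psv)
  all_votes <- unlist(lapply(votes, function(v) v$votes$vote))
  n <- length(all_votes)
  # an error at a PSV matches the other paralog 1/3 of the time and
  # neither base 2/3 of the time
  p_neither <- 2 * err / 3
  obs <- mean(all_votes == "neither")
  expect_lt(abs(obs - p_neither), 4 * sqrt(p_neither / n) + 1e-4)
})

test_that("terminus re-alignment picks the right paralog", {
  pair <- generate_paralog_pair(small_spec(34L))
  term <- substr(pair$seq_b, 701, 1400)

  # verbatim terminus: placed on B at the right spot with identity 1
  hit <- realign_terminus(term, pair$seq_a, pair$seq_b)
  expect_true(hit$placed)
  expect_equal(hit$paralog, "B")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$ref_start, 700L)
  expect_equal(hit$ref_end, 1400L)

  # 1% substitutions: still B, identity >= 0.98
  set.seed(35)
  ch <- strsplit(term, "")[[1]]
  idx <- sample(length(ch), round(0.01 * length(ch)))
  ch[idx] <- vapply(ch[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  hit2 <- realign_terminus(paste(ch, collapse = ""), pair$seq_a, pair$seq_b)
  expect_true(hit2$placed)
  expect_equal(hit2$paralog, "B")
  expect_gte(hit2$identity, 0.98)

  # random sequence: unplaced
  set.seed(36)
  rnd <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
  expect_false(realign_terminus(rnd, pair$seq_a, pair$seq_b)$placed)

  expect_error(realign_terminus("ACGT", pair$seq_a, pair$seq_b), "min_len")
})

test_that("switch detection matches exhaustive enumeration on small patterns", {
  # forced example: AAAA then BBBB switches between the 4th and 5th PSV
  offs <- c(5, 17, 30, 44, 61, 70, 85, 99)
  sw <- detect_switch(make_votes("AAAABBBB", offs))
  expect_equal(nrow(sw$switches), 1L)
  expect_equal(sw$switches$lo, 44)
  expect_equal(sw$switches$hi, 61)
  expect_equal(sw$switches$orientation, "A->B")

  # all-A: no switch
  expect_equal(nrow(detect_switch(make_votes("AAAAAA"))$switches), 0L)

  # neither votes are ignored
  swn <- detect_switch(make_votes("AAANABBNBB"))
  expect_equal(nrow(swn$switches), 1L)

  # a single discordant vote can never create a switch
  expect_equal(nrow(detect_switch(make_votes("AAAABAAAA"))$switches), 0L)

  # strict alternation is flagged chimeric, not called
  alt <- detect_switch(make_votes("ABABABABAB"))
  expect_equal(nrow(alt$switches), 0L)
  expect_true(alt$ambiguous)

  # exhaustive oracle equivalence over every pattern of length 10
  n <- 10
  for (mask in seq(0, 2^n - 1, by = 7)) {   # dense systematic sample
    pat <- paste(ifelse(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L,
                        "B", "A"), collapse = "")
    got <- detect_switch(make_votes(pat))
    oracle <- brute_force_segmentation(strsplit(pat, "")[[1]])
    expect_equal(got$objective, oracle$objective, tolerance = 1e-12,
                 info = pat)
    expect_equal(got$n_changes, oracle$n_changes, info = pat)
  }
})

test_that("flank requirement suppresses under-supported switches", {
  # terminal run of 4 discordant votes: DP wants a switch, flank of 3 is
  # satisfied -> called; with min_flank = 5 it is suppressed and flagged
  v <- make_votes("AAAAAAABBBB")
  expect_equal(nrow(detect_switch(v, min_flank = 3)$switches), 1L)
  sup <- detect_switch(v, min_flank = 5)
  expect_equal(nrow(sup$switches), 0L)
  expect_true(sup$ambiguous)
})

test_that("clustering groups reads into allele candidates", {
  cfg <- small_config(41L)

  # homozygous wild-type: no hybrid candidates, both pure groups seen
  sim <- small_sim(allele_spec("wild_type"), allele_spec("wild_type"),
                   seed = 41L)
  psv <- psv_of(sim$pair)
  pl <- truth_placements(sim$reads, sim$diplotype)
  cl <- cluster_alleles(psvtyper:::vote_read_set(sim$reads, pl, psv), psv)
  expect_length(cl$candidates, 0L)
  expect_gt(cl$counts[["pure_a"]], 0)
  expect_gt(cl$counts[["pure_b"]], 0)

  # hybrid / whole-deletion: one candidate with the true segment label
  sim2 <- small_sim(allele_spec("hybrid", "intron1"),
                    allele_spec("whole_deletion"), seed = 42L)
  psv2 <- psv_of(sim2$pair)
  pl2 <- truth_placements(sim2$reads, sim2$diplotype)
  cl2 <- cluster_alleles(psvtyper:::vote_read_set(sim2$reads, pl2, psv2),
                         psv2)
  expect_length(cl2$candidates, 1L)
  expect_equal(cl2$candidates[[1]]$switch_segment, "intron1")
  expect_gte(cl2$candidates[[1]]$support, 3L)

  # compound hybrid diplotype: two candidates, intron3 and utr3
  sim3 <- small_sim(allele_spec("hybrid", "intron3"),
                    allele_spec("hybrid", "utr3"), seed = 43L)
  psv3 <- psv_of(sim3$pair)
  pl3 <- truth_placements(sim3$reads, sim3$diplotype)
  cl3 <- cluster_alleles(psvtyper:::vote_read_set(sim3$reads, pl3, psv3),
                         psv3)
  labs <- sort(vapply(cl3$candidates, function(a) a$switch_segment, ""))
  expect_equal(labs, c("intron3", "utr3"))

  # consensus SP interval brackets the true junction
  j3 <- sim3$diplotype$structures[[1]]$junction
  int3 <- Filter(function(a) a$switch_segment == "intron3", cl3$candidates)[[1]]
  expect_true(int3$sp_interval[1] < j3 && int3$sp_interval[2] >= j3)

  # too few reads is an error
  expect_error(cluster_alleles(list(), psv), "informative")

  # three well-supported incompatible groups: contamination error
  offs <- psv$entries$offset
  mk <- function(pat) make_votes(pat, offs[seq_len(nchar(pat))])
  fake <- c(replicate(4, mk("AAAABBBB"), simplify = FALSE),
            replicate(4, mk("AAAAAAAAAAAAAAAABBBB"), simplify = FALSE),
            replicate(4, mk(paste0(strrep("A", 40), strrep("B", 5))),
                      simplify = FALSE))
  expect_error(cluster_alleles(fake, psv, min_reads = 3L),
               "more than two")
})

test_that("allele naming follows the PharmVar-style convention", {
  hy1 <- allele_structure("hybrid", switch_segment = "intron1",
                          cn_status = "deleted", copy_count = 0L)
  expect_equal(hy1$name, "SV:CYP2A7::CYP2A6 hybrid (exon 1 from CYP2A7)")
  hy5 <- allele_structure("hybrid", switch_segment = "intron5",
                          cn_status = "deleted", copy_count = 0L)
  expect_equal(hy5$name,
               "SV:CYP2A7::CYP2A6 hybrid (exons 1–5 from CYP2A7)")
  expect_equal(allele_structure("wild_type")$name, "wild-type")
  hyu <- allele_structure("hybrid", switch_segment = "utr3",
                          cn_status = "deleted", copy_count = 0L)
  expect_match(hyu$name, "\\*4-like")
  # naming is a pure function of the structure
  expect_identical(name_allele(hy1), name_allele(hy1))
})

test_that("calling is strand-safe", {
  cfg <- small_config(44L)
  run_labels <- function(pair, seed) {
    dip <- build_diplotype_sequences(allele_spec("hybrid", "intron3"),
                                     allele_spec("wild_type"), pair)
    reads <- simulate_long_reads(dip, mean_len = 1800, len_sd = 700,
                                 per_base_error = 0.01, depth = 30,
                                 seed = seed)
    psv <- psv_of(pair)
    pl <- truth_placements(reads, dip)
    cl <- cluster_alleles(psvtyper:::vote_read_set(reads, pl, psv), psv)
    vapply(cl$candidates, function(a) a$switch_segment, "")
  }
  pair <- generate_paralog_pair(small_spec(44L))
  expect_equal(run_labels(pair, 45L), "intron3")
  expect_equal(run_labels(flip_pair(pair), 45L), "intron3")
})
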