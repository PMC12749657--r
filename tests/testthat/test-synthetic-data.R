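test_that("paralog pair generation honors identity and records truth PSVs", {
  # identity case: (near-)zero substitution rate leaves B identical to A
  spec0 <- paralog_pair_spec(length = 600L, identity = 0.9999, psv_rate = 0,
                             n_exons = 2L, intergenic_gap = 300L,
                             flank = 100L, seed = 3L)
  p0 <- generate_paralog_pair(spec0)
  expect_identical(p0$seq_a, p0$seq_b)
  expect_equal(nrow(p0$psv_truth), 0L)

  # realized identity and Hamming oracle at the stated scale
  spec <- paralog_pair_spec(length = 30000L, identity = 0.95, seed = 7L)
  p <- generate_paralog_pair(spec)
  ham <- sum(strsplit(p$seq_a, "")[[1]] != strsplit(p$seq_b, "")[[1]])
  expect_equal(nrow(p$psv_truth), ham)
  realized <- 1 - ham / 30000
  expect_gte(realized, 0.94)
  expect_lte(realized, 0.96)

  # determinism: same spec, same bytes
  expect_identical(generate_paralog_pair(spec), p)

  # inconsistent identity/psv_rate is rejected with a named message
  expect_error(paralog_pair_spec(identity = 0.95, psv_rate = 0.2),
               "psv_rate")
})

test_that("realized identity stays within one point of target across seeds", {
  devs <- vapply(1:25, function(s) {
    p <- generate_paralog_pair(small_spec(s))
    abs((1 - nrow(p$psv_truth) / p$spec$length) - 0.95)
  }, 0)
  expect_lt(max(devs), 0.01)
})

test_that("diplotype construction produces the specified architectures", {
  pair <- generate_paralog_pair(small_spec(5L))
  contig <- pair$contig
  ga0 <- pair$model_a$gene_start
  gb0 <- pair$model_b$gene_start
  L <- pair$spec$length

  # wild-type: both haplotypes equal the unmodified reference
  wt <- build_diplotype_sequences(allele_spec("wild_type"),
                                  allele_spec("wild_type"), pair)
  expect_identical(wt$haplotypes[1], contig)
  expect_identical(wt$haplotypes[2], contig)

  # intron-1 hybrid: exon 1 from paralog A, exons 2..n from paralog B
  hy <- build_diplotype_sequences(allele_spec("hybrid", "intron1"),
                                  allele_spec("wild_type"), pair)
  st <- hy$structures[[1]]
  j <- st$junction
  iv <- psvtyper:::segment_interval(pair$model_a, "intron1")
  expect_gte(j, iv["start"]); expect_lt(j, iv["end"])
  expect_identical(hy$haplotypes[1],
                   paste0(substr(contig, 1, ga0 + j),
                          substr(contig, gb0 + j + 1, nchar(contig))))
  # fused gene content: exon1 region matches paralog A, exon 2..n region
  # matches paralog B
  fused <- substr(hy$haplotypes[1], ga0 + 1, ga0 + L)
  expect_identical(substr(fused, 1, j), substr(pair$seq_a, 1, j))
  expect_identical(substr(fused, j + 1, L), substr(pair$seq_b, j + 1, L))
  # truth SP interval brackets the junction with PSV endpoints
  expect_true(st$sp_interval[1] < j && st$sp_interval[2] >= j)
  expect_true(all(st$sp_interval %in% pair$psv_truth$offset))

  # 3'UTR hybrid removes the whole gene-B coding region
  hu <- build_diplotype_sequences(allele_spec("hybrid", "utr3"),
                                  allele_spec("wild_type"), pair)
  ex_b <- pair$model_b$exons
  for (i in seq_len(nrow(ex_b))) {
    exon_seq <- substr(contig, ex_b[i, "start"] + 1, ex_b[i, "end"])
    expect_false(grepl(exon_seq, hu$haplotypes[1], fixed = TRUE),
                 info = sprintf("gene-B exon %d should be deleted", i))
  }

  # whole deletion removes exactly the gene-B span; duplication repeats it
  de <- build_diplotype_sequences(allele_spec("whole_deletion"),
                                  allele_spec("duplication",
                                              copy_count = 3L), pair)
  expect_identical(nchar(de$haplotypes[1]), nchar(contig) - L)
  expect_identical(nchar(de$haplotypes[2]), nchar(contig) + 2L * L)

  # unknown switch segment is rejected
  expect_error(build_diplotype_sequences(allele_spec("hybrid", "intron99"),
                                         allele_spec("wild_type"), pair),
               "intron99")
})

test_that("read simulation matches its declared distributions", {
  pair <- generate_paralog_pair(paralog_pair_spec(length = 30000L,
                                                  seed = 2L))
  dip <- build_diplotype_sequences(allele_spec("wild_type"),
                                   allele_spec("wild_type"), pair)
  hap <- dip$haplotypes[1]

  # error-free reads are exact substrings
  rs0 <- simulate_long_reads(hap, mean_len = 5000, len_sd = 2000,
                             per_base_error = 0, depth = 3, seed = 9L)
  hits <- vapply(seq_len(nrow(rs0$reads)), function(i)
    substr(hap, rs0$reads$start[i] + 1,
           rs0$reads$start[i] + rs0$reads$length[i]) ==
      rs0$reads$sequence[i], TRUE)
  expect_true(all(hits))

  # read count near depth * L / mean_len, mean length within 10%
  rs <- simulate_long_reads(hap, mean_len = 5000, len_sd = 2900,
                            per_base_error = 0.01, depth = 30, seed = 10L)
  n_expect <- 30 * nchar(hap) / 5000
  expect_lt(abs(nrow(rs$reads) - n_expect), 3 * sqrt(n_expect) + 1)
  expect_lt(abs(mean(rs$reads$length) - 5000) / 5000, 0.1)

  # determinism down to FASTQ bytes
  rs2 <- simulate_long_reads(hap, mean_len = 5000, len_sd = 2900,
                             per_base_error = 0.01, depth = 30, seed = 10L)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  psvtyper:::write_fastq(rs, f1); psvtyper:::write_fastq(rs2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(simulate_long_reads(substr(hap, 1, 1000), mean_len = 5000,
                                   depth = 10), "mean_len")
})

test_that("depth profiles track true copy number", {
  pair <- generate_paralog_pair(small_spec(8L))
  gb0 <- pair$model_b$gene_start
  L <- pair$spec$length

  # homozygous whole deletion: CN 0 over gene B
  dd <- build_diplotype_sequences(allele_spec("whole_deletion"),
                                  allele_spec("whole_deletion"), pair)
  pr <- simulate_depth_profile(dd, seed = 1L)
  in_b <- pr$windows$start >= gb0 & pr$windows$end <= gb0 + L
  expect_true(all(pr$windows$cn_true[in_b] == 0))
  expect_true(all(pr$windows$depth[in_b] == 0))

  # heterozygous deletion: CN 1 over gene B, 2 elsewhere
  hd <- build_diplotype_sequences(allele_spec("wild_type"),
                                  allele_spec("whole_deletion"), pair)
  pr2 <- simulate_depth_profile(hd, seed = 2L)
  expect_true(all(pr2$windows$cn_true[in_b] == 1))
  out_b <- pr2$windows$end <= gb0 | pr2$windows$start >= gb0 + L
  expect_true(all(pr2$windows$cn_true[out_b] == 2))

  # noise averages out: per-segment mean normalized CN near truth (a
  # larger flank gives the baseline estimate a decent control region)
  pair_big <- generate_paralog_pair(
    paralog_pair_spec(length = 2500L, intergenic_gap = 2000L,
                      flank = 5000L, seed = 8L))
  hd_big <- build_diplotype_sequences(allele_spec("wild_type"),
                                      allele_spec("whole_deletion"),
                                      pair_big)
  mads <- vapply(1:10, function(s) {
    p <- simulate_depth_profile(hd_big, noise_cv = 0.1, seed = s)
    use <- p$windows$cn_true %in% c(1, 2)
    segs <- split(seq_len(nrow(p$windows))[use], p$windows$cn_true[use])
    mean(vapply(names(segs), function(k)
      abs(mean(p$windows$cn_norm[segs[[k]]]) - as.numeric(k)), 0))
  }, 0)
  expect_lt(mean(mads), 0.05)

  expect_error(simulate_depth_profile(hd, window = 20L), "window")
})

test_that("mutation catalogs follow the signature mixture", {
  S <- synthetic_signature_matrix()

  # pure signature: multinomial counts match the column (chi-square GOF)
  cat1 <- simulate_mutation_catalog(1e5, c(sbs4_like = 1), S, seed = 4L)
  gof <- suppressWarnings(
    chisq.test(cat1$counts, p = S[, "sbs4_like"]))
  expect_gt(gof$p.value, 1e-3)

  # empty catalog
  cat0 <- simulate_mutation_catalog(0, c(flat = 1), S, seed = 1L)
  expect_equal(sum(cat0$counts), 0)
  expect_equal(compute_tmb(cat0)$tmb, 0)

  expect_error(simulate_mutation_catalog(10, c(nope = 1), S), "nope")
  expect_error(simulate_mutation_catalog(10, c(flat = 0.7), S), "sum to 1")
})

test_that("truth serialization round-trips", {
  pair <- generate_paralog_pair(small_spec(12L))
  dip <- build_diplotype_sequences(allele_spec("hybrid", "intron3"),
                                   allele_spec("duplication",
                                               copy_count = 2L), pair)
  path <- tempfile(fileext = ".json")
  psvtyper:::write_truth_json(dip, path)
  back <- psvtyper:::read_truth_json(path)
  for (i in 1:2) {
    orig <- dip$structures[[i]]
    got <- back$alleles[[i]]
    for (f in c("kind", "switch_segment", "cn_status", "copy_count", "name"))
      expect_identical(got[[f]], orig[[f]], info = f)
    expect_equal(got$sp_interval, unname(orig$sp_interval))
  }
  expect_equal(back$psv$offset, dip$pair$psv_truth$offset)
  expect_equal(back$psv$base_a, dip$pair$psv_truth$base_a)
})
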