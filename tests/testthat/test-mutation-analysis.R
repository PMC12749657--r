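test_that("TMB is mutations per callable megabase", {
  expect_equal(compute_tmb(0, footprint_mb = 40)$tmb, 0)
  expect_equal(compute_tmb(100, footprint_mb = 40)$tmb, 2.5)
  expect_error(compute_tmb(10, footprint_mb = 0), "footprint")

  # variant-table input restricted to exonic rows
  vt <- data.frame(pos = 1:10, exonic = rep(c(TRUE, FALSE), 5))
  expect_equal(compute_tmb(vt, footprint_mb = 1)$tmb, 5)

  # catalog input: simulated counts land where the generator put them
  S <- synthetic_signature_matrix()
  cat_ <- simulate_mutation_catalog(320, c(flat = 1), S, seed = 2L,
                                    footprint_mb = 40)
  expect_equal(compute_tmb(cat_)$tmb, 8)
})

test_that("Welch's t-test matches the direct-formula oracle", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_t(a, b)
  oracle <- welch_direct(a, b)
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p, oracle$p, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- welch_t(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # symmetry: swapping groups negates t, preserves p
  sw <- welch_t(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)

  # zero-variance guard
  degen <- welch_t(c(1, 1), c(2, 2))
  expect_equal(degen$p, 0)
  expect_true(is.infinite(degen$t))
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)

  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("NNLS refitting recovers generating mixtures", {
  S <- synthetic_signature_matrix()

  # exact catalog: exposure 1.0, residual 0
  cat1 <- structure(list(sample_id = "exact",
                         counts = setNames(round(1e6 * S[, "sbs4_like"]),
                                           rownames(S)),
                         footprint_mb = 40),
                    class = "mutation_catalog")
  fit1 <- fit_signatures(cat1, S)
  expect_gt(fit1$fractions["sbs4_like"], 0.999)
  expect_lt(fit1$residual, 1e-3)

  # 0.7/0.3 mixture at n = 50000: recovery within 0.03 per component
  cat2 <- simulate_mutation_catalog(5e4, c(sbs4_like = 0.7, flat = 0.3), S,
                                    seed = 11L)
  fit2 <- fit_signatures(cat2, S)
  expect_lt(abs(fit2$fractions["sbs4_like"] - 0.7), 0.03)
  expect_lt(abs(fit2$fractions["flat"] - 0.3), 0.03)

  # two-signature NNLS equals the grid-search oracle
  S2 <- S[, c("sbs4_like", "sbs92_like")]
  cat3 <- simulate_mutation_catalog(5e4, c(sbs4_like = 0.4,
                                           sbs92_like = 0.6), S,
                                    seed = 12L)
  v <- as.numeric(cat3$counts) / sum(cat3$counts)
  w_grid <- grid_search_two_sig(v, S2, step = 0.01)
  fit3 <- fit_signatures(cat3, S2)
  expect_lt(abs(fit3$fractions["sbs4_like"] - w_grid), 0.011)

  # exclusion list is applied before fitting
  fit4 <- fit_signatures(cat2, S, exclude = "sbs92_like")
  expect_false("sbs92_like" %in% names(fit4$fractions))

  # empty catalog is an explicit error
  cat0 <- simulate_mutation_catalog(0, c(flat = 1), S)
  expect_error(fit_signatures(cat0, S), "empty catalog")
})

test_that("adding a generative signature never worsens the NNLS residual", {
  S <- synthetic_signature_matrix()
  cat_ <- simulate_mutation_catalog(2e4, c(sbs4_like = 0.5, flat = 0.5), S,
                                    seed = 13L)
  r_partial <- fit_signatures(cat_, S[, "flat", drop = FALSE])$residual
  r_full <- fit_signatures(cat_, S[, c("flat", "sbs4_like")])$residual
  expect_lte(r_full, r_partial + 1e-12)
})

test_that("minor signatures merge into 'others' conserving mass", {
  S <- synthetic_signature_matrix()
  ex <- structure(list(fractions = c(S1 = 0.5, S2 = 0.15, SBS4 = 0.1,
                                     S3 = 0.25),
                       raw = NULL, residual = 0, n_mutations = 100,
                       sample_id = "x"),
                  class = "signature_exposure")
  m <- merge_minor(ex, threshold = 0.2, protected = c("SBS4", "SBS92"))
  expect_equal(unname(m$fractions["SBS4"]), 0.1)     # protected, kept
  expect_equal(unname(m$fractions["others"]), 0.15)  # only S2 is minor
  expect_equal(unname(m$fractions["S3"]), 0.25)      # above threshold
  expect_equal(sum(m$fractions), sum(ex$fractions))

  # all minor and unprotected: a single others bucket
  ex2 <- ex; ex2$fractions <- c(a = 0.1, b = 0.1, c = 0.8 * 0.2, d = 0.64)
  ex2$fractions <- ex2$fractions / sum(ex2$fractions)
  m2 <- merge_minor(ex2, threshold = 0.9, protected = character())
  expect_equal(unname(m2$fractions[["others"]]), 1)

  # threshold 0 is the identity transform
  m3 <- merge_minor(ex, threshold = 0)
  expect_equal(m3$fractions[names(ex$fractions)], ex$fractions)
})

test_that("class summaries report TMB tests and signature presence", {
  S <- synthetic_signature_matrix()
  # two identical classes: p = 1, equal presence
  tmb_same <- rbind(
    data.frame(sample_id = paste0("d", 1:3), tmb = c(2, 3, 4),
               functional_class = "deletion", stratum = "all"),
    data.frame(sample_id = paste0("r", 1:3), tmb = c(2, 3, 4),
               functional_class = "retained", stratum = "all"))
  ex_same <- setNames(lapply(1:6, function(i)
    fit_signatures(simulate_mutation_catalog(1000, c(flat = 1), S,
                                             seed = 100L),
                   S)), c(paste0("d", 1:3), paste0("r", 1:3)))
  rep1 <- summarize_by_class(tmb_same, ex_same,
                             signatures_of_interest = c("sbs4_like"))
  expect_equal(rep1$tests$p, 1)
  expect_equal(unique(rep1$presence$fraction_detected),
               rep1$presence$fraction_detected[1])

  # a stratum with < 2 samples per group is skipped with a notice
  tmb_small <- tmb_same
  tmb_small$stratum <- c("lung", "other", "other", rep("lung", 3))
  rep2 <- summarize_by_class(tmb_small, ex_same,
                             signatures_of_interest = "sbs4_like")
  expect_match(rep2$tests$note[rep2$tests$stratum == "other"], "skipped")

  # unclassified samples are rejected
  tmb_bad <- tmb_same; tmb_bad$functional_class[1] <- NA
  expect_error(summarize_by_class(tmb_bad, ex_same), "classified")
})

test_that("a genotype-conditioned cohort shows the smoking-signature split", {
  S <- synthetic_signature_matrix()
  # signatures are fitted on genome-wide catalogs (thousands of
  # mutations), TMB on the exonic count over a 40 Mb footprint
  build_cohort <- function(n, mix, tmb_mean, class, seed0) {
    lapply(seq_len(n), function(i) {
      cat_ <- simulate_mutation_catalog(round(tmb_mean * 3000), mix, S,
                                        seed = seed0 + i,
                                        sample_id = sprintf("%s%02d",
                                                            class, i))
      exonic <- withr::with_seed(seed0 + i, rpois(1, tmb_mean * 40))
      list(catalog = cat_, tmb = compute_tmb(exonic, footprint_mb = 40,
                                             sample_id = cat_$sample_id))
    })
  }
  del <- build_cohort(7, c(flat = 0.7, sbs92_like = 0.3), 2, "del", 500L)
  ret <- build_cohort(7, c(flat = 0.6, sbs4_like = 0.4), 8, "ret", 600L)
  cohort <- c(del, ret)
  tmb <- do.call(rbind, lapply(cohort, `[[`, "tmb"))
  tmb$functional_class <- rep(c("deletion", "retained"), each = 7)
  tmb$stratum <- "lung"
  fits <- setNames(lapply(cohort, function(s)
    fit_signatures(s$catalog, S)), tmb$sample_id)
  rep_ <- summarize_by_class(tmb, fits,
                             signatures_of_interest = c("sbs4_like",
                                                        "sbs92_like"))
  pres <- rep_$presence
  sbs4_del <- pres$fraction_detected[pres$signature == "sbs4_like" &
                                       pres$functional_class == "deletion"]
  sbs4_ret <- pres$fraction_detected[pres$signature == "sbs4_like" &
                                       pres$functional_class == "retained"]
  expect_equal(sbs4_del, 0)
  expect_equal(sbs4_ret, 1)
  expect_lt(rep_$tests$p, 0.05)
  del_mean <- rep_$tmb_summary$mean_tmb[
    rep_$tmb_summary$functional_class == "deletion"]
  ret_mean <- rep_$tmb_summary$mean_tmb[
    rep_$tmb_summary$functional_class == "retained"]
  expect_lt(del_mean, ret_mean)
})

test_that("VCF catalogs count trinucleotide contexts correctly", {
  skip_if_not_installed("vcfR")
  ref <- c(chr1 = "TTACGTAGCTAGGCTTA")
  # SNVs: pos 4 C>T in ACG context -> A[C>T]G
  #       pos 7 A>C in TAG context -> (purine) revcomp CTA -> C[T>G]A
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=17>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t4\t.\tC\tT\t.\tPASS\t.",
           "chr1\t7\t.\tA\tC\t.\tPASS\t.",
           "chr1\t10\t.\tC\tCA\t.\tPASS\t.")   # indel: ignored
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  cat_ <- catalog_from_vcf(path, ref)
  expect_equal(sum(cat_$counts), 2)
  expect_equal(unname(cat_$counts["A[C>T]G"]), 1L)
  expect_equal(unname(cat_$counts["C[T>G]A"]), 1L)
})
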