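#' Pipeline configuration
#'
#' Central bag of parameters for the simulate/call workflow; every
#' parameter has a default, and the effective configuration is serialized
#' alongside the outputs of [run_simulate()] / [run_call()] so a run can
#' be re-executed bit-identically.
#'
#' @param seed master integer seed.
#' @param pair_spec a [paralog_pair_spec()].
#' @param alleles list of two [allele_spec()]s defining the simulated
#'   diplotype.
#' @param mean_len,len_sd,per_base_error,depth long-read simulation
#'   parameters (see [simulate_long_reads()]).
#' @param window,noise_cv,base_depth depth-profile parameters (see
#'   [simulate_depth_profile()]).
#' @param penalty,min_flank switch-detection parameters (see
#'   [detect_switch()]).
#' @param min_reads,min_support clustering parameters (see
#'   [cluster_alleles()]).
#' @param min_windows,guard depth segmentation parameters (see
#'   [segment_depth()]).
#' @param out_dir output directory for file-writing runs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            pair_spec = paralog_pair_spec(seed = seed),
                            alleles = list(allele_spec("wild_type"),
                                           allele_spec("wild_type")),
                            mean_len = 4700, len_sd = 2900,
                            per_base_error = 0.01, depth = 30,
                            window = 100L, noise_cv = 0.1, base_depth = 30,
                            penalty = 2, min_flank = 3L,
                            min_reads = 10L, min_support = 3L,
                            min_windows = 5L, guard = 0.35,
                            out_dir = tempfile("psvtyper_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields override [pipeline_config()] defaults; `pair_spec` and
#' `alleles` may be given as nested maps.
#'
#' @param path YAML or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$pair_spec))
    args$pair_spec <- do.call(paralog_pair_spec, raw$pair_spec)
  if (!is.null(raw$alleles))
    args$alleles <- lapply(raw$alleles, function(a) do.call(allele_spec, a))
  scalars <- setdiff(names(raw), c("pair_spec", "alleles"))
  args[scalars] <- raw[scalars]
  do.call(pipeline_config, args)
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_fastq <- function(read_set, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(read_set$reads$sequence,
                                                read_set$reads$read_id))
  q <- Biostrings::BStringSet(vapply(nchar(read_set$reads$sequence),
                                     function(n)
                                       paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

write_depth_tsv <- function(profile, path, contig = "synthetic_locus") {
  df <- data.frame(contig = contig, start = profile$windows$start,
                   end = profile$windows$end,
                   depth = profile$windows$depth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Truth sidecar: enough to reload the simulated diplotype structures and
# PSV list and compare them field-by-field (truth round-trip).
write_truth_json <- function(diplotype, path) {
  strip <- function(s)
    s[c("kind", "switch_segment", "junction", "sp_interval", "cn_status",
        "copy_count", "name")]
  jsonlite::write_json(
    list(alleles = lapply(diplotype$structures, strip),
         psv = diplotype$pair$psv_truth),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  alleles <- lapply(seq_len(nrow(x$alleles)), function(i) {
    a <- x$alleles[i, ]
    st <- allele_structure(a$kind,
                           switch_segment = a$switch_segment %||% NA_character_,
                           junction = a$junction %||% NA_integer_,
                           sp_interval = unlist(a$sp_interval),
                           cn_status = a$cn_status,
                           copy_count = a$copy_count)
    st
  })
  list(alleles = alleles, psv = x$psv)
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes paralog references and haplotypes (FASTA), long reads (FASTQ),
#' the windowed depth table (TSV), the truth sidecar (JSON) and a manifest
#' with MD5 checksums. Partial output is removed on failure.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory objects (`pair`,
#'   `diplotype`, `reads`, `profile`) and `manifest`.
#' @export
run_simulate <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(config$out_dir, recursive = TRUE))
  pair <- generate_paralog_pair(config$pair_spec)
  dip <- build_diplotype_sequences(config$alleles[[1]], config$alleles[[2]],
                                   pair)
  reads <- simulate_long_reads(dip, mean_len = config$mean_len,
                               len_sd = config$len_sd,
                               per_base_error = config$per_base_error,
                               depth = config$depth, seed = config$seed)
  profile <- simulate_depth_profile(dip, window = config$window,
                                    noise_cv = config$noise_cv,
                                    base_depth = config$base_depth,
                                    seed = config$seed + 1L)
  paths <- file.path(config$out_dir,
                     c(refs = "references.fasta",
                       haps = "haplotypes.fasta",
                       reads = "reads.fastq", depth = "depth.tsv",
                       truth = "truth.json", config = "config.json"))
  names(paths) <- c("refs", "haps", "reads", "depth", "truth", "config")
  write_fasta(c(geneA = pair$seq_a, geneB = pair$seq_b, contig = pair$contig),
              paths["refs"])
  write_fasta(stats::setNames(dip$haplotypes, c("hap1", "hap2")),
              paths["haps"])
  write_fastq(reads, paths["reads"])
  write_depth_tsv(profile, paths["depth"])
  write_truth_json(dip, paths["truth"])
  serialize_config(config, paths["config"])
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(list(pair = pair, diplotype = dip, reads = reads,
                 profile = profile, manifest = manifest,
                 out_dir = config$out_dir))
}

serialize_config <- function(config, path) {
  x <- config
  x$out_dir <- NULL   # path is machine-local, not part of provenance
  x$pair_spec <- unclass(x$pair_spec)
  x$alleles <- lapply(x$alleles, unclass)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Call a diplotype end-to-end on a simulated locus
#'
#' Runs the full inference chain: paralog alignment, PSV-table
#' construction, read voting with truth placements, per-read switch
#' detection, clustering into allele candidates, depth segmentation, and
#' CN integration into a classified diplotype. When `out_dir` is given,
#' writes the allele-call JSON, a diplotype TSV row and a symbolic-SV VCF.
#'
#' @param sim a [run_simulate()] result (or a list with `pair`,
#'   `diplotype`, `reads`, `profile`).
#' @param config a [pipeline_config()] (thresholds).
#' @param out_dir optional output directory.
#' @param psv optional precomputed [build_psv_table()] (skips alignment).
#' @return the [integrate_diplotype()] result, with the cluster object
#'   attached as attribute `clusters`.
#' @export
run_call <- function(sim, config = pipeline_config(), out_dir = NULL,
                     psv = NULL) {
  pair <- sim$pair
  if (is.null(psv)) {
    al <- align_paralogs(pair$seq_a, pair$seq_b)
    psv <- build_psv_table(al, pair$model_a, pair$model_b)
  }
  placements <- truth_placements(sim$reads, sim$diplotype)
  votes <- vote_read_set(sim$reads, placements, psv)
  clusters <- cluster_alleles(votes, psv, min_reads = config$min_reads,
                              min_support = config$min_support,
                              penalty = config$penalty,
                              min_flank = config$min_flank, pair = pair)
  segments <- segment_depth(sim$profile, min_windows = config$min_windows,
                            guard = config$guard)
  dip <- integrate_diplotype(clusters, segments, pair, sim$profile)
  attr(dip, "clusters") <- clusters
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(candidates = lapply(clusters$candidates, function(a)
        a[c("kind", "switch_segment", "sp_interval", "name", "support")]),
        counts = as.list(clusters$counts)),
      file.path(out_dir, "allele_calls.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    write.table(data.frame(allele1 = dip$allele1$name,
                           allele2 = dip$allele2$name,
                           class = dip$functional_class,
                           agreement = dip$agreement,
                           flags = paste(dip$flags, collapse = ";")),
                file.path(out_dir, "diplotype.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_sv_vcf(dip, pair, file.path(out_dir, "sv_calls.vcf"))
  }
  dip
}

#' Write symbolic structural-variant VCF records for a diplotype
#'
#' Whole-gene deletions become symbolic `<DEL>` records; hybrid junctions
#' become breakend (BND) mates with `CIPOS` spanning the switch-position
#' interval (the junction is only resolvable to the PSV-free stretch
#' between the flanking discriminating sites).
#'
#' @param diplotype a [integrate_diplotype()] result.
#' @param pair the locus ([generate_paralog_pair()]).
#' @param path output VCF path.
#' @param contig contig name used in the records.
#' @export
write_sv_vcf <- function(diplotype, pair, path, contig = "synthetic_locus") {
  ga0 <- pair$model_a$gene_start
  gb0 <- pair$model_b$gene_start
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contig,
                     nchar(pair$contig)),
             "##ALT=<ID=DEL,Description=\"Deletion\">",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of SV\">",
             "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
             "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO"), collapse = "\t")))
  rec <- character()
  n <- 0L
  for (a in list(diplotype$allele1, diplotype$allele2)) {
    if (a$kind == "whole_deletion") {
      n <- n + 1L
      pos <- gb0              # 1-based POS of base before the event
      rec <- c(rec, sprintf("%s\t%d\tDEL%d\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d",
                            contig, pos, n, gb0 + gene_length(pair$model_b)))
    } else if (a$kind == "hybrid") {
      n <- n + 1L
      lo <- a$sp_interval[1]; hi <- a$sp_interval[2]
      mid <- floor((lo + hi) / 2)
      p1 <- min(ga0, gb0) + mid + 1L
      p2 <- max(ga0, gb0) + mid + 1L
      ci <- sprintf("CIPOS=%d,%d", as.integer(lo - mid),
                    as.integer(hi - mid))
      rec <- c(rec,
               sprintf("%s\t%d\tBND%da\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=BND%db;%s",
                       contig, p1, n, contig, p2, n, ci),
               sprintf("%s\t%d\tBND%db\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=BND%da;%s",
                       contig, p2, n, contig, p1, n, ci))
    }
  }
  writeLines(c(lines, rec), path)
  invisible(path)
}

#' Reference cohort fixtures
#'
#' A published 20-patient reference cohort of CYP2A6 structural-variant
#' typing, shipped as plain TSVs: per-patient clinical fields with the
#' gene-level CYP2A6 CNV value, and the per-allele structure strings with
#' the reported genome class.
#'
#' @return list of two data.frames: `cnv` (patient, sex, age, smoking,
#'   tumor_type, cyp2a6_cnv) and `alleles` (patient, tumor_type, amplicon,
#'   allele1, allele2, genome_class).
#' @export
cohort_fixtures <- function() {
  dir <- system.file("extdata", package = "psvtyper")
  list(cnv = read.delim(file.path(dir, "cohort_cnv.tsv"),
                        stringsAsFactors = FALSE),
       alleles = read.delim(file.path(dir, "cohort_alleles.tsv"),
                            stringsAsFactors = FALSE))
}

#' Reproduce the cohort genome classification from fixtures
#'
#' For each patient, parses the two allele-structure strings, audits them
#' against the gene-level CNV value (integer state via [round_half_up()]
#' with the guard band; a state outside the range implied by the alleles
#' is listed as a discrepancy, not resolved), applies the
#' deletion/retained rule, and compares with the reported class.
#'
#' @param fixtures a [cohort_fixtures()]-shaped list; defaults to the
#'   shipped cohort.
#' @param guard guard band for the low-confidence CNV flag.
#' @return object of class `cohort_report`: per-patient data.frame
#'   (`patient`, `allele1`, `allele2`, `predicted_class`,
#'   `reported_class`, `concordant`, `cnv`, `cnv_state`, `cnv_low_conf`,
#'   `cnv_discrepant`), allele-category counts, and the concordance
#'   summary.
#' @export
run_tables <- function(fixtures = cohort_fixtures(), guard = 0.35) {
  al <- fixtures$alleles
  if (nrow(al) == 0L)
    return(structure(list(per_patient = al, n = 0L, n_concordant = 0L,
                          allele_counts = table(character())),
                     class = "cohort_report"))
  cnv <- fixtures$cnv
  rows <- lapply(seq_len(nrow(al)), function(i) {
    a1 <- parse_allele_string(al$allele1[i])
    a2 <- parse_allele_string(al$allele2[i])
    cls <- classify_functional(list(allele1 = a1, allele2 = a2))
    v <- cnv$cyp2a6_cnv[match(al$patient[i], cnv$patient)]
    exp_cn <- expected_exon_cn(a1, a2)
    state <- if (length(v) && !is.na(v)) pmin(pmax(round_half_up(v), 0), 4)
             else NA_real_
    data.frame(patient = al$patient[i],
               allele1 = al$allele1[i], allele2 = al$allele2[i],
               predicted_class = cls, reported_class = al$genome_class[i],
               concordant = identical(cls, al$genome_class[i]),
               cnv = if (length(v)) v else NA_real_, cnv_state = state,
               cnv_low_conf = !is.na(state) && abs(v - state) > guard,
               cnv_discrepant = !is.na(state) &&
                 (state < min(exp_cn) || state > max(exp_cn)),
               stringsAsFactors = FALSE)
  })
  per_patient <- do.call(rbind, rows)
  structure(list(per_patient = per_patient,
                 n = nrow(per_patient),
                 n_concordant = sum(per_patient$concordant),
                 allele_counts = table(c(al$allele1, al$allele2))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d/%d genome classes reproduced\n",
              x$n_concordant, x$n))
  if (x$n > 0) {
    disc <- x$per_patient[x$per_patient$cnv_discrepant |
                            !x$per_patient$concordant, , drop = FALSE]
    if (nrow(disc)) {
      cat("flagged rows (CNV discrepancy or class mismatch):\n")
      print(disc[, c("patient", "allele1", "allele2", "cnv",
                     "predicted_class", "reported_class")],
            row.names = FALSE)
    }
  }
  invisible(x)
}
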