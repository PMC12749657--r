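#' The canonical 96 single-base-substitution channels
#'
#' Pyrimidine-centered trinucleotide substitution classes in COSMIC order:
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each in 16
#' flanking contexts, labelled like `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  ctx <- expand.grid(three = DNA, five = DNA, sub = subs,
                     stringsAsFactors = FALSE)
  ctx <- ctx[order(match(ctx$sub, subs), match(ctx$five, DNA),
                   match(ctx$three, DNA)), ]
  sprintf("%s[%s]%s", ctx$five, ctx$sub, ctx$three)
}

#' Synthetic SBS signature matrix
#'
#' Three deterministic 96-channel probability vectors used by the
#' simulator and tests: `flat` (uniform), `sbs4_like` (mass concentrated
#' on C>A channels, emulating the shape class of the tobacco-smoking
#' signature) and `sbs92_like` (mass concentrated on T>C channels). These
#' are synthetic stand-ins, not COSMIC signatures; supply a COSMIC v3.3
#' TSV via [read_signature_matrix()] for real catalogs.
#'
#' @return 96 x 3 matrix, columns summing to 1, rownames the channels.
#' @export
synthetic_signature_matrix <- function() {
  ch <- sbs_channels()
  sub_of <- sub(".\\[(.+)\\].", "\\1", ch)
  peaked <- function(major_sub, major_mass = 0.85) {
    p <- rep((1 - major_mass) / 96, 96)
    idx <- which(sub_of == major_sub)
    # triangular profile over the 16 major channels: distinct, not uniform
    wt <- seq_along(idx)
    p[idx] <- p[idx] + major_mass * wt / sum(wt)
    p / sum(p)
  }
  m <- cbind(flat = rep(1 / 96, 96),
             sbs4_like = peaked("C>A"),
             sbs92_like = peaked("T>C"))
  rownames(m) <- ch
  m
}

#' Read a signature matrix from TSV
#'
#' Expects a channel column (named `Type` or the first column) with the 96
#' canonical labels and one column per signature; rows are reordered to
#' canonical channel order and columns renormalized to sum to 1.
#'
#' @param path TSV file (e.g. a COSMIC v3.3 SBS matrix export).
#' @return numeric matrix 96 x k.
#' @export
read_signature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  chcol <- if ("Type" %in% names(df)) "Type" else names(df)[1]
  ch <- df[[chcol]]
  stop_if(!setequal(ch, sbs_channels()),
          "signature file does not contain the canonical 96 channels")
  m <- as.matrix(df[, setdiff(names(df), chcol), drop = FALSE])
  rownames(m) <- ch
  m <- m[sbs_channels(), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Channel counts are multinomial with probabilities equal to the
#' signature matrix times the mixture weights.
#'
#' @param n_mutations total mutations to draw.
#' @param mixture named numeric vector of non-negative weights summing
#'   to 1; names must be columns of `signatures`.
#' @param signatures 96 x k probability matrix (default
#'   [synthetic_signature_matrix()]).
#' @param seed integer seed.
#' @param sample_id identifier carried into the catalog.
#' @param footprint_mb callable exonic footprint for TMB (Mb).
#' @return object of class `mutation_catalog`: named `counts` (96),
#'   `sample_id`, `footprint_mb`, and the generating mixture.
#' @export
simulate_mutation_catalog <- function(n_mutations, mixture,
                                      signatures = synthetic_signature_matrix(),
                                      seed = 1L, sample_id = "sample",
                                      footprint_mb = 40) {
  stop_if(any(mixture < 0), "mixture weights must be >= 0")
  stop_if(abs(sum(mixture) - 1) > 1e-8, "mixture weights must sum to 1")
  missing <- setdiff(names(mixture), colnames(signatures))
  stop_if(length(missing) > 0, "mixture names absent from matrix: ",
          paste(missing, collapse = ", "))
  p <- as.numeric(signatures[, names(mixture), drop = FALSE] %*% mixture)
  counts <- if (n_mutations == 0) stats::setNames(rep(0L, 96), sbs_channels())
            else local_seed(seed, {
              stats::setNames(as.integer(rmultinom(1, n_mutations, p)),
                              sbs_channels())
            })
  structure(list(sample_id = sample_id, counts = counts,
                 footprint_mb = footprint_mb, mixture = mixture),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog %s: %d mutations, footprint %.0f Mb (TMB %.2f)\n",
              x$sample_id, sum(x$counts), x$footprint_mb,
              sum(x$counts) / x$footprint_mb))
  invisible(x)
}

#' Write / read a 96-channel catalog TSV
#'
#' Two columns: `channel` (e.g. `"A[C>T]G"`) and `count`.
#'
#' @param catalog a `mutation_catalog`.
#' @param path file path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write.table(data.frame(channel = names(catalog$counts),
                         count = as.integer(catalog$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @param sample_id,footprint_mb metadata for the reloaded catalog.
#' @export
read_catalog_tsv <- function(path, sample_id = basename(path),
                             footprint_mb = 40) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if(!setequal(df$channel, sbs_channels()), "not a 96-channel catalog")
  counts <- stats::setNames(df$count, df$channel)[sbs_channels()]
  structure(list(sample_id = sample_id, counts = counts,
                 footprint_mb = footprint_mb, mixture = NULL),
            class = "mutation_catalog")
}

#' Build a 96-channel catalog from a VCF of somatic SNVs
#'
#' Trinucleotide context is taken from the supplied reference; purine-
#' centered substitutions are reverse-complemented onto the pyrimidine
#' strand. Non-SNV records are ignored. Requires the `vcfR` package.
#'
#' @param vcf_path VCF file (plain text or bgzipped).
#' @param ref named character vector or `DNAStringSet` of reference
#'   contigs.
#' @param sample_id,footprint_mb catalog metadata.
#' @return a `mutation_catalog`.
#' @export
catalog_from_vcf <- function(vcf_path, ref, sample_id = basename(vcf_path),
                             footprint_mb = 40) {
  stop_if(!requireNamespace("vcfR", quietly = TRUE),
          "catalog_from_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- fix[nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
               fix$REF %in% DNA & fix$ALT %in% DNA, , drop = FALSE]
  if (inherits(ref, "DNAStringSet")) ref <- as.character(ref)
  counts <- stats::setNames(rep(0L, 96), sbs_channels())
  for (i in seq_len(nrow(snv))) {
    chrom <- snv$CHROM[i]; pos <- as.integer(snv$POS[i])
    ctx <- substr(ref[[chrom]], pos - 1L, pos + 1L)
    if (nchar(ctx) != 3L) next
    refb <- snv$REF[i]; altb <- snv$ALT[i]
    if (refb %in% c("A", "G")) {
      ctx <- revcomp_chr(ctx)
      refb <- chartr("AG", "TC", refb)
      altb <- chartr("ACGT", "TGCA", altb)
    }
    lab <- sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), refb, altb,
                   substr(ctx, 3, 3))
    if (lab %in% names(counts)) counts[lab] <- counts[lab] + 1L
  }
  structure(list(sample_id = sample_id, counts = counts,
                 footprint_mb = footprint_mb, mixture = NULL),
            class = "mutation_catalog")
}

#' Tumor mutation burden
#'
#' Somatic mutation count divided by the callable exonic footprint.
#' Accepts a `mutation_catalog`, a bare count, or a variant data.frame
#' (restricted to rows with `exonic == TRUE` when that column exists).
#'
#' @param x catalog, count, or variant table.
#' @param footprint_mb callable footprint in Mb (> 0); TMB is
#'   footprint-dependent, so the footprint is always carried in the
#'   result.
#' @param sample_id,functional_class metadata carried through.
#' @return data.frame (one row): `sample_id`, `n_mutations`,
#'   `footprint_mb`, `tmb`, `functional_class`.
#' @export
compute_tmb <- function(x, footprint_mb = NULL, sample_id = NULL,
                        functional_class = NA_character_) {
  if (inherits(x, "mutation_catalog")) {
    n <- sum(x$counts)
    footprint_mb <- footprint_mb %||% x$footprint_mb
    sample_id <- sample_id %||% x$sample_id
  } else if (is.data.frame(x)) {
    n <- if ("exonic" %in% names(x)) sum(x$exonic) else nrow(x)
  } else {
    n <- as.numeric(x)
  }
  stop_if(is.null(footprint_mb) || footprint_mb <= 0,
          "footprint_mb must be > 0")
  data.frame(sample_id = sample_id %||% NA_character_, n_mutations = n,
             footprint_mb = footprint_mb, tmb = n / footprint_mb,
             functional_class = functional_class,
             stringsAsFactors = FALSE)
}

#' Welch's t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and two-sided p value. When both groups have zero
#' variance the statistic is degenerate: t = 0 and p = 1 for equal means,
#' t = +/-Inf and p = 0 otherwise, with df = NA.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite values.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stop_if(length(a) < 2L || length(b) < 2L, "each group needs n >= 2")
  stop_if(!all(is.finite(a)) || !all(is.finite(b)),
          "non-finite values in input")
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, p = if (d == 0) 1 else 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Refit signature exposures by non-negative least squares
#'
#' The normalized 96-channel catalog is decomposed on the signature
#' columns by NNLS; exposures are reported as fractions summing to 1,
#' with the residual norm of the fit. Signatures on the exclusion list
#' (e.g. sequencing artifacts) are removed before fitting.
#'
#' @param catalog a `mutation_catalog` with at least one mutation.
#' @param signatures 96 x k probability matrix (columns sum to 1).
#' @param exclude character vector of signature names dropped before
#'   fitting.
#' @return object of class `signature_exposure`: `fractions` (named, sum
#'   1), `raw` (unnormalized NNLS solution), `residual` (L2 norm on the
#'   frequency scale), `n_mutations`.
#' @export
fit_signatures <- function(catalog, signatures = synthetic_signature_matrix(),
                           exclude = character()) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  n <- sum(catalog$counts)
  stop_if(n == 0, "empty catalog: exposures undefined")
  S <- signatures[, setdiff(colnames(signatures), exclude), drop = FALSE]
  stop_if(any(abs(colSums(S) - 1) > 1e-6),
          "signature columns must sum to 1")
  v <- as.numeric(catalog$counts[rownames(S)]) / n
  fit <- pracma::lsqnonneg(S, v)
  x <- stats::setNames(fit$x, colnames(S))
  stop_if(sum(x) == 0, "degenerate NNLS fit: all exposures zero")
  structure(list(fractions = x / sum(x), raw = x,
                 residual = sqrt(sum((as.numeric(S %*% x) - v)^2)),
                 n_mutations = n, sample_id = catalog$sample_id),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat(sprintf("signature_exposure %s (n = %d, residual %.4f):\n",
              x$sample_id, x$n_mutations, x$residual))
  print(round(x$fractions[x$fractions > 0], 3))
  invisible(x)
}

#' Merge minor signature exposures into an "others" bucket
#'
#' Unprotected signatures with a contribution fraction below the
#' threshold are pooled into `others`; protected (smoking-related)
#' signatures are always reported, at any fraction. Total exposure mass
#' is conserved exactly.
#'
#' @param exposure a [fit_signatures()] result.
#' @param threshold merge threshold on the contribution fraction.
#' @param protected signature names never merged.
#' @return a `signature_exposure` with a possibly reduced set of named
#'   fractions plus `others`.
#' @export
merge_minor <- function(exposure, threshold = 0.2,
                        protected = c("SBS4", "SBS92")) {
  stopifnot(inherits(exposure, "signature_exposure"))
  f <- exposure$fractions
  minor <- f < threshold & !names(f) %in% protected
  kept <- f[!minor]
  out <- exposure
  out$fractions <- c(kept, others = sum(f[minor]))
  out
}

#' Summarize TMB and signature exposures by functional class
#'
#' Builds the association report comparing deletion-type and
#' retained-type samples: per-class TMB distributions with Welch's t-test
#' per stratum (e.g. lung-only and all samples), and per-class presence
#' fractions of the protected signatures (presence = fitted exposure
#' above `presence_threshold`).
#'
#' @param tmb data.frame from [compute_tmb()] rows, with columns
#'   `sample_id`, `tmb`, `functional_class`, and optionally `stratum`.
#' @param exposures named list of [fit_signatures()] results keyed by
#'   sample id.
#' @param presence_threshold exposure fraction above which a signature
#'   counts as detected (reported in the output metadata).
#' @param signatures_of_interest signatures whose presence is tabulated.
#' @return object of class `association_report`: `tmb_summary`, `tests`
#'   (one row per stratum; skipped strata carry a notice), `presence`.
#' @export
summarize_by_class <- function(tmb, exposures,
                               presence_threshold = 0.05,
                               signatures_of_interest = c("SBS4", "SBS92")) {
  stop_if(any(is.na(tmb$functional_class)), "every sample must be classified")
  if (!"stratum" %in% names(tmb)) tmb$stratum <- "all"
  classes <- sort(unique(tmb$functional_class))
  tmb_summary <- do.call(rbind, lapply(classes, function(cl) {
    v <- tmb$tmb[tmb$functional_class == cl]
    data.frame(functional_class = cl, n = length(v), mean_tmb = mean(v),
               median_tmb = median(v), sd_tmb = if (length(v) > 1) sd(v)
               else NA_real_)
  }))
  tests <- do.call(rbind, lapply(unique(tmb$stratum), function(st) {
    sub <- tmb[tmb$stratum == st, ]
    a <- sub$tmb[sub$functional_class == "deletion"]
    b <- sub$tmb[sub$functional_class == "retained"]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(stratum = st, n_deletion = length(a),
                        n_retained = length(b), t = NA_real_, df = NA_real_,
                        p = NA_real_,
                        note = "skipped: fewer than 2 samples in a group"))
    wt <- welch_t(a, b)
    data.frame(stratum = st, n_deletion = length(a), n_retained = length(b),
               t = wt$t, df = wt$df, p = wt$p, note = "")
  }))
  pres_one <- function(cl, sig) {
    ids <- tmb$sample_id[tmb$functional_class == cl]
    ex <- exposures[ids]
    det <- vapply(ex, function(e) {
      f <- e$fractions[sig]
      isTRUE(!is.na(f) && f > presence_threshold)
    }, TRUE)
    mean(det)
  }
  presence <- expand.grid(functional_class = classes,
                          signature = signatures_of_interest,
                          stringsAsFactors = FALSE)
  presence$fraction_detected <- mapply(pres_one, presence$functional_class,
                                       presence$signature)
  structure(list(tmb_summary = tmb_summary, tests = tests,
                 presence = presence,
                 presence_threshold = presence_threshold),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("association_report\n")
  print(x$tmb_summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  cat(sprintf("signature presence (exposure > %.2f):\n",
              x$presence_threshold))
  print(x$presence, row.names = FALSE)
  invisible(x)
}
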