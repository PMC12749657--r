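#' Primer set for the junction screen
#'
#' Several forward primers sharing one common reverse primer, mirroring a
#' screening assay in which presence of a junction-spanning product, not
#' its exact size, is the readout.
#'
#' @param forwards data.frame with columns `label`, `sequence`.
#' @param reverse the shared reverse primer sequence.
#' @param max_amplicon maximum product size considered amplifiable (bp);
#'   the default covers the 2.5-6 kb product range of a long-range
#'   polymerase with headroom.
#' @return object of class `primer_set`.
#' @export
primer_set <- function(forwards, reverse, max_amplicon = 7000L) {
  check_primer <- function(p) {
    stop_if(nchar(p) < 15L || nchar(p) > 35L,
            "primer length must be 15-35 nt: ", p)
    stop_if(grepl("[^ACGT]", p), "primer has non-ACGT characters: ", p)
  }
  for (p in forwards$sequence) check_primer(p)
  check_primer(reverse)
  structure(list(forwards = forwards, reverse = reverse,
                 max_amplicon = as.integer(max_amplicon)),
            class = "primer_set")
}

#' Load a primer set from a TSV file
#'
#' Columns: `label`, `sequence`, `role` (`forward`/`reverse`). The primer
#' sequences used for the CYP2A7::CYP2A6 junction screen ship with the
#' package (`system.file("extdata", "primers.tsv", package = "psvtyper")`).
#'
#' @param path TSV file; defaults to the shipped screen primers.
#' @param max_amplicon passed to [primer_set()].
#' @return a [primer_set()].
#' @export
read_primer_set <- function(path = system.file("extdata", "primers.tsv",
                                               package = "psvtyper"),
                            max_amplicon = 7000L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  primer_set(df[df$role == "forward", c("label", "sequence")],
             df$sequence[df$role == "reverse"][1], max_amplicon)
}

#' Find primer binding sites on a template
#'
#' Scans both strands for placements with at most `max_mismatch`
#' substitutions. A site on the minus strand is reported at the plus-strand
#' interval of its reverse complement.
#'
#' @param template template sequence (character).
#' @param primer primer sequence.
#' @param max_mismatch allowed substitutions (default 0: the screen treats
#'   binding as exact).
#' @return data.frame: `start`, `end` (0-based half-open, plus strand),
#'   `strand` (`"+"` if the primer sequence matches the plus strand).
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0L) {
  template <- Biostrings::DNAString(as.character(template))
  scan <- function(p, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), template,
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L)
      return(data.frame(start = integer(), end = integer(),
                        strand = character()))
    data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  rbind(scan(primer, "+"), scan(revcomp_chr(primer), "-"))
}

#' Predict amplicons of a primer set on an allele sequence
#'
#' For every forward primer, reports whether a convergent forward/reverse
#' placement within `max_amplicon` exists and the product length(s).
#' A deletion that removes a forward primer's binding site (or pushes the
#' primers beyond `max_amplicon`) yields `present = FALSE`, mirroring the
#' loss of product used as deletion evidence in amplicon screens.
#'
#' @param template allele sequence (character).
#' @param primers a [primer_set()].
#' @param max_mismatch allowed substitutions per primer site.
#' @return data.frame: `label`, `length` (NA when absent), `present`.
#'   Multiple convergent placements give multiple rows for a label.
#' @export
predict_amplicons <- function(template, primers, max_mismatch = 0L) {
  stopifnot(inherits(primers, "primer_set"))
  rev_sites <- find_binding_sites(template, primers$reverse, max_mismatch)
  out <- list()
  for (i in seq_len(nrow(primers$forwards))) {
    lab <- primers$forwards$label[i]
    fwd_sites <- find_binding_sites(template, primers$forwards$sequence[i],
                                    max_mismatch)
    lens <- integer()
    # convergent pairs in either template orientation:
    # forward on + with reverse-site on - downstream, and the mirrored
    # arrangement (forward on -, reverse-site on + upstream)
    f_plus <- fwd_sites[fwd_sites$strand == "+", , drop = FALSE]
    r_minus <- rev_sites[rev_sites$strand == "-", , drop = FALSE]
    for (a in seq_len(nrow(f_plus))) for (b in seq_len(nrow(r_minus))) {
      len <- r_minus$end[b] - f_plus$start[a]
      if (len >= nchar(primers$reverse) + nchar(primers$forwards$sequence[i]) &&
          len <= primers$max_amplicon)
        lens <- c(lens, len)
    }
    f_minus <- fwd_sites[fwd_sites$strand == "-", , drop = FALSE]
    r_plus <- rev_sites[rev_sites$strand == "+", , drop = FALSE]
    for (a in seq_len(nrow(f_minus))) for (b in seq_len(nrow(r_plus))) {
      len <- f_minus$end[a] - r_plus$start[b]
      if (len >= nchar(primers$reverse) + nchar(primers$forwards$sequence[i]) &&
          len <= primers$max_amplicon)
        lens <- c(lens, len)
    }
    out[[i]] <- if (length(lens) == 0L)
      data.frame(label = lab, length = NA_integer_, present = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(label = lab, length = sort(lens), present = TRUE,
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
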