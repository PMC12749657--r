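#' Allele structure
#'
#' One haplotype's architecture at the two-paralog locus: which paralog each
#' gene segment derives from, the switch-position (SP) interval for hybrid
#' alleles, and the copy-number status of the downstream gene (the CYP2A6
#' analog, "gene B"). Used both for simulation truth and for inferred
#' allele candidates.
#'
#' @param kind one of `"wild_type"`, `"whole_deletion"`, `"duplication"`,
#'   `"hybrid"`.
#' @param switch_segment for hybrids, the segment label containing the SP
#'   (`"intron<k>"` or `"utr3"`).
#' @param junction for simulated truth, the base-level junction offset in
#'   the shared gene frame (unobservable in inference, where only
#'   `sp_interval` is known).
#' @param sp_interval length-2 vector `(lo, hi)` of gene-frame offsets of
#'   the flanking PSVs: the junction lies in the PSV-free stretch between
#'   them.
#' @param cn_status `"present"`, `"deleted"` or `"duplicated"`.
#' @param copy_count copies of gene B carried by this allele.
#' @param support number of reads supporting an inferred structure.
#' @return an object of class `allele_structure`.
#' @export
allele_structure <- function(kind, switch_segment = NA_character_,
                             junction = NA_integer_, sp_interval = c(NA, NA),
                             cn_status = "present", copy_count = 1L,
                             support = NA_integer_) {
  stop_if(!kind %in% c("wild_type", "whole_deletion", "duplication", "hybrid"),
          "unknown allele kind: ", kind)
  stop_if(kind == "hybrid" && is.na(switch_segment),
          "hybrid allele requires a switch_segment")
  stop_if(kind == "duplication" && copy_count < 2L,
          "duplication requires copy_count >= 2")
  x <- structure(list(kind = kind, switch_segment = switch_segment,
                      junction = junction,
                      sp_interval = as.numeric(sp_interval),
                      cn_status = cn_status,
                      copy_count = as.integer(copy_count),
                      support = support, name = NA_character_),
                 class = "allele_structure")
  x$name <- name_allele(x)
  x
}

#' @export
print.allele_structure <- function(x, ...) {
  cat(sprintf("allele_structure: %s%s\n  name: %s\n", x$kind,
              if (!is.na(x$switch_segment))
                paste0(" (SP in ", x$switch_segment, ")") else "",
              x$name))
  invisible(x)
}

#' @export
format.allele_structure <- function(x, ...) x$name

# Two structures describe the same allele class (used for grouping and for
# hypothesis bookkeeping; SP intervals may differ between reads).
same_allele_class <- function(a, b) {
  identical(a$kind, b$kind) &&
    identical(a$switch_segment, b$switch_segment) &&
    identical(a$copy_count, b$copy_count)
}
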