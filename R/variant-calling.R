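# Somatic variant filter chain on tumor/normal allele-count pileups, and
# phasing of nearby variant pairs from read-haplotype evidence.

#' The 13-site homopolymer/reference-error blacklist
#'
#' Recurrent false-positive calls caused by misalignment around the rCRS
#' homopolymer tracts at 302-315 and 513-525 and the reference N at 3107.
#'
#' @return \code{data.frame(pos, ref, alt)} of blacklisted substitutions.
#' @export
defaultBlacklist <- function() {
  sites <- c("A302C", "C309T", "C311T", "C312T", "C313T", "G316C",
            "C514A", "A515G", "A523C", "C524G",
            "C3106A", "T3109C", "C3110A")
  m <- regmatches(sites, regexec("^([ACGT])([0-9]+)([ACGT])$", sites))
  data.frame(pos = as.integer(vapply(m, `[`, character(1), 3L)),
             ref = vapply(m, `[`, character(1), 2L),
             alt = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Default somatic-calling thresholds
#'
#' @return Named list of the filter-chain parameters: minimum VAF 0.03,
#'   minimum 4 variant reads (3 with VAF >= 0.20 via the low-read rescue),
#'   one-sided strand fraction limit 0.90 with the perfect-match bias
#'   rescue at difference < 0.1, normal VAF < 0.01 for somatic status, and
#'   a 0.10 fallback contamination floor.
#' @export
callingDefaults <- function() {
  list(min_vaf = 0.03, min_reads = 4L, rescue_reads = 3L,
       rescue_vaf = 0.20, strand_max = 0.90, strand_bias_diff = 0.1,
       normal_max_vaf = 0.01, fallback_floor = 0.10)
}

pileupAlleleCounts <- function(row) {
  sapply(BASES, function(a)
    row[[paste0(a, "_plus")]] + row[[paste0(a, "_minus")]])
}

#' Call somatic variants from tumor/normal pileups
#'
#' Applies the full filter chain at every tumor pileup site and non-reference
#' allele: at least 4 Q20 variant reads (or 3 when VAF >= 20\%, tagged
#' \code{low_read_rescue}), VAF >= 3\%, a strand filter requiring <= 90\%
#' of variant reads on one sequencing strand (or rescue when the
#' perfect-match and mismatch strand biases differ by < 0.1, tagged
#' \code{strand_bias_rescue}), exclusion of the 13-site blacklist, a
#' per-sample VAF floor against cross-contamination (5x the 95\% upper
#' contamination bound, or the 0.10 fallback), and absence of the allele in
#' the matched normal (VAF < 1\%).
#'
#' @param tumor,normal Pileup \code{data.frame}s as produced by
#'   \code{\link{simulatePileups}} (columns \code{sample}, \code{pos},
#'   \code{ref}, \code{<base>_plus}, \code{<base>_minus}).
#' @param vafFloor Per-sample contamination VAF floor; \code{NA} uses the
#'   fallback. May be a named vector keyed by sample.
#' @param blacklist \code{data.frame(pos, alt)}; \code{NULL} disables.
#' @param params Threshold list (see \code{\link{callingDefaults}}).
#' @param keepFiltered Also return failing candidate alleles (>= 2 variant
#'   reads) with their failed filters.
#' @return \code{data.frame} of calls: \code{sample}, \code{pos},
#'   \code{ref}, \code{alt}, \code{vaf}, \code{variant_reads},
#'   \code{depth}, \code{rescue_tags}, \code{filters_failed} (empty string
#'   for emitted calls).
#' @export
callSomatic <- function(tumor, normal, vafFloor = NA_real_,
                        blacklist = defaultBlacklist(),
                        params = callingDefaults(),
                        keepFiltered = FALSE) {
  if (is.null(normal)) stop_data("matched normal pileup is required")
  p <- params
  normKey <- paste(normal$sample, normal$pos)
  out <- list()
  plusCols <- paste0(BASES, "_plus"); minusCols <- paste0(BASES, "_minus")
  tp <- as.matrix(tumor[, plusCols]); tm <- as.matrix(tumor[, minusCols])
  np <- as.matrix(normal[, plusCols]); nm <- as.matrix(normal[, minusCols])
  colnames(tp) <- colnames(tm) <- colnames(np) <- colnames(nm) <- BASES
  tot <- tp + tm
  ntot <- np + nm
  blKey <- if (is.null(blacklist)) character(0) else
    paste(blacklist$pos, blacklist$alt)
  floors <- vafFloor
  for (i in seq_len(nrow(tumor))) {
    refb <- tumor$ref[i]
    depth <- sum(tot[i, ])
    if (depth == 0) next
    ni <- match(paste(tumor$sample[i], tumor$pos[i]), normKey)
    sampleFloor <- if (length(floors) > 1)
      floors[[tumor$sample[i]]] %||% NA_real_ else floors
    if (is.na(sampleFloor)) sampleFloor <- p$fallback_floor
    for (a in setdiff(BASES, refb)) {
      vreads <- tot[i, a]
      if (vreads < 2L) next  # not a candidate
      vaf <- vreads / (vreads + tot[i, refb])
      failed <- character(0)
      tags <- character(0)
      # read support with low-read rescue
      if (vreads < p$min_reads) {
        if (vreads >= p$rescue_reads && vaf >= p$rescue_vaf)
          tags <- c(tags, "low_read_rescue")
        else failed <- c(failed, "min_reads")
      }
      if (vaf < p$min_vaf) failed <- c(failed, "min_vaf")
      # strand filter with perfect-match bias rescue
      fplus <- tp[i, a] / vreads
      if (vreads > 0 && (fplus > p$strand_max || fplus < 1 - p$strand_max)) {
        pmReads <- tot[i, refb]
        pmBias <- if (pmReads > 0) tp[i, refb] / pmReads else NA_real_
        if (!is.na(pmBias) && abs(pmBias - fplus) < p$strand_bias_diff)
          tags <- c(tags, "strand_bias_rescue")
        else failed <- c(failed, "strand_bias")
      }
      if (paste(tumor$pos[i], a) %in% blKey)
        failed <- c(failed, "blacklist")
      if (vaf <= sampleFloor) failed <- c(failed, "contamination_floor")
      # matched-normal evidence
      if (is.na(ni)) {
        failed <- c(failed, "no_matched_normal")
      } else {
        ndep <- ntot[ni, a] + ntot[ni, refb]
        nvaf <- if (ndep > 0) ntot[ni, a] / ndep else 0
        if (nvaf >= p$normal_max_vaf) failed <- c(failed, "germline")
      }
      if (length(failed) == 0 || keepFiltered) {
        out[[length(out) + 1L]] <- data.frame(
          sample = tumor$sample[i], pos = tumor$pos[i], ref = refb,
          alt = a, vaf = vaf, variant_reads = vreads, depth = depth,
          rescue_tags = paste(tags, collapse = ","),
          filters_failed = paste(failed, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(), pos = integer(),
                      ref = character(), alt = character(), vaf = numeric(),
                      variant_reads = integer(), depth = integer(),
                      rescue_tags = character(), filters_failed = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Classify a phased pair of nearby variants
#'
#' From counts of the four read haplotypes spanning two variant positions:
#' co-clonal when only wt1-wt2 and subs1-subs2 are seen; on different
#' mtDNA copies when subs1-wt2 and wt1-subs2 occur without subs1-subs2;
#' sub-clonal when subs1-subs2 occurs together with exactly one of the
#' single-mutant haplotypes (the variant whose single-mutant haplotype is
#' absent is the later, sub-clonal one); otherwise unresolved.
#'
#' @param counts Named vector with \code{wt1_wt2}, \code{wt1_subs2},
#'   \code{subs1_wt2}, \code{subs1_subs2}.
#' @param minReads A haplotype counts as observed when supported by at
#'   least this many reads (default 2).
#' @return List with \code{classification} (one of \code{different_strand},
#'   \code{co_clonal}, \code{sub_clonal}, \code{unresolved}),
#'   \code{subclonal_variant} (1, 2 or \code{NA}), and \code{counts}.
#' @export
phasePair <- function(counts, minReads = 2L) {
  need <- c("wt1_wt2", "wt1_subs2", "subs1_wt2", "subs1_subs2")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop_data("missing haplotype counts: ",
                              paste(miss, collapse = ", "))
  obs <- counts[need] >= minReads
  both <- obs[["subs1_subs2"]]
  only1 <- obs[["subs1_wt2"]]
  only2 <- obs[["wt1_subs2"]]
  cls <- "unresolved"; sub <- NA_integer_
  if (!both && only1 && only2) {
    cls <- "different_strand"
  } else if (both && !only1 && !only2) {
    cls <- "co_clonal"
  } else if (both && xor(only1, only2)) {
    cls <- "sub_clonal"
    sub <- if (only1) 2L else 1L  # missing single-mutant haplotype is later
  }
  list(classification = cls, subclonal_variant = sub,
       counts = counts[need])
}
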