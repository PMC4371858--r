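# Sample-swap detection, minor cross-contamination estimation and
# polymorphism/back-mutation sample filters, as applied to tumor/normal
# pairs before somatic calling.

#' Genotype mismatch rate between a tumor and its matched normal
#'
#' Over sites where the normal is homozygous for a common SNP, the tumor
#' genotype should agree. The mismatch rate is
#' (N_het + N_wt) / (N_hom + N_het + N_wt): 0 for a perfectly matched
#' pair, about 0.5 when the two samples come from different individuals.
#' Pairs with rate > 0.1 are flagged as sample swaps.
#'
#' @param nHom,nHet,nWt Counts of homozygous-matching, heterozygous and
#'   wild-type tumor genotypes at normal-homozygous sites.
#' @param threshold Swap threshold on the mismatch rate.
#' @return List with \code{rate} and \code{swap_flag}.
#' @export
genotypeMismatchRate <- function(nHom, nHet, nWt, threshold = 0.1) {
  total <- nHom + nHet + nWt
  if (total < 1) stop_data("no informative genotype sites")
  rate <- (nHet + nWt) / total
  list(rate = rate, swap_flag = rate > threshold)
}

#' Estimate minor cross-contamination from homozygous-SNP sites
#'
#' At sites where the normal is homozygous for a common SNP, wild-type
#' (reference) reads in the tumor arise from sequencing error or from a
#' contaminating sample, which contributes wild-type alleles at about half
#' of its reads. The contaminant fraction is estimated as
#' \deqn{C = 2 (\sum RC_{wt} - Ne) / (\sum RD_{hom} - Ne)}
#' with \eqn{Ne} the expected number of error reads
#' (\code{errorRate} times total depth), clamped to [0, 1]. The 95\% CI is
#' Clopper-Pearson on the summed wild-type count, propagated through the
#' same formula. The somatic VAF floor implied by the estimate is 5 times
#' the upper CI bound.
#'
#' @param sites \code{data.frame} with columns \code{RD_hom} (Q20 depth)
#'   and \code{RC_wt} (wild-type read count) per site. Sites should be
#'   pre-filtered to depth >= 10 and normal VAF >= 0.90; rows violating
#'   \code{RC_wt <= RD_hom} are an error.
#' @param errorRate Assumed sequencing error rate (default 0.001).
#' @param floorFactor Multiplier on the CI upper bound for the VAF floor.
#' @return List with \code{C}, \code{ci95} (length-2), \code{Ne},
#'   \code{vaf_floor}.
#' @export
estimateContamination <- function(sites, errorRate = 0.001,
                                  floorFactor = 5) {
  if (nrow(sites) == 0 || sum(sites$RD_hom) == 0)
    stop_data("no covered homozygous sites: cannot estimate contamination")
  if (any(sites$RC_wt > sites$RD_hom) || any(sites$RC_wt < 0))
    stop_data("RC_wt must lie in [0, RD_hom]")
  RD <- sum(sites$RD_hom)
  RC <- sum(sites$RC_wt)
  Ne <- errorRate * RD
  if (RD <= Ne) stop_data("total depth does not exceed expected errors")
  toC <- function(rc) min(max(2 * (rc - Ne) / (RD - Ne), 0), 1)
  C <- toC(RC)
  ci_p <- binom.test(RC, RD)$conf.int  # Clopper-Pearson on the wt fraction
  ci <- c(toC(ci_p[1] * RD), toC(ci_p[2] * RD))
  list(C = C, ci95 = ci, Ne = Ne, vaf_floor = floorFactor * ci[2])
}

#' Polymorphism and back-mutation sample filter
#'
#' A contaminated tumor shows apparent somatic calls that coincide with
#' known germline polymorphisms, and "back mutations" reverting the
#' patient's own germline polymorphisms to the reference allele. Samples
#' with >= 3 known-polymorphism somatic calls or >= 2 back mutations are
#' flagged.
#'
#' @param somatic \code{data.frame(pos, alt)} of somatic calls for the
#'   sample.
#' @param germline \code{data.frame(pos, ref, alt)} of the patient's
#'   germline polymorphisms (alt = the inherited allele).
#' @param polymorphismSet \code{data.frame(pos, alt)} of known population
#'   polymorphisms.
#' @param maxKnown,maxBack Flag thresholds.
#' @return List with \code{n_known}, \code{n_back}, \code{flag}.
#' @export
polymorphismQC <- function(somatic, germline, polymorphismSet,
                           maxKnown = 3L, maxBack = 2L) {
  key <- function(d) paste(d$pos, d$alt)
  n_known <- if (nrow(somatic) == 0) 0L else
    sum(key(somatic) %in% key(polymorphismSet))
  # back mutation: somatic call at a germline-polymorphic position whose
  # alt equals the reference allele there (reversion to reference)
  n_back <- if (nrow(somatic) == 0 || nrow(germline) == 0) 0L else
    sum(paste(somatic$pos, somatic$alt) %in%
          paste(germline$pos, germline$ref))
  list(n_known = n_known, n_back = n_back,
       flag = n_known >= maxKnown || n_back >= maxBack)
}
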