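# Strand-resolved pyrimidine-centred mutation classes.
#
# Every single-base substitution is recorded internally as the L-strand
# reference/alternate pair at a genomic position. For signature work it is
# re-expressed on the strand carrying the mutated pyrimidine: when the
# L-strand base is C or T the class lives on the L strand with the L-strand
# context; when it is a purine, the complementary change on the H strand is
# the pyrimidine change, with the reverse-complemented context. This gives
# 12 classes (6 changes x 2 strands) or 192 (x 16 flanking combinations).

#' Enumerate strand-resolved mutation class names
#'
#' @param nclass 12 or 192.
#' @return Character vector of class keys, e.g. \code{"H:C>T"} (12-class)
#'   or \code{"H:A[C>T]G"} (192-class).
#' @export
signatureClasses <- function(nclass = 192L) {
  nclass <- as.integer(nclass)
  stopifnot(nclass %in% c(12L, 192L))
  strands <- c("L", "H")
  if (nclass == 12L)
    return(as.vector(outer(strands, SUB_CLASSES, paste, sep = ":")))
  keys <- character(0)
  for (s in strands)
    for (sub in SUB_CLASSES)
      for (p5 in BASES)
        for (p3 in BASES)
          keys <- c(keys, paste0(s, ":", p5, "[", sub, "]", p3))
  keys
}

#' Classify substitutions into strand-resolved classes
#'
#' @param ref An \linkS4class{MtReference}.
#' @param pos Integer vector of positions.
#' @param refAllele,altAllele L-strand reference and alternate alleles
#'   (single bases).
#' @param nclass 12 or 192.
#' @return Character vector of class keys (same representation as
#'   \code{\link{signatureClasses}}).
#' @export
classifyVariants <- function(ref, pos, refAllele, altAllele, nclass = 192L) {
  nclass <- as.integer(nclass)
  stopifnot(nclass %in% c(12L, 192L))
  n <- length(pos)
  stopifnot(length(refAllele) == n, length(altAllele) == n)
  b <- referenceBases(ref)
  if (!all(refAllele == b[pos]))
    stop_data("refAllele does not match the reference at some positions")
  pyr <- refAllele %in% PYRIMIDINES
  strand <- ifelse(pyr, "L", "H")
  fromP <- ifelse(pyr, refAllele, comp_base(refAllele))
  toP <- ifelse(pyr, altAllele, comp_base(altAllele))
  sub <- paste0(fromP, ">", toP)
  if (nclass == 12L) return(paste0(strand, ":", sub))
  ctxL <- trinucleotideContext(ref, pos, "L")
  ctx <- ifelse(pyr, ctxL, revcomp(ctxL))
  paste0(strand, ":", substr(ctx, 1, 1), "[", sub, "]", substr(ctx, 3, 3))
}

#' Context opportunities over a set of positions
#'
#' Counts, for each strand-resolved class, the reference positions whose
#' pyrimidine-strand centre (and flanking context, in the 192-class model)
#' matches the class. Each position contributes to the three classes that
#' share its centre/context.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param positions Positions to count over (default: whole genome).
#' @param nclass 12 or 192.
#' @return Named numeric vector over \code{\link{signatureClasses}}.
#' @export
contextOpportunities <- function(ref, positions = seq_len(length(ref)),
                                 nclass = 192L) {
  nclass <- as.integer(nclass)
  classes <- signatureClasses(nclass)
  opp <- setNames(numeric(length(classes)), classes)
  b <- referenceBases(ref)[positions]
  keep <- b %in% BASES
  positions <- positions[keep]; b <- b[keep]
  pyr <- b %in% PYRIMIDINES
  strand <- ifelse(pyr, "L", "H")
  centre <- ifelse(pyr, b, comp_base(b))
  if (nclass == 12L) {
    tab <- table(paste0(strand, ":", centre))
    for (nm in names(tab)) {
      s <- substr(nm, 1, 1); ctr <- substr(nm, 3, 3)
      alts <- setdiff(BASES, ctr)
      keys <- paste0(s, ":", ctr, ">", alts)
      opp[keys] <- opp[keys] + as.numeric(tab[nm])
    }
    return(opp)
  }
  ctxL <- trinucleotideContext(ref, positions, "L")
  ctx <- ifelse(pyr, ctxL, revcomp(ctxL))
  tab <- table(paste0(strand, ":", ctx))
  for (nm in names(tab)) {
    s <- substr(nm, 1, 1)
    p5 <- substr(nm, 3, 3); ctr <- substr(nm, 4, 4); p3 <- substr(nm, 5, 5)
    alts <- setdiff(BASES, ctr)
    keys <- paste0(s, ":", p5, "[", ctr, ">", alts, "]", p3)
    opp[keys] <- opp[keys] + as.numeric(tab[nm])
  }
  opp
}

#' Per-site, per-alternate class keys
#'
#' Expands a set of positions into all 3 possible single-base changes at
#' each, with the class key of each change. Used by the cohort generator
#' and by signature-weighted expectations (e.g. tRNA anticodon tests).
#'
#' @inheritParams contextOpportunities
#' @param invertedSegment Optional logical vector along \code{positions};
#'   where \code{TRUE}, the strand letter of the key is flipped. This
#'   models the reversal of replicative strand roles between Ori-b and
#'   O_H: the physical change is unchanged but the class it is drawn from
#'   belongs to the opposite strand role.
#' @return A \code{data.frame} with columns \code{pos}, \code{ref},
#'   \code{alt} (L-strand alleles) and \code{class}.
#' @export
siteClassTable <- function(ref, positions = seq_len(length(ref)),
                           nclass = 192L, invertedSegment = NULL) {
  b <- referenceBases(ref)[positions]
  keep <- b %in% BASES
  positions <- positions[keep]; b <- b[keep]
  if (!is.null(invertedSegment)) invertedSegment <- invertedSegment[keep]
  pos3 <- rep(positions, each = 3L)
  ref3 <- rep(b, each = 3L)
  alt3 <- unlist(lapply(b, function(x) setdiff(BASES, x)), use.names = FALSE)
  cls <- classifyVariants(ref, pos3, ref3, alt3, nclass = nclass)
  if (!is.null(invertedSegment)) {
    inv3 <- rep(invertedSegment, each = 3L)
    flip <- function(k) ifelse(startsWith(k, "L:"),
                               sub("^L:", "H:", k), sub("^H:", "L:", k))
    cls[inv3] <- flip(cls[inv3])
  }
  data.frame(pos = pos3, ref = ref3, alt = alt3, class = cls,
             stringsAsFactors = FALSE)
}

#' Membership in the Ori-b to O_H segment
#'
#' The segment wraps the origin: it covers positions
#' \code{[oriB..length]} and \code{[1..oH]}. Boundary positions are inside.
#'
#' @param position Positions to test.
#' @param oriB,oH Segment boundaries (defaults 16197 and 191, the typical
#'   Ori-b and O_H locations on rCRS).
#' @param genomeLength Genome length; \code{oriB} must exceed \code{oH} so
#'   the segment wraps.
#' @return Logical vector.
#' @export
inOriSegment <- function(position, oriB = 16197L, oH = 191L,
                         genomeLength = NULL) {
  if (oriB <= oH)
    stop_data("oriB must be greater than oH (segment wraps the origin)")
  position >= oriB | position <= oH
}
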