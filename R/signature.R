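# Strand-resolved mutational signature extraction, strand-bias summaries,
# replicative vs transcriptional strand-model comparison, and the
# origin-segment (Ori-b..O_H) inversion analysis.

#' Compute a strand-resolved mutational signature
#'
#' Assigns each single-base substitution to a strand-resolved class and
#' normalizes class counts by the context opportunities of the region on
#' the circular reference. Under the replicative model the class strand is
#' the physical strand (L or H) carrying the mutated pyrimidine. Under the
#' transcriptional model, variants are restricted to annotated genes and
#' the strand label records whether the mutated pyrimidine lies on the
#' coding (\code{L} slot) or template (\code{H} slot) strand of the
#' containing gene.
#'
#' @param variants \code{data.frame} with \code{pos}, \code{ref},
#'   \code{alt} (single-base, L-strand alleles).
#' @param ref An \linkS4class{MtReference}.
#' @param region Integer vector of positions defining the region
#'   (default: whole genome). Variants outside are skipped with a message.
#' @param nclass 12 or 192.
#' @param strandModel \code{"replicative"} or \code{"transcriptional"}.
#' @param annotation Annotation \code{data.frame}, required for the
#'   transcriptional model.
#' @param regionLabel Label stored on the result.
#' @return A \linkS4class{SignatureTable}.
#' @export
computeSignature <- function(variants, ref, region = NULL, nclass = 192L,
                             strandModel = c("replicative", "transcriptional"),
                             annotation = NULL, regionLabel = "genome") {
  strandModel <- match.arg(strandModel)
  nclass <- as.integer(nclass)
  if (is.null(region)) region <- seq_len(length(ref))
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  inRegion <- snv$pos %in% region
  if (any(!inRegion))
    message(sum(!inRegion), " variant(s) outside region skipped")
  snv <- snv[inRegion, , drop = FALSE]
  if (strandModel == "replicative") {
    cls <- if (nrow(snv)) classifyVariants(ref, snv$pos, snv$ref, snv$alt,
                                           nclass = nclass) else character(0)
    opp <- contextOpportunities(ref, region, nclass = nclass)
  } else {
    if (is.null(annotation))
      stop_data("transcriptional strand model requires an annotation")
    ann <- validateAnnotation(annotation)
    ann <- ann[ann$feature %in% c("protein", "tRNA", "rRNA"), , drop = FALSE]
    strandOf <- genomicCodingStrand(ann, length(ref))
    region <- intersect(region, which(!is.na(strandOf)))
    keep <- snv$pos %in% region
    if (any(!keep)) message(sum(!keep), " variant(s) outside genes skipped")
    snv <- snv[keep, , drop = FALSE]
    cls <- if (nrow(snv)) classifyVariants(ref, snv$pos, snv$ref, snv$alt,
                                           nclass = nclass) else character(0)
    cls <- relabelTranscriptional(cls, strandOf[snv$pos])
    opp <- transcriptionalOpportunities(ref, region, strandOf, nclass)
  }
  classes <- signatureClasses(nclass)
  counts <- setNames(numeric(length(classes)), classes)
  if (length(cls)) {
    tab <- table(cls)
    counts[names(tab)] <- as.numeric(tab)
  }
  rates <- ifelse(opp > 0, counts / opp, 0)
  if (any(opp == 0 & counts > 0))
    stop_data("mutation observed in a class with zero opportunity")
  new("SignatureTable", counts = counts, opportunities = opp,
      rates = setNames(rates, classes), nclass = nclass,
      strandModel = strandModel, region = regionLabel)
}

# coding strand ("L"/"H") per genomic position, NA outside genes; when
# genes overlap the first annotation row wins
genomicCodingStrand <- function(ann, genomeLength) {
  out <- rep(NA_character_, genomeLength)
  for (i in rev(seq_len(nrow(ann)))) {
    s <- ann$start[i]; e <- ann$end[i]
    pos <- if (e >= s) s:e else c(s:genomeLength, 1:e)
    out[pos] <- ann$coding_strand[i]
  }
  out
}

# physical-strand class keys -> coding/template labels reusing the L/H
# slots: "L" = pyrimidine on the coding strand, "H" = on the template
relabelTranscriptional <- function(cls, codingStrand) {
  if (!length(cls)) return(cls)
  phys <- substr(cls, 1, 1)
  lab <- ifelse(phys == codingStrand, "L", "H")
  paste0(lab, substring(cls, 2))
}

transcriptionalOpportunities <- function(ref, region, strandOf, nclass) {
  opp <- contextOpportunities(ref, region, nclass = nclass)
  # recompute with relabelled strands: count per position directly
  b <- referenceBases(ref)[region]
  keep <- b %in% BASES
  region <- region[keep]; b <- b[keep]
  pyr <- b %in% PYRIMIDINES
  phys <- ifelse(pyr, "L", "H")
  lab <- ifelse(phys == strandOf[region], "L", "H")
  centre <- ifelse(pyr, b, comp_base(b))
  classes <- signatureClasses(nclass)
  opp <- setNames(numeric(length(classes)), classes)
  if (nclass == 12L) {
    tab <- table(paste0(lab, ":", centre))
    for (nm in names(tab)) {
      s <- substr(nm, 1, 1); ctr <- substr(nm, 3, 3)
      keys <- paste0(s, ":", ctr, ">", setdiff(BASES, ctr))
      opp[keys] <- opp[keys] + as.numeric(tab[nm])
    }
  } else {
    ctxL <- trinucleotideContext(ref, region, "L")
    ctx <- ifelse(pyr, ctxL, revcomp(ctxL))
    tab <- table(paste0(lab, ":", ctx))
    for (nm in names(tab)) {
      s <- substr(nm, 1, 1)
      p5 <- substr(nm, 3, 3); ctr <- substr(nm, 4, 4); p3 <- substr(nm, 5, 5)
      keys <- paste0(s, ":", p5, "[", ctr, ">", setdiff(BASES, ctr), "]", p3)
      opp[keys] <- opp[keys] + as.numeric(tab[nm])
    }
  }
  opp
}

#' Strand-bias summary of a 12-class signature
#'
#' For each of the six base changes, reports the share of mutations whose
#' pyrimidine lies on the H strand, the compositional ratio of
#' opportunities (L over H), and the rate fold (H rate over L rate). The
#' rate fold satisfies \code{fold = hShare/(1-hShare) * compRatio}. A
#' chi-square test compares the observed 12-class counts with the counts
#' expected if all classes mutated at one common rate (expected
#' proportional to opportunities).
#'
#' @param sig A 12-class \linkS4class{SignatureTable}.
#' @return List with \code{by_class} \code{data.frame} (\code{sub},
#'   \code{n_H}, \code{n_L}, \code{h_share}, \code{comp_ratio},
#'   \code{rate_fold}) and \code{chisq} (statistic, df, p.value).
#' @export
strandBiasSummary <- function(sig) {
  stopifnot(is(sig, "SignatureTable"))
  if (sig@nclass != 12L) stop_data("strandBiasSummary expects 12 classes")
  counts <- sig@counts; opp <- sig@opportunities
  rows <- lapply(SUB_CLASSES, function(sub) {
    kH <- paste0("H:", sub); kL <- paste0("L:", sub)
    if ((opp[kH] == 0 && counts[kH] > 0) || (opp[kL] == 0 && counts[kL] > 0))
      stop_data("nonzero count with zero opportunity in class ", sub)
    nH <- counts[kH]; nL <- counts[kL]
    hShare <- if (nH + nL > 0) nH / (nH + nL) else NA_real_
    compRatio <- if (opp[kH] > 0) opp[kL] / opp[kH] else NA_real_
    fold <- if (opp[kL] > 0 && opp[kH] > 0 && counts[kL] > 0)
      (counts[kH] / opp[kH]) / (counts[kL] / opp[kL]) else NA_real_
    data.frame(sub = sub, n_H = nH, n_L = nL, h_share = hShare,
               comp_ratio = compRatio, rate_fold = fold,
               stringsAsFactors = FALSE)
  })
  by_class <- do.call(rbind, rows)
  rownames(by_class) <- NULL
  keep <- opp > 0
  expd <- sum(counts[keep]) * opp[keep] / sum(opp[keep])
  stat <- sum((counts[keep] - expd)^2 / expd)
  df <- sum(keep) - 1L
  list(by_class = by_class,
       chisq = list(statistic = stat, df = df,
                    p.value = pchisq(stat, df, lower.tail = FALSE)))
}

#' Chi-square distance between an observed signature and a background
#'
#' Expected class counts are the observed total distributed in proportion
#' to background rate times local opportunity. Used to ask which strand
#' model (replicative or transcriptional) better explains a gene subset:
#' the correct labelling yields the smaller statistic against the
#' genome-wide background.
#'
#' @param sig Observed \linkS4class{SignatureTable}.
#' @param background Background \linkS4class{SignatureTable} (same
#'   \code{nclass}).
#' @return List with \code{statistic}, \code{df}, \code{p.value}.
#' @export
signatureChisq <- function(sig, background) {
  stopifnot(sig@nclass == background@nclass)
  w <- background@rates * sig@opportunities
  keep <- sig@opportunities > 0
  if (sum(w[keep]) == 0)
    stop_data("background has zero weight over the whole region")
  # tiny floor keeps the statistic finite (and very large) when a
  # labelling puts observed mutations where the background has no mass
  w <- w[keep] + sum(w[keep]) * 1e-6
  expd <- sum(sig@counts[keep]) * w / sum(w)
  stat <- sum((sig@counts[keep] - expd)^2 / expd)
  df <- sum(keep) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Compare replicative and transcriptional strand models on a gene set
#'
#' Computes the 12-class signature of the variants twice, labelling
#' strands by physical (replicative) strand and by coding/template
#' (transcriptional) strand, and scores each against the supplied
#' background with \code{\link{signatureChisq}}. The labelling with the
#' smaller statistic is the better-fitting strand model.
#'
#' @param variants Variant \code{data.frame} (gene-region substitutions).
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation \code{data.frame}.
#' @param background Genome-wide replicative 12-class
#'   \linkS4class{SignatureTable}.
#' @param region Optional region restriction.
#' @return List with \code{replicative}, \code{transcriptional} (each the
#'   chi-square result) and \code{preferred}.
#' @export
compareStrandModels <- function(variants, ref, annotation, background,
                                region = NULL) {
  repl <- computeSignature(variants, ref, region = region, nclass = 12L,
                           strandModel = "replicative",
                           regionLabel = "gene set")
  trans <- computeSignature(variants, ref, region = region, nclass = 12L,
                            strandModel = "transcriptional",
                            annotation = annotation,
                            regionLabel = "gene set")
  r <- signatureChisq(repl, background)
  t <- signatureChisq(trans, background)
  list(replicative = r, transcriptional = t,
       preferred = if (r$statistic <= t$statistic) "replicative"
                   else "transcriptional")
}

#' Signatures inside and outside the Ori-b..O_H segment
#'
#' Splits the genome at the replication-origin segment, which wraps the
#' sequence origin (positions \code{[oriB..length]} and \code{[1..oH]}),
#' and computes separate signatures. Under the bidirectional replication
#' model, leading/lagging strand roles reverse inside this segment, so its
#' signature appears strand-swapped relative to the rest of the genome.
#'
#' @param variants Variant \code{data.frame}.
#' @param ref An \linkS4class{MtReference}.
#' @param oriB,oH Segment boundaries (must wrap: \code{oriB > oH}).
#' @param nclass 12 or 192.
#' @return List with \code{inside} and \code{outside}
#'   \linkS4class{SignatureTable}s.
#' @export
dloopSegmentSignature <- function(variants, ref, oriB = 16197L, oH = 191L,
                                  nclass = 192L) {
  L <- length(ref)
  inside <- which(inOriSegment(seq_len(L), oriB, oH))
  if (length(inside) >= L)
    stop_data("segment covers the whole genome")
  outside <- setdiff(seq_len(L), inside)
  list(
    inside = computeSignature(variants, ref, region = inside,
                              nclass = nclass, regionLabel = "ori-segment"),
    outside = computeSignature(variants, ref, region = outside,
                               nclass = nclass, regionLabel = "outside"))
}

#' Swap the strand labels of a signature's classes
#'
#' Utility for inversion analysis: returns the rate/count vectors with
#' L and H class labels exchanged.
#'
#' @param x Named vector over signature classes.
#' @return The same vector re-keyed with strands swapped.
#' @export
swapStrandLabels <- function(x) {
  nm <- names(x)
  swapped <- ifelse(startsWith(nm, "L:"), sub("^L:", "H:", nm),
                    sub("^H:", "L:", nm))
  setNames(x, swapped)[nm]
}

#' Write a signature table to TSV
#'
#' @param sig A \linkS4class{SignatureTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureTsv <- function(sig, path) {
  cls <- names(sig@counts)
  df <- data.frame(class = cls,
                   strand = substr(cls, 1, 1),
                   count = as.numeric(sig@counts),
                   opportunity = as.numeric(sig@opportunities),
                   rate = as.numeric(sig@rates),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
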