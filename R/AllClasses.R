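#' MtReference: a circular mitochondrial reference sequence
#'
#' Holds the reference sequence recorded on the light (L) strand, together
#' with its name. mtDNA is circular, so all position arithmetic in the
#' package wraps modulo the sequence length: position \code{length + 1} is
#' position 1. Heavy (H) strand alleles and contexts are obtained by
#' complementing the stored L-strand sequence.
#'
#' @slot sequence A \link[Biostrings]{DNAString} with the L-strand sequence.
#' @slot name Character identifier for the record.
#'
#' @seealso \code{\link{loadReference}}, \code{\link{trinucleotideContext}}
#' @export
setClass("MtReference",
  representation(sequence = "DNAString", name = "character"))

setValidity("MtReference", function(object) {
  s <- as.character(object@sequence)
  if (nchar(s) < 3L) return("sequence must be at least 3 bp")
  if (grepl("[^ACGTN]", s)) return("sequence may only contain A/C/G/T/N")
  TRUE
})

#' Construct an MtReference from a sequence string
#'
#' @param sequence Character scalar or \code{DNAString}; uppercased.
#' @param name Identifier for the sequence.
#' @return An \linkS4class{MtReference}.
#' @export
MtReference <- function(sequence, name = "mt") {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop_data("sequence may only contain A/C/G/T/N")
  if (nchar(sequence) < 3L) stop_data("sequence must be at least 3 bp")
  obj <- new("MtReference",
    sequence = Biostrings::DNAString(sequence),
    name = as.character(name))
  validObject(obj)
  obj
}

#' @describeIn MtReference-class Genome length in base pairs.
#' @param x An \code{MtReference}.
#' @export
setMethod("length", "MtReference", function(x) length(x@sequence))

#' Reference bases as a character vector
#'
#' @param x An \linkS4class{MtReference}.
#' @return Character vector of single bases (L strand), length \code{length(x)}.
#' @export
referenceBases <- function(x) {
  stopifnot(is(x, "MtReference"))
  strsplit(as.character(x@sequence), "")[[1]]
}

#' Reference name
#' @param x An \linkS4class{MtReference}.
#' @return Character scalar.
#' @export
referenceName <- function(x) x@name

setMethod("show", "MtReference", function(object) {
  cat("MtReference '", object@name, "': circular, ",
      length(object@sequence), " bp (L strand)\n", sep = "")
})

#' SignatureTable: strand-resolved mutation counts, opportunities and rates
#'
#' Mutations are assigned to strand-resolved pyrimidine-centred classes:
#' 12 classes (6 base changes x 2 strands) or 192 classes (the 6 changes x
#' 16 flanking-base combinations x 2 strands). Opportunities are the number
#' of reference positions in the region whose pyrimidine-strand context
#' matches each class; rates are counts divided by opportunities.
#'
#' @slot counts Named numeric vector of mutation counts per class.
#' @slot opportunities Named numeric vector of context opportunities.
#' @slot rates Named numeric vector, \code{counts/opportunities}.
#' @slot nclass Integer, 12 or 192.
#' @slot strandModel \code{"replicative"} (physical L/H strand of the
#'   mutated pyrimidine) or \code{"transcriptional"} (coding/template strand
#'   of the containing gene).
#' @slot region Character label for the region the table covers.
#'
#' @seealso \code{\link{computeSignature}}, \code{\link{strandBiasSummary}}
#' @export
setClass("SignatureTable",
  representation(counts = "numeric", opportunities = "numeric",
                 rates = "numeric", nclass = "integer",
                 strandModel = "character", region = "character"))

setValidity("SignatureTable", function(object) {
  n <- length(object@counts)
  if (!object@nclass %in% c(12L, 192L)) return("nclass must be 12 or 192")
  if (n != object@nclass) return("counts length must equal nclass")
  if (length(object@opportunities) != n || length(object@rates) != n)
    return("counts, opportunities and rates must have equal length")
  if (any(object@counts < 0) || any(object@opportunities < 0))
    return("counts and opportunities must be non-negative")
  bad <- object@opportunities == 0 & object@counts > 0
  if (any(bad)) return("class with zero opportunity has non-zero count")
  TRUE
})

setMethod("show", "SignatureTable", function(object) {
  cat("SignatureTable (", object@nclass, " classes, ",
      object@strandModel, " strand model, region: ", object@region, ")\n",
      "  total mutations: ", sum(object@counts), "\n", sep = "")
  top <- sort(object@rates, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat("  top classes by rate:\n")
    for (i in seq_len(min(5L, length(top))))
      cat(sprintf("    %-14s rate %.4g\n", names(top)[i], top[i]))
  }
})

#' Accessors for SignatureTable
#'
#' @param x A \linkS4class{SignatureTable}.
#' @return Named numeric vector over mutation classes.
#' @export
signatureCounts <- function(x) x@counts

#' @rdname signatureCounts
#' @export
signatureOpportunities <- function(x) x@opportunities

#' @rdname signatureCounts
#' @export
signatureRates <- function(x) x@rates

#' SelectionFit: context-dependent Poisson dN/dS fit
#'
#' Result of maximum-likelihood fitting of per-class mutation rates together
#' with selection coefficients for missense (and optionally nonsense)
#' mutations, under a Poisson model with per-class synonymous/missense/
#' nonsense opportunity counts.
#'
#' @slot rates Named numeric, fitted per-class mutation rates.
#' @slot wMis Missense selection coefficient (dN/dS).
#' @slot wNon Nonsense selection coefficient, \code{NA} when not fitted.
#' @slot logLik Maximised log-likelihood.
#' @slot lrtStat Likelihood-ratio statistic against neutrality (w = 1).
#' @slot lrtP LRT p-value (chi-square, one df per selection parameter).
#' @slot ciMis Profile-likelihood 95\% CI for \code{wMis}.
#' @slot ciNon Profile-likelihood 95\% CI for \code{wNon} (NA if not fitted).
#' @slot model \code{"12-rate"} or \code{"192-rate"}.
#' @export
setClass("SelectionFit",
  representation(rates = "numeric", wMis = "numeric", wNon = "numeric",
                 logLik = "numeric", lrtStat = "numeric", lrtP = "numeric",
                 ciMis = "numeric", ciNon = "numeric", model = "character"))

setMethod("show", "SelectionFit", function(object) {
  cat("SelectionFit (", object@model, " model)\n", sep = "")
  cat(sprintf("  w_mis = %.4g (95%% CI %.4g-%.4g)\n",
              object@wMis, object@ciMis[1], object@ciMis[2]))
  if (!is.na(object@wNon))
    cat(sprintf("  w_non = %.4g (95%% CI %.4g-%.4g)\n",
                object@wNon, object@ciNon[1], object@ciNon[2]))
  cat(sprintf("  logLik = %.4f, LRT stat = %.4g, p = %.4g\n",
              object@logLik, object@lrtStat, object@lrtP))
})

#' Accessors for SelectionFit
#' @param x A \linkS4class{SelectionFit}.
#' @return Numeric scalar or vector.
#' @export
selectionWMis <- function(x) x@wMis

#' @rdname selectionWMis
#' @export
selectionWNon <- function(x) x@wNon

#' @rdname selectionWMis
#' @export
selectionCI <- function(x) x@ciMis

#' @rdname selectionWMis
#' @export
selectionRates <- function(x) x@rates

#' @rdname selectionWMis
#' @export
selectionLogLik <- function(x) x@logLik
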