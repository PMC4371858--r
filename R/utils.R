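# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' @importClassesFrom Biostrings DNAString
#' @importFrom methods new is validObject slot setValidity
#' @importFrom stats rbinom rpois runif rnorm optimize uniroot qchisq pchisq
#'   dpois ppois binom.test chisq.test wilcox.test aov cor setNames sd
#'   rmultinom quantile
#' @importFrom utils read.delim write.table head
NULL

# circular 1-based index
circ_index <- function(pos, len) ((pos - 1L) %% len) + 1L

comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

revcomp <- function(s) {
  vapply(s, function(one) {
    paste(rev(comp_base(strsplit(one, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Vertebrate mitochondrial genetic code (NCBI table 2), stops as "*"
mito_code <- function() Biostrings::getGeneticCode("SGC1")

translate_codons <- function(codons) {
  code <- mito_code()
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

is_stop <- function(codons) translate_codons(codons) == "*"

cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)
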