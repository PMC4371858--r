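# Shared fixtures and independent oracles, built in code at test time.

# tiny circular reference with one L-strand protein gene, one H-strand
# protein gene, one tRNA; deterministic
tinyGenome <- function(seed = 42L) {
  mitosig::simulateReference(length = 1200L, seed = seed)
}

# brute-force consequence enumerator: classify every single-base change in
# a protein gene by direct codon translation, independent of
# annotateConsequence's indexing
bruteForceConsequences <- function(ref, feature) {
  code <- Biostrings::getGeneticCode("SGC1")
  L <- length(ref)
  pos <- mitosig::featurePositions(feature, L)
  b <- mitosig::referenceBases(ref)
  cds <- b[pos]
  if (identical(feature$coding_strand, "H"))
    cds <- unname(c(A = "T", C = "G", G = "C", T = "A")[cds])
  out <- character(0)
  for (i in seq_along(cds)) {
    ci <- (i - 1) %/% 3
    w <- (i - 1) %% 3 + 1
    codon <- cds[(ci * 3 + 1):(ci * 3 + 3)]
    for (a in setdiff(c("A", "C", "G", "T"), cds[i])) {
      mut <- codon
      mut[w] <- a
      aa0 <- code[[paste(codon, collapse = "")]]
      aa1 <- code[[paste(mut, collapse = "")]]
      out <- c(out,
        if (aa0 == aa1) "silent"
        else if (aa1 == "*") "nonsense"
        else if (aa0 == "*") "stop_lost"
        else "missense")
    }
  }
  table(out)
}

# dense grid-search oracle for the dN/dS MLE: profile log-likelihood over
# w with the closed-form rate profile, maximised on a fine grid
gridSearchWMis <- function(observed, opportunities, grid = seq(0.02, 6, by = 0.001)) {
  Ls <- opportunities$L_syn
  Lm <- opportunities$L_mis + opportunities$L_stoploss
  ns <- observed$N_syn
  nm <- observed$N_mis + observed$N_stoploss
  keep <- (Ls + Lm) > 0
  Ls <- Ls[keep]; Lm <- Lm[keep]; ns <- ns[keep]; nm <- nm[keep]
  ll <- vapply(grid, function(w) {
    denom <- Ls + w * Lm
    r <- ifelse(denom > 0, (ns + nm) / denom, 0)
    sum(dpois(ns, r * Ls, log = TRUE)[Ls > 0 | ns > 0]) +
      sum(dpois(nm, r * w * Lm, log = TRUE)[Lm > 0 | nm > 0])
  }, numeric(1))
  grid[which.max(ll)]
}

# draw observed class counts directly from the Poisson selection model
simulateSelectionCounts <- function(opp, rates, wMis, seed) {
  set.seed(seed)
  data.frame(class = opp$class,
             N_syn = rpois(nrow(opp), rates * opp$L_syn),
             N_mis = rpois(nrow(opp), rates * wMis * opp$L_mis),
             N_non = rpois(nrow(opp), rates * opp$L_non),
             N_stoploss = rpois(nrow(opp), rates * wMis * opp$L_stoploss),
             stringsAsFactors = FALSE)
}

# single-site pileup row with given allele counts (plus/minus strands)
pileupRow <- function(pos, ref, counts_plus, counts_minus,
                      sample = "S1") {
  row <- data.frame(sample = sample, pos = pos, ref = ref,
                    stringsAsFactors = FALSE)
  for (a in c("A", "C", "G", "T")) {
    row[[paste0(a, "_plus")]] <- counts_plus[[a]]
    row[[paste0(a, "_minus")]] <- counts_minus[[a]]
  }
  row
}

balancedPileup <- function(pos, ref, counts, sample = "S1") {
  half <- lapply(counts, function(x) x %/% 2)
  other <- mapply(function(t, h) t - h, counts, half, SIMPLIFY = FALSE)
  pileupRow(pos, ref, half, other, sample)
}

# one-site tumor/normal pair run through the filter chain
mk <- function(ref, alt, nref, nalt, pos = 500, vafFloor = 0.001,
               altPlusFrac = 0.5, pmPlusFrac = 0.5, normalAlt = 0,
               blacklist = NULL, params = mitosig::callingDefaults()) {
  counts_plus <- setNames(as.list(rep(0, 4)), c("A", "C", "G", "T"))
  counts_minus <- counts_plus
  counts_plus[[ref]] <- round(nref * pmPlusFrac)
  counts_minus[[ref]] <- nref - round(nref * pmPlusFrac)
  counts_plus[[alt]] <- round(nalt * altPlusFrac)
  counts_minus[[alt]] <- nalt - round(nalt * altPlusFrac)
  tumor <- pileupRow(pos, ref, counts_plus, counts_minus)
  ncounts <- setNames(as.list(rep(0, 4)), c("A", "C", "G", "T"))
  ncounts[[ref]] <- 1000 - normalAlt
  ncounts[[alt]] <- normalAlt
  normal <- balancedPileup(pos, ref, ncounts)
  mitosig::callSomatic(tumor, normal, vafFloor = vafFloor,
                       blacklist = blacklist, params = params,
                       keepFiltered = TRUE)
}

cleanNormal <- function(pos, ref, depth = 1000, sample = "S1") {
  counts <- setNames(as.list(c(0, 0, 0, 0)), c("A", "C", "G", "T"))
  counts[[ref]] <- depth
  balancedPileup(pos, ref, counts, sample)
}
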