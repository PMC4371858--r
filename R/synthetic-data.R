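# Synthetic data with the statistical structure the analysis assumes:
# circular annotated genomes, strand-asymmetric signature-driven variant
# cohorts, heteroplasmic VAFs from drift, binomial pileups with sequencing
# error, injectable sample swaps and cross-contamination.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Default feature plan for synthetic genomes
#'
#' Two L-strand protein genes, one H-strand protein gene (mirroring the
#' 12:1 L:H split of human mtDNA at small scale), two tRNAs, one rRNA and
#' a control region placed across the origin.
#'
#' @return A \code{data.frame} with columns \code{feature},
#'   \code{proportion}, \code{coding_strand}.
#' @export
defaultGenePlan <- function() {
  data.frame(
    feature = c("protein", "protein", "protein", "tRNA", "tRNA",
                "rRNA", "dloop"),
    proportion = c(0.25, 0.20, 0.10, 0.02, 0.02, 0.10, 0.08),
    coding_strand = c("L", "L", "H", "L", "H", "L", "L"),
    stringsAsFactors = FALSE)
}

#' Simulate a circular annotated reference genome
#'
#' Generates a random circular sequence and places the features of
#' \code{genePlan} along it, separated by intergenic gaps. Protein genes
#' are valid open reading frames under the vertebrate mitochondrial code
#' (ATG start, no internal stop, terminal stop); the control region
#' (\code{dloop}) is placed across the origin so downstream circular
#' arithmetic is exercised. Deterministic given \code{seed}.
#'
#' @param length Genome length in bp (>= 300).
#' @param genePlan \code{data.frame} of features with proportions of the
#'   genome to occupy (see \code{\link{defaultGenePlan}}); proportions must
#'   sum to at most 1.
#' @param seed Integer RNG seed.
#' @param name Reference name.
#' @return A list with \code{ref} (\linkS4class{MtReference}),
#'   \code{annotation} (\code{data.frame}), and suggested origin-segment
#'   boundaries \code{oriB}, \code{oH} inside the control region.
#' @export
simulateReference <- function(length = 3000L, genePlan = defaultGenePlan(),
                              seed = 1L, name = "synthetic-mt") {
  length <- as.integer(length)
  if (length < 300L) stop_data("length must be >= 300")
  if (sum(genePlan$proportion) > 1)
    stop_data("gene plan proportions sum to more than 1")
  if (is.null(genePlan$coding_strand)) genePlan$coding_strand <- "L"
  with_seed(seed, {
    base <- sample(BASES, length, replace = TRUE)
    # D-loop (if any) wraps the origin; other features placed sequentially
    dloop <- genePlan[genePlan$feature == "dloop", , drop = FALSE]
    rest <- genePlan[genePlan$feature != "dloop", , drop = FALSE]
    ann <- list()
    cursor <- 1L
    budget_end <- length
    if (nrow(dloop) > 0) {
      dlen <- max(3L, round(length * dloop$proportion[1]))
      half <- dlen %/% 2L
      start <- length - (dlen - half) + 1L
      end <- half
      ann[[length(ann) + 1L]] <- data.frame(
        gene = "DLOOP", start = start, end = end, coding_strand = "L",
        feature = "dloop", frame_offset = 0L,
        anticodon_start = NA_integer_, stringsAsFactors = FALSE)
      cursor <- end + 10L
      budget_end <- start - 10L
    }
    code <- mito_code()
    sense_codons <- names(code)[code != "*"]
    stop_codon <- "TAA"
    counters <- c(protein = 0L, tRNA = 0L, rRNA = 0L)
    for (i in seq_len(nrow(rest))) {
      f <- rest[i, ]
      flen <- max(3L, round(length * f$proportion))
      if (f$feature == "protein") {
        ncod <- max(3L, flen %/% 3L)
        flen <- ncod * 3L
      }
      if (cursor + flen - 1L > budget_end)
        stop_data("gene plan infeasible: features do not fit the genome")
      start <- cursor; end <- cursor + flen - 1L
      anticodon <- NA_integer_
      if (f$feature == "protein") {
        ncod <- flen %/% 3L
        codons <- c("ATG",
                    sample(sense_codons, ncod - 2L, replace = TRUE),
                    stop_codon)
        cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
        if (f$coding_strand == "H") cds <- rev(comp_base(cds))
        base[start:end] <- cds
      } else if (f$feature == "tRNA") {
        anticodon <- start + flen %/% 2L
      }
      counters[f$feature] <- counters[f$feature] + 1L
      ann[[length(ann) + 1L]] <- data.frame(
        gene = paste0(toupper(substr(f$feature, 1, 1)),
                      substr(f$feature, 2, 10), counters[f$feature]),
        start = start, end = end, coding_strand = f$coding_strand,
        feature = f$feature, frame_offset = 0L,
        anticodon_start = anticodon, stringsAsFactors = FALSE)
      cursor <- end + 10L
    }
    annotation <- do.call(rbind, ann)
    ref <- MtReference(paste(base, collapse = ""), name = name)
    oriB <- if (nrow(dloop) > 0) annotation$start[1] + 5L else NA_integer_
    oH <- if (nrow(dloop) > 0) max(3L, annotation$end[1] - 5L) else NA_integer_
    list(ref = ref, annotation = annotation, oriB = oriB, oH = oH)
  })
}

#' Default strand-asymmetric signature preset
#'
#' A 192-class rate table qualitatively mimicking the somatic mtDNA
#' signature: C>T on the H strand dominates, about 10-fold enriched when
#' followed by G (NpCpG); T>C on the L strand is next, about 6-fold
#' enriched when followed by C (NpTpC); all other classes carry a small
#' background rate. Values are illustrative presets, not calibrated
#' estimates.
#'
#' @return Named numeric vector over the 192 classes.
#' @export
defaultSignatureRates <- function() {
  cls <- signatureClasses(192L)
  r <- setNames(rep(0.02, length(cls)), cls)
  ct_h <- grepl("^H:.\\[C>T\\].$", cls)
  r[ct_h] <- 0.20
  r[ct_h & grepl("\\]G$", cls)] <- 2.0
  tc_l <- grepl("^L:.\\[T>C\\].$", cls)
  r[tc_l] <- 0.12
  r[tc_l & grepl("\\]C$", cls)] <- 0.72
  r
}

#' Simulate a somatic variant cohort under a mutational signature
#'
#' Draws per-sample substitution counts from a Poisson distribution and
#' places each substitution at a genomic site with probability proportional
#' to the signature rate of its class (rate times context opportunity).
#' Within the configured Ori-b to O_H segment the replicative strand roles
#' are swapped when \code{dloopInversion} is set, so the emitted physical
#' changes there follow the opposite-strand classes. True VAFs come from
#' the configured heteroplasmy model.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation \code{data.frame} (kept with the truth for
#'   downstream consequence analysis).
#' @param signatureRates Named rate vector over 12 or 192 classes
#'   (see \code{\link{defaultSignatureRates}}).
#' @param nSamples Number of tumor samples.
#' @param mutationRate Expected substitutions per sample (Poisson mean).
#' @param vafModel List: \code{list(type="fixed", vaf=0.5)},
#'   \code{list(type="uniform", min=0.05, max=1)}, or
#'   \code{list(type="drift", M=50, T=100, x0=5)} (Wright-Fisher
#'   trajectory of \code{x0}/M initial heteroplasmy over T mitochondrial
#'   generations, conditioned on survival).
#' @param dloopInversion Swap strand roles inside the Ori-b..O_H segment.
#' @param oriB,oH Segment boundaries (required when \code{dloopInversion}).
#' @param contamination Per-sample contaminant fraction (recycled).
#' @param swapPairs Optional list of length-2 sample-index vectors marking
#'   intentionally swapped tumor/normal pairs.
#' @param seed Integer RNG seed.
#' @return A \code{CohortTruth} list: \code{variants} (sample, pos, ref,
#'   alt, vaf), \code{signature_rates}, \code{contamination},
#'   \code{swap_pairs}, \code{ref}, \code{annotation}, segment settings and
#'   \code{seed}.
#' @export
simulateCohort <- function(ref, annotation = NULL,
                           signatureRates = defaultSignatureRates(),
                           nSamples = 10L, mutationRate = 2,
                           vafModel = list(type = "uniform", min = 0.05, max = 1),
                           dloopInversion = FALSE, oriB = NULL, oH = NULL,
                           contamination = 0, swapPairs = NULL, seed = 1L) {
  nclass <- length(signatureRates)
  if (!nclass %in% c(12L, 192L))
    stop_data("signatureRates must cover 12 or 192 classes")
  if (any(signatureRates < 0)) stop_data("rates must be non-negative")
  if (all(signatureRates == 0) && mutationRate > 0)
    stop_data("all-zero signature rates with positive mutation rate")
  inv <- NULL
  if (dloopInversion) {
    if (is.null(oriB) || is.null(oH))
      stop_data("dloopInversion requires oriB and oH")
    inv <- inOriSegment(seq_len(length(ref)), oriB, oH)
  }
  sites <- siteClassTable(ref, nclass = nclass, invertedSegment = inv)
  w <- unname(signatureRates[sites$class])
  if (sum(w) == 0) stop_data("no site has positive mutation rate")
  contamination <- rep_len(contamination, nSamples)
  with_seed(seed, {
    nmut <- rpois(nSamples, mutationRate)
    rows <- lapply(seq_len(nSamples), function(i) {
      n <- min(nmut[i], sum(w > 0))
      if (n == 0L) return(NULL)
      pick <- sample.int(nrow(sites), n, prob = w)
      data.frame(sample = paste0("S", i), sites[pick, c("pos", "ref", "alt")],
                 stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, rows)
    if (is.null(variants))
      variants <- data.frame(sample = character(), pos = integer(),
                             ref = character(), alt = character(),
                             stringsAsFactors = FALSE)
    rownames(variants) <- NULL
    variants$vaf <- drawVafs(nrow(variants), vafModel)
    structure(list(variants = variants, signature_rates = signatureRates,
                   contamination = contamination, swap_pairs = swapPairs,
                   ref = ref, annotation = annotation,
                   dloop_inversion = dloopInversion, oriB = oriB, oH = oH,
                   seed = seed),
              class = "CohortTruth")
  })
}

drawVafs <- function(n, vafModel) {
  if (n == 0L) return(numeric(0))
  type <- vafModel$type %||% "fixed"
  switch(type,
    fixed = rep(vafModel$vaf %||% 0.5, n),
    uniform = runif(n, vafModel$min %||% 0.05, vafModel$max %||% 1),
    drift = {
      M <- vafModel$M %||% 50L
      T_ <- vafModel$T %||% 100L
      x0 <- vafModel$x0 %||% max(1L, round(0.1 * M))
      out <- numeric(n)
      todo <- seq_len(n)
      while (length(todo) > 0) {
        X <- rep(as.integer(x0), length(todo))
        for (g in seq_len(T_)) {
          seg <- X > 0L & X < M
          if (!any(seg)) break
          X[seg] <- rbinom(sum(seg), M, X[seg] / M)
        }
        ok <- X > 0L
        out[todo[ok]] <- X[ok] / M
        todo <- todo[!ok]  # condition on survival: redraw extinct
      }
      out
    },
    stop_data("unknown vaf model type: ", type))
}

#' @export
print.CohortTruth <- function(x, ...) {
  cat("CohortTruth:", nrow(x$variants), "variants in",
      length(unique(x$variants$sample)), "samples;",
      length(x$signature_rates), "signature classes; seed", x$seed, "\n")
  invisible(x)
}

#' Simulate tumor/normal allele-count pileups from a cohort truth
#'
#' Read depth at each emitted site is Poisson around \code{depth}; variant
#' read counts are binomial in the true VAF scaled down by the sample's
#' contaminant fraction; sequencing errors move reads to random other
#' alleles at \code{errorRate}; counts are split evenly between sequencing
#' strands. Germline polymorphism sites (if given) appear near-homoplasmic
#' in both tumor and normal.
#'
#' @param truth A \code{CohortTruth} from \code{\link{simulateCohort}}.
#' @param depth Mean read depth.
#' @param errorRate Per-read error probability (0 <= e < 0.25).
#' @param seed Integer RNG seed.
#' @param allSites Emit every genomic position per sample (useful for
#'   false-positive checks on small genomes); otherwise only variant and
#'   germline sites are emitted.
#' @param germline Optional \code{data.frame(pos, alt)} of shared
#'   germline polymorphisms.
#' @return List with \code{tumor} and \code{normal} pileup
#'   \code{data.frame}s (sample, pos, ref, then \code{<base>_plus} /
#'   \code{<base>_minus} Q20 counts).
#' @export
simulatePileups <- function(truth, depth = 1000, errorRate = 0.001,
                            seed = 1L, allSites = FALSE, germline = NULL) {
  stopifnot(inherits(truth, "CohortTruth"))
  if (depth < 0) stop_data("depth must be positive")
  if (depth == 0) {
    empty <- emptyPileup()
    return(list(tumor = empty, normal = empty))
  }
  if (errorRate < 0 || errorRate >= 0.25)
    stop_data("errorRate must be in [0, 0.25)")
  ref <- truth$ref
  b <- referenceBases(ref)
  samples <- unique(truth$variants$sample)
  if (length(samples) == 0L) samples <- "S1"
  with_seed(seed, {
    tumor <- list(); normal <- list()
    for (si in seq_along(samples)) {
      s <- samples[si]
      vs <- truth$variants[truth$variants$sample == s, , drop = FALSE]
      contam <- truth$contamination[min(si, length(truth$contamination))]
      pos <- if (allSites) seq_len(length(ref)) else
        sort(unique(c(vs$pos, germline$pos)))
      if (length(pos) == 0L) next
      vafT <- setNames(rep(0, length(pos)), pos)
      vafN <- vafT
      altAt <- setNames(rep(NA_character_, length(pos)), pos)
      if (nrow(vs) > 0) {
        vafT[as.character(vs$pos)] <- vs$vaf * (1 - contam)
        altAt[as.character(vs$pos)] <- vs$alt
      }
      if (!is.null(germline) && nrow(germline) > 0) {
        gp <- as.character(germline$pos)
        vafT[gp] <- 0.999; vafN[gp] <- 0.999
        altAt[gp] <- germline$alt
      }
      tumor[[s]] <- pileupRows(s, pos, b[pos], altAt, vafT, depth, errorRate)
      normal[[s]] <- pileupRows(s, pos, b[pos], altAt, vafN, depth, errorRate)
    }
    list(tumor = do.call(rbind, tumor) %||% emptyPileup(),
         normal = do.call(rbind, normal) %||% emptyPileup())
  })
}

emptyPileup <- function() {
  cols <- c("sample", "pos", "ref",
            paste0(rep(BASES, each = 2), c("_plus", "_minus")))
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df$pos <- integer(0)
  df
}

pileupRows <- function(sample, pos, refb, altb, vaf, depth, errorRate) {
  n <- length(pos)
  d <- rpois(n, depth)
  nvar <- rbinom(n, d, pmin(pmax(vaf, 0), 1))
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(n)) {
    cn <- setNames(integer(4), BASES)
    cn[refb[i]] <- d[i] - nvar[i]
    if (nvar[i] > 0 && !is.na(altb[i])) cn[altb[i]] <- cn[altb[i]] + nvar[i]
    if (errorRate > 0) {
      for (a in BASES) {
        if (cn[a] == 0) next
        nerr <- rbinom(1, cn[a], errorRate)
        if (nerr > 0) {
          to <- sample(setdiff(BASES, a), nerr, replace = TRUE)
          cn[a] <- cn[a] - nerr
          for (t in to) cn[t] <- cn[t] + 1L
        }
      }
    }
    counts[i, ] <- cn
  }
  plus <- matrix(rbinom(length(counts), as.vector(counts), 0.5),
                 n, 4L, dimnames = list(NULL, BASES))
  out <- data.frame(sample = sample, pos = pos, ref = refb,
                    stringsAsFactors = FALSE)
  for (a in BASES) {
    out[[paste0(a, "_plus")]] <- plus[, a]
    out[[paste0(a, "_minus")]] <- counts[, a] - plus[, a]
  }
  out
}

#' Simulate homozygous-SNP site counts for contamination estimation
#'
#' Emulates the nuclear common-SNP panel: at each normal-homozygous site
#' the tumor's wild-type (reference) reads arise from sequencing error plus
#' the contaminant, which contributes wild-type alleles at about half its
#' reads (it is heterozygous or homozygous reference at most such sites).
#'
#' @param contamination True contaminant fraction.
#' @param nSites Number of panel sites.
#' @param depth Mean Q20 depth per site.
#' @param errorRate Per-read error probability.
#' @param seed RNG seed.
#' @return \code{data.frame(RD_hom, RC_wt)}, one row per site.
#' @export
simulateHomSites <- function(contamination = 0, nSites = 100L, depth = 1000,
                             errorRate = 0.001, seed = 1L) {
  with_seed(seed, {
    RD <- rpois(nSites, depth)
    p_wt <- (1 - contamination) * errorRate + contamination / 2
    RC <- rbinom(nSites, RD, p_wt)
    data.frame(RD_hom = RD, RC_wt = RC)
  })
}

#' Simulate a genotype panel for sample-swap detection
#'
#' Returns counts of homozygous-matching, heterozygous and wild-type tumor
#' genotypes at normal-homozygous common SNP sites. Matched pairs genotype
#' almost perfectly; swapped pairs (different individuals) disagree at
#' about half the sites.
#'
#' @param swapped Is the pair a sample swap?
#' @param nSites Number of informative sites.
#' @param seed RNG seed.
#' @return Named integer vector \code{c(N_hom, N_het, N_wt)}.
#' @export
simulateGenotypePanel <- function(swapped = FALSE, nSites = 320L, seed = 1L) {
  with_seed(seed, {
    if (!swapped) {
      mism <- rbinom(1L, nSites, 0.002)
      c(N_hom = nSites - mism, N_het = mism, N_wt = 0L)
    } else {
      # unrelated individual at MAF ~0.5 sites: 1/4 hom, 1/2 het, 1/4 wt
      g <- rmultinom(1L, nSites, c(0.25, 0.5, 0.25))[, 1]
      c(N_hom = g[1], N_het = g[2], N_wt = g[3])
    }
  })
}

#' Simulate read evidence for phasing a nearby variant pair
#'
#' @param pos1,pos2 Variant positions; must be within \code{fragmentSpan}.
#' @param configuration \code{"co_clonal"}, \code{"sub_clonal"} or
#'   \code{"different_strand"}.
#' @param nReads Number of spanning fragments.
#' @param vaf VAF of the clone carrying variant 1.
#' @param subFraction For \code{sub_clonal}: fraction of variant-1 genomes
#'   that also carry variant 2.
#' @param seed RNG seed.
#' @return Named integer vector of haplotype read counts
#'   (\code{wt1_wt2}, \code{wt1_subs2}, \code{subs1_wt2}, \code{subs1_subs2}).
#' @export
simulatePhasingReads <- function(pos1, pos2,
                                 configuration = c("co_clonal", "sub_clonal",
                                                   "different_strand"),
                                 nReads = 50L, vaf = 0.5, subFraction = 0.5,
                                 fragmentSpan = 500L, seed = 1L) {
  configuration <- match.arg(configuration)
  if (abs(pos2 - pos1) > fragmentSpan)
    stop_data("positions farther apart than the fragment span")
  with_seed(seed, {
    probs <- switch(configuration,
      co_clonal = c(wt1_wt2 = 1 - vaf, wt1_subs2 = 0,
                    subs1_wt2 = 0, subs1_subs2 = vaf),
      sub_clonal = c(wt1_wt2 = 1 - vaf, wt1_subs2 = 0,
                     subs1_wt2 = vaf * (1 - subFraction),
                     subs1_subs2 = vaf * subFraction),
      different_strand = c(wt1_wt2 = 1 - 2 * vaf, wt1_subs2 = vaf,
                           subs1_wt2 = vaf, subs1_subs2 = 0))
    if (any(probs < 0)) stop_data("vaf too high for this configuration")
    counts <- rmultinom(1L, nReads, probs)[, 1]
    setNames(as.integer(counts), names(probs))
  })
}
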