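# Germline-scale sequence evolution under a strand-asymmetric signature,
# to stationary composition, with an optional synonymous-only constraint;
# plus codon-usage skew statistics.

# 64 x 4 lookup of per-generation substitution probabilities: row = the
# L-strand trinucleotide around a site, column = proposed L-strand target
# base. Built once from a 12- or 192-class strand-resolved rate table.
rateLookup <- function(rates) {
  nclass <- length(rates)
  stopifnot(nclass %in% c(12L, 192L))
  # row order must match trinucIndex(): 16*(left-1) + 4*(centre-1) + right
  trinucs <- character(64)
  for (l in 1:4) for (cc in 1:4) for (r in 1:4)
    trinucs[16L * (l - 1L) + 4L * (cc - 1L) + r] <-
      paste0(BASES[l], BASES[cc], BASES[r])
  lk <- matrix(0, nrow = 64, ncol = 4,
               dimnames = list(trinucs, BASES))
  for (t in trinucs) {
    b0 <- substr(t, 2, 2)
    pyr <- b0 %in% PYRIMIDINES
    for (a in setdiff(BASES, b0)) {
      if (pyr) {
        key <- if (nclass == 12L) paste0("L:", b0, ">", a) else
          paste0("L:", substr(t, 1, 1), "[", b0, ">", a, "]", substr(t, 3, 3))
      } else {
        rc <- revcomp(t)
        key <- if (nclass == 12L) paste0("H:", comp_base(b0), ">", comp_base(a))
          else paste0("H:", substr(rc, 1, 1), "[", comp_base(b0), ">",
                      comp_base(a), "]", substr(rc, 3, 3))
      }
      lk[t, a] <- rates[[key]]
    }
  }
  lk
}

seqToInt <- function(s) {
  match(strsplit(s, "")[[1]], BASES)
}
intToSeq <- function(v) paste(BASES[v], collapse = "")

# per-site trinucleotide row indices into the 64-row lookup (circular)
trinucIndex <- function(iv) {
  n <- length(iv)
  left <- iv[c(n, seq_len(n - 1L))]
  right <- iv[c(seq_len(n)[-1], 1L)]
  16L * (left - 1L) + 4L * (iv - 1L) + right
}

#' Evolve a circular sequence under a mutational signature
#'
#' Runs discrete generations of substitution on a circular sequence. Each
#' generation, every site independently mutates with probability equal to
#' the summed rate of its three possible changes given its current
#' trinucleotide context (rates are interpreted as per-site,
#' per-generation substitution probabilities); accepted changes pick the
#' target base in proportion to the class rates. Under the
#' \code{synonymous_only} constraint, proposals that would alter the
#' translation of any protein feature are rejected, holding the proteome
#' fixed (mutation-selection equilibrium). The run stops when the total
#' variation distance between trinucleotide compositions sampled
#' \code{window} generations apart falls below \code{stationarityTol}, or
#' at \code{maxGenerations}.
#'
#' @param start Character sequence, \linkS4class{MtReference}, or integer
#'   length (a uniform-random start of that length).
#' @param rates Named 12- or 192-class rate vector (per-site
#'   per-generation substitution probabilities; row sums at any context
#'   must not exceed 1).
#' @param constraint \code{"none"} or \code{"synonymous_only"}.
#' @param annotation Annotation \code{data.frame} (required under the
#'   synonymous constraint).
#' @param maxGenerations Generation cap.
#' @param stationarityTol Total-variation threshold for stationarity.
#' @param window Generations between composition snapshots.
#' @param seed RNG seed.
#' @return List of class \code{EvolutionRun}: \code{final} (character
#'   sequence), \code{generations}, \code{converged}, \code{trajectory}
#'   (matrix of 3-mer compositions by snapshot), \code{start},
#'   \code{constraint}, \code{seed}.
#' @export
evolveSequence <- function(start, rates, constraint = c("none", "synonymous_only"),
                           annotation = NULL, maxGenerations = 5000L,
                           stationarityTol = 1e-3, window = 100L, seed = 1L) {
  constraint <- match.arg(constraint)
  if (any(rates < 0)) stop_data("rates must be non-negative")
  startSeq <- if (is(start, "MtReference")) as.character(start@sequence)
    else if (is.numeric(start))
      with_seed(seed, paste(sample(BASES, start, replace = TRUE),
                            collapse = ""))
    else toupper(start)
  iv <- seqToInt(startSeq)
  if (anyNA(iv)) stop_data("start sequence must be A/C/G/T only")
  n <- length(iv)
  lk <- rateLookup(rates)
  tot <- rowSums(lk)
  if (any(tot > 1)) stop_data("per-site total rate exceeds 1 at some context")
  if (all(tot == 0)) {
    return(structure(list(final = startSeq, generations = 0L,
                          converged = TRUE, trajectory = NULL,
                          start = startSeq, constraint = constraint,
                          seed = seed), class = "EvolutionRun"))
  }
  checkSyn <- NULL
  if (constraint == "synonymous_only") {
    if (is.null(annotation))
      stop_data("synonymous_only constraint requires an annotation")
    checkSyn <- makeSynChecker(validateAnnotation(annotation), n)
  }
  with_seed(seed, {
    snaps <- list()
    lastComp <- NULL
    converged <- FALSE
    gen <- 0L
    while (gen < maxGenerations) {
      gen <- gen + 1L
      ti <- trinucIndex(iv)
      hit <- which(runif(n) < tot[ti])
      if (length(hit)) {
        for (s in hit) {
          # re-evaluate context: an earlier change this generation may
          # have altered this site's neighbours
          left <- iv[if (s == 1L) n else s - 1L]
          right <- iv[if (s == n) 1L else s + 1L]
          row <- lk[16L * (left - 1L) + 4L * (iv[s] - 1L) + right, ]
          if (sum(row) == 0) next
          tgt <- sample.int(4L, 1L, prob = row)
          if (!is.null(checkSyn) && !checkSyn(iv, s, tgt)) next
          iv[s] <- tgt
        }
      }
      if (gen %% window == 0L) {
        comp <- trimerComposition(iv)
        snaps[[length(snaps) + 1L]] <- comp
        if (!is.null(lastComp)) {
          tv <- 0.5 * sum(abs(comp - lastComp))
          if (tv < stationarityTol) { converged <- TRUE; break }
        }
        lastComp <- comp
      }
    }
    traj <- if (length(snaps)) do.call(rbind, snaps) else NULL
    structure(list(final = intToSeq(iv), generations = gen,
                   converged = converged, trajectory = traj,
                   start = startSeq, constraint = constraint, seed = seed),
              class = "EvolutionRun")
  })
}

#' @export
print.EvolutionRun <- function(x, ...) {
  cat("EvolutionRun:", nchar(x$start), "bp,", x$generations, "generations,",
      if (x$converged) "stationary" else "generation cap reached",
      "(constraint:", paste0(x$constraint, ")"), "\n")
  invisible(x)
}

trimerComposition <- function(iv) {
  ti <- trinucIndex(iv)
  tabulate(ti, nbins = 64L) / length(iv)
}

# closure testing whether substituting site s -> tgt preserves every
# protein translation (vertebrate mito code, stop stays stop)
makeSynChecker <- function(ann, genomeLength) {
  prot <- ann[ann$feature == "protein", , drop = FALSE]
  # site -> (gene row, codon base indices in genomic coords, within-codon
  # slot, coding strand); sites may belong to several genes
  siteInfo <- vector("list", genomeLength)
  for (i in seq_len(nrow(prot))) {
    pos <- featurePositions(prot[i, ], genomeLength)
    off <- as.integer(prot$frame_offset[i] %||% 0L)
    cds <- pos[(off + 1L):length(pos)]
    ncod <- length(cds) %/% 3L
    for (ci in seq_len(ncod)) {
      cp <- cds[(3L * (ci - 1L) + 1L):(3L * ci)]
      for (w in 1:3) {
        s <- cp[w]
        siteInfo[[s]] <- c(siteInfo[[s]],
          list(list(codon = cp, within = w,
                    strand = prot$coding_strand[i])))
      }
    }
  }
  code <- mito_code()
  compIdx <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in BASES order
  function(iv, s, tgt) {
    infos <- siteInfo[[s]]
    if (is.null(infos)) return(TRUE)
    for (info in infos) {
      b <- iv[info$codon]
      if (info$strand == "H") b <- compIdx[b]
      ref_codon <- paste(BASES[b], collapse = "")
      b2 <- iv[info$codon]
      b2[info$within] <- tgt
      if (info$strand == "H") b2 <- compIdx[b2]
      alt_codon <- paste(BASES[b2], collapse = "")
      if (!identical(code[[ref_codon]], code[[alt_codon]])) return(FALSE)
    }
    TRUE
  }
}

#' Pearson correlation of k-mer compositions between two sequences
#'
#' @param seqA,seqB Character sequences or \linkS4class{MtReference}s.
#' @param k K-mer size for circular L-strand counting (e.g. 1 or 3), or
#'   \code{"codon"} to compare in-frame codon frequencies over annotated
#'   protein features (requires \code{annA}/\code{annB}).
#' @param annA,annB Annotations for codon mode.
#' @return Pearson's r between the frequency vectors.
#' @export
compositionCorrelation <- function(seqA, seqB, k = 3L,
                                   annA = NULL, annB = NULL) {
  getSeq <- function(x) if (is(x, "MtReference")) as.character(x@sequence)
    else toupper(x)
  a <- getSeq(seqA); b <- getSeq(seqB)
  if (identical(k, "codon")) {
    fa <- codonFrequencies(MtReference(a), annA)
    fb <- codonFrequencies(MtReference(b), annB)
  } else {
    k <- as.integer(k)
    if (nchar(a) < k || nchar(b) < k) stop_data("sequences shorter than k")
    fa <- kmerFrequencies(a, k)
    fb <- kmerFrequencies(b, k)
  }
  if (sd(fa) == 0 || sd(fb) == 0)
    stop_data("constant k-mer frequency vector: correlation undefined")
  cor(fa, fb)
}

kmerFrequencies <- function(s, k) {
  iv <- seqToInt(s)
  n <- length(iv)
  idx <- rep(0L, n)
  for (j in seq_len(k))
    idx <- idx * 4L + (iv[circ_index(seq_len(n) + j - 1L, n)] - 1L)
  tabulate(idx + 1L, nbins = 4L^k) / n
}

codonFrequencies <- function(ref, ann) {
  if (is.null(ann)) stop_data("codon mode requires an annotation")
  ann <- validateAnnotation(ann)
  prot <- ann[ann$feature == "protein", , drop = FALSE]
  counts <- setNames(numeric(64),
                     as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                     BASES, paste0)))
  for (i in seq_len(nrow(prot))) {
    s <- featureSequence(ref, prot[i, ])
    off <- as.integer(prot$frame_offset[i] %||% 0L)
    s <- substr(s, off + 1L, nchar(s))
    cods <- substring(s, seq(1, nchar(s) - 2, by = 3),
                      seq(3, nchar(s), by = 3))
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts / max(1, sum(counts))
}

#' Codon-usage skew under asymmetric mutational pressure
#'
#' Counts third-codon-position bases per gene group and computes
#' \deqn{TCskew = (N_C - N_T)/(N_C + N_T)}
#' \deqn{GAskew = (N_A - N_G)/(N_A + N_G)}
#' along with per-family synonymous codon ratios (NNA:NNG and NNT:NNC
#' within synonymous pairs). L- and H-strand genes are reported
#' separately: they sit under opposite mutational pressure.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation \code{data.frame}.
#' @param genes Optional gene restriction; all must be protein features.
#' @return List with \code{by_strand} \code{data.frame} (strand, N_A,
#'   N_C, N_G, N_T, tc_skew, ga_skew) and \code{codon_ratios}
#'   \code{data.frame} (strand, family, ratio_A_G, ratio_T_C).
#' @export
codonSkew <- function(ref, annotation, genes = NULL) {
  ann <- validateAnnotation(annotation)
  if (!is.null(genes)) {
    ann <- ann[ann$gene %in% genes, , drop = FALSE]
    if (any(ann$feature != "protein"))
      stop_data("gene set contains non-protein features")
  }
  prot <- ann[ann$feature == "protein", , drop = FALSE]
  if (nrow(prot) == 0) stop_data("no protein features")
  code <- mito_code()
  res <- list(); ratios <- list()
  for (strand in intersect(c("L", "H"), unique(prot$coding_strand))) {
    pp <- prot[prot$coding_strand == strand, , drop = FALSE]
    thirds <- character(0)
    codons <- character(0)
    for (i in seq_len(nrow(pp))) {
      s <- featureSequence(ref, pp[i, ])
      off <- as.integer(pp$frame_offset[i] %||% 0L)
      s <- substr(s, off + 1L, nchar(s))
      cods <- substring(s, seq(1, nchar(s) - 2, by = 3),
                        seq(3, nchar(s), by = 3))
      codons <- c(codons, cods)
      thirds <- c(thirds, substr(cods, 3, 3))
    }
    N <- vapply(BASES, function(b) sum(thirds == b), numeric(1))
    res[[strand]] <- data.frame(
      strand = strand, N_A = N[["A"]], N_C = N[["C"]],
      N_G = N[["G"]], N_T = N[["T"]],
      tc_skew = (N[["C"]] - N[["T"]]) / max(1, N[["C"]] + N[["T"]]),
      ga_skew = (N[["A"]] - N[["G"]]) / max(1, N[["A"]] + N[["G"]]),
      stringsAsFactors = FALSE)
    tab <- table(codons)
    fam <- unique(substr(names(code), 1, 2))
    for (f in fam) {
      cA <- paste0(f, "A"); cG <- paste0(f, "G")
      cT <- paste0(f, "T"); cC <- paste0(f, "C")
      getn <- function(x) if (x %in% names(tab)) as.numeric(tab[x]) else 0
      rAG <- if (identical(code[[cA]], code[[cG]]))
        getn(cA) / max(1, getn(cG)) else NA_real_
      rTC <- if (identical(code[[cT]], code[[cC]]))
        getn(cT) / max(1, getn(cC)) else NA_real_
      ratios[[paste(strand, f)]] <- data.frame(
        strand = strand, family = f, ratio_A_G = rAG, ratio_T_C = rTC,
        stringsAsFactors = FALSE)
    }
  }
  by_strand <- do.call(rbind, res); rownames(by_strand) <- NULL
  codon_ratios <- do.call(rbind, ratios); rownames(codon_ratios) <- NULL
  list(by_strand = by_strand, codon_ratios = codon_ratios)
}

#' Analytic stationary base composition for a context-free rate table
#'
#' For a 12-class (context-free) rate table, each L-strand site is an
#' independent 4-state Markov chain; the stationary distribution is the
#' left eigenvector (eigenvalue 1) of the per-generation transition
#' matrix. Used to validate the simulator.
#'
#' @param rates Named 12-class rate vector.
#' @return Named numeric of stationary A/C/G/T frequencies (L strand).
#' @export
stationaryComposition <- function(rates) {
  stopifnot(length(rates) == 12L)
  P <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (b in BASES) {
    for (a in setdiff(BASES, b)) {
      key <- if (b %in% PYRIMIDINES) paste0("L:", b, ">", a) else
        paste0("H:", comp_base(b), ">", comp_base(a))
      P[b, a] <- rates[[key]]
    }
    P[b, b] <- 1 - sum(P[b, ])
  }
  if (any(diag(P) < 0)) stop_data("rates too large for a transition matrix")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  setNames(pmax(v, 0) / sum(pmax(v, 0)), BASES)
}
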