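# Context-dependent Poisson dN/dS inference and related selection tests.
#
# For selection the substitution classes are directional changes on the
# L-strand reference: 12 classes ("A>C", ..., "T>G") or 192 classes with
# the L-strand 5'/3' neighbours ("A[C>T]G"). Directional classes are kept
# (not pyrimidine-collapsed) because the mutational process is strongly
# strand-asymmetric.

selClassKey <- function(ref, pos, refAllele, altAllele, nclass = 192L) {
  if (nclass == 12L) return(paste0(refAllele, ">", altAllele))
  ctx <- trinucleotideContext(ref, pos, "L")
  paste0(substr(ctx, 1, 1), "[", refAllele, ">", altAllele, "]",
         substr(ctx, 3, 3))
}

selClasses <- function(nclass = 192L) {
  if (nclass == 12L) {
    keys <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
    return(keys[substr(keys, 1, 1) != substr(keys, 3, 3)])
  }
  keys <- character(0)
  for (p5 in BASES) for (b in BASES) for (a in setdiff(BASES, b))
    for (p3 in BASES)
      keys <- c(keys, paste0(p5, "[", b, ">", a, "]", p3))
  keys
}

#' Opportunity counts for dN/dS
#'
#' Enumerates every possible single-base change at every protein-coding
#' position, classifies it under the vertebrate mitochondrial code on the
#' coding strand of its gene, and tallies per substitution class the
#' number of sites whose mutation would be synonymous, missense, nonsense
#' or stop-lost. Positions inside overlapping protein genes are counted
#' once per gene.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation \code{data.frame}; only \code{protein}
#'   features are used.
#' @param nclass 12 or 192 (L-strand directional classes).
#' @param genes Optional character vector restricting to named genes.
#' @return \code{data.frame(class, L_syn, L_mis, L_non, L_stoploss)} over
#'   all classes.
#' @export
opportunityCounts <- function(ref, annotation, nclass = 192L, genes = NULL) {
  ann <- validateAnnotation(annotation)
  ann <- ann[ann$feature == "protein", , drop = FALSE]
  if (!is.null(genes)) ann <- ann[ann$gene %in% genes, , drop = FALSE]
  if (nrow(ann) == 0) stop_data("no protein features in annotation")
  classes <- selClasses(nclass)
  cols <- c(silent = "L_syn", missense = "L_mis", nonsense = "L_non",
            stop_lost = "L_stoploss")
  m <- matrix(0, nrow = length(classes), ncol = 4,
              dimnames = list(classes, unname(cols)))
  b <- referenceBases(ref)
  L <- length(ref)
  for (i in seq_len(nrow(ann))) {
    f <- ann[i, ]
    pos <- featurePositions(f, L)
    off <- as.integer(f$frame_offset %||% 0L)
    cds_len <- length(pos) - off
    if (cds_len %% 3L != 0L)
      stop_data("protein feature ", f$gene,
                " length not divisible by 3 after frame offset")
    usable <- pos[(off + 1L):length(pos)]
    for (p in usable) {
      refb <- b[p]
      if (!refb %in% BASES) next
      for (a in setdiff(BASES, refb)) {
        cc <- codonChange(ref, f, p, a)
        if (!cc$category %in% names(cols)) next
        key <- selClassKey(ref, p, refb, a, nclass)
        m[key, cols[[cc$category]]] <- m[key, cols[[cc$category]]] + 1
      }
    }
  }
  data.frame(class = classes, m, row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed protein-coding mutation counts by class and consequence
#'
#' @param variants Variant \code{data.frame} with \code{pos}, \code{ref},
#'   \code{alt} (single-base substitutions; others are ignored).
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation \code{data.frame}.
#' @param nclass 12 or 192.
#' @param genes Optional gene restriction.
#' @return \code{data.frame(class, N_syn, N_mis, N_non, N_stoploss)}.
#' @export
observedCounts <- function(variants, ref, annotation, nclass = 192L,
                           genes = NULL) {
  ann <- validateAnnotation(annotation)
  ann <- ann[ann$feature == "protein", , drop = FALSE]
  if (!is.null(genes)) ann <- ann[ann$gene %in% genes, , drop = FALSE]
  classes <- selClasses(nclass)
  cols <- c(silent = "N_syn", missense = "N_mis", nonsense = "N_non",
            stop_lost = "N_stoploss")
  m <- matrix(0, nrow = length(classes), ncol = 4,
              dimnames = list(classes, unname(cols)))
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  L <- length(ref)
  snv <- snv[snv$ref != snv$alt & snv$ref %in% BASES &
               snv$alt %in% BASES, , drop = FALSE]
  for (j in seq_len(nrow(snv))) {
    p <- snv$pos[j]
    for (i in seq_len(nrow(ann))) {
      if (!featureContains(ann[i, ], p, L)) next
      cc <- codonChange(ref, ann[i, ], p, snv$alt[j])
      if (!cc$category %in% names(cols)) next
      key <- selClassKey(ref, p, snv$ref[j], snv$alt[j], nclass)
      m[key, cols[[cc$category]]] <- m[key, cols[[cc$category]]] + 1
    }
  }
  data.frame(class = classes, m, row.names = NULL, stringsAsFactors = FALSE)
}

# log-likelihood of the Poisson model for given rates and selection params
dndsLogLik <- function(r, wMis, wNon, obs, Ls, Lm, Ln) {
  lam_s <- r * Ls; lam_m <- r * wMis * Lm
  ll <- sum(dpois(obs$ns, lam_s, log = TRUE)[Ls > 0 | obs$ns > 0]) +
        sum(dpois(obs$nm, lam_m, log = TRUE)[Lm > 0 | obs$nm > 0])
  if (!is.na(wNon))
    ll <- ll + sum(dpois(obs$nn, r * wNon * Ln, log = TRUE)[Ln > 0 | obs$nn > 0])
  ll
}

#' Fit the context-dependent Poisson dN/dS model
#'
#' Models per-class mutation counts as Poisson with expectations
#' \eqn{\lambda_{syn,k} = r_k L_{syn,k}},
#' \eqn{\lambda_{mis,k} = r_k w_{mis} L_{mis,k}} (and
#' \eqn{\lambda_{non,k} = r_k w_{non} L_{non,k}} when \code{fitWNon}),
#' with a common selection coefficient across classes. Maximum-likelihood
#' estimates are found by hill climbing: coordinate-wise closed-form
#' updates of the rates and selection coefficients from random restarts,
#' stopping when the log-likelihood improves by less than \code{tol}.
#' Neutrality (w = 1) is tested by a likelihood-ratio test with one df per
#' selection parameter; 95\% confidence intervals are profile-likelihood.
#'
#' @param observed Output of \code{\link{observedCounts}} (or a
#'   \code{data.frame} with \code{class}, \code{N_syn}, \code{N_mis},
#'   \code{N_non}, \code{N_stoploss}).
#' @param opportunities Output of \code{\link{opportunityCounts}}.
#' @param fitWNon Also fit a nonsense selection coefficient; otherwise
#'   nonsense counts/opportunities are excluded from the likelihood.
#' @param stopLossAs How stop-lost sites are fitted: \code{"missense"}
#'   (folded into the missense class, the default) or \code{"nonsense"}.
#' @param nRestarts Number of random restarts for the hill climb.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param seed Seed for restart starting points.
#' @return A \linkS4class{SelectionFit}.
#' @export
fitDnds <- function(observed, opportunities, fitWNon = FALSE,
                    stopLossAs = c("missense", "nonsense"),
                    nRestarts = 5L, tol = 1e-8, seed = 1L) {
  stopLossAs <- match.arg(stopLossAs)
  stopifnot(identical(observed$class, opportunities$class))
  Ls <- opportunities$L_syn
  Lm <- opportunities$L_mis
  Ln <- opportunities$L_non
  ns <- observed$N_syn; nm <- observed$N_mis; nn <- observed$N_non
  if (stopLossAs == "missense") {
    Lm <- Lm + opportunities$L_stoploss
    nm <- nm + observed$N_stoploss
  } else {
    Ln <- Ln + opportunities$L_stoploss
    nn <- nn + observed$N_stoploss
  }
  keep <- (Ls + Lm + Ln) > 0
  if (any((ns + nm + nn)[!keep] > 0))
    stop_data("observed mutations in a class with zero opportunity")
  Ls <- Ls[keep]; Lm <- Lm[keep]; Ln <- Ln[keep]
  ns <- ns[keep]; nm <- nm[keep]; nn <- nn[keep]
  if (sum(ns) == 0)
    stop_data("no synonymous observations: selection unidentifiable")
  obs <- list(ns = ns, nm = nm, nn = nn)
  if (!fitWNon) { nn0 <- nn; nn <- rep(0, length(nn)); Ln <- rep(0, length(Ln)) }
  obs <- list(ns = ns, nm = nm, nn = nn)

  climb <- function(w0m, w0n, fixMis = NA_real_, fixNon = NA_real_) {
    wm <- if (!is.na(fixMis)) fixMis else w0m
    wn <- if (fitWNon) { if (!is.na(fixNon)) fixNon else w0n } else NA_real_
    ll <- -Inf
    for (iter in 1:500) {
      denom <- Ls + wm * Lm + (if (fitWNon) wn * Ln else 0)
      tot <- ns + nm + (if (fitWNon) nn else 0)
      r <- ifelse(denom > 0, tot / denom, 0)
      if (is.na(fixMis)) {
        d <- sum(r * Lm)
        wm <- if (d > 0) sum(nm) / d else 1
      }
      if (fitWNon && is.na(fixNon)) {
        d <- sum(r * Ln)
        wn <- if (d > 0) sum(nn) / d else 1
      }
      newll <- dndsLogLik(r, wm, if (fitWNon) wn else NA_real_, obs, Ls, Lm, Ln)
      if (is.finite(newll) && newll - ll < tol && iter > 1) {
        ll <- newll; break
      }
      ll <- newll
    }
    list(r = r, wMis = wm, wNon = if (fitWNon) wn else NA_real_, ll = ll)
  }

  best <- NULL
  starts <- with_seed(seed, cbind(exp(runif(nRestarts, log(0.2), log(5))),
                                  exp(runif(nRestarts, log(0.2), log(5)))))
  starts[1, ] <- c(1, 1)
  for (i in seq_len(nrow(starts))) {
    fit <- climb(starts[i, 1], starts[i, 2])
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  # null model: all selection parameters fixed at 1
  null <- climb(1, 1, fixMis = 1, fixNon = if (fitWNon) 1 else NA_real_)
  lrt <- max(0, 2 * (best$ll - null$ll))
  df <- 1L + as.integer(fitWNon)
  pval <- pchisq(lrt, df, lower.tail = FALSE)

  profile <- function(which) {
    function(w) {
      f <- if (which == "mis") climb(w, best$wNon %||% 1, fixMis = w)
           else climb(best$wMis, w, fixNon = w)
      f$ll
    }
  }
  ciMis <- profileCI(profile("mis"), best$wMis, best$ll)
  ciNon <- if (fitWNon) profileCI(profile("non"), best$wNon, best$ll)
           else c(NA_real_, NA_real_)

  rates <- setNames(best$r, observed$class[keep])
  new("SelectionFit", rates = rates, wMis = best$wMis,
      wNon = if (fitWNon) best$wNon else NA_real_,
      logLik = best$ll, lrtStat = lrt, lrtP = pval,
      ciMis = ciMis, ciNon = ciNon,
      model = paste0(if (length(keep) > 20) "192" else "12", "-rate"))
}

# 95% profile-likelihood interval: w where 2*(llmax - profll(w)) = chisq
profileCI <- function(profll, what, llmax, level = 0.95) {
  crit <- qchisq(level, 1) / 2
  f <- function(w) llmax - profll(w) - crit
  lo <- tryCatch({
    if (f(1e-4) < 0) 1e-4 else uniroot(f, c(1e-4, what))$root
  }, error = function(e) NA_real_)
  hi <- tryCatch({
    if (f(1e4) < 0) 1e4 else uniroot(f, c(what, 1e4))$root
  }, error = function(e) NA_real_)
  c(lo, hi)
}

#' tRNA anticodon negative-selection test
#'
#' Compares the observed number of substitutions falling in tRNA
#' anticodon triplets with the number expected under the mutational
#' signature. Each tRNA site's mutability is the summed signature rate of
#' its three possible changes; the expectation is the total tRNA mutation
#' count apportioned by the anticodon share of that mutability. The
#' p-value is a two-sided exact Poisson tail.
#'
#' @param variants Variant \code{data.frame}.
#' @param ref An \linkS4class{MtReference}.
#' @param annotation Annotation with tRNA features carrying
#'   \code{anticodon_start}.
#' @param sig A replicative \linkS4class{SignatureTable} supplying rates.
#' @return List with \code{observed}, \code{expected}, \code{n_trna},
#'   \code{p.value}.
#' @export
trnaAnticodonTest <- function(variants, ref, annotation, sig) {
  ann <- validateAnnotation(annotation)
  trna <- ann[ann$feature == "tRNA", , drop = FALSE]
  if (nrow(trna) == 0) stop_data("no tRNA features")
  if (any(is.na(trna$anticodon_start)))
    stop_data("tRNA features missing anticodon_start")
  L <- length(ref)
  trnaPos <- unique(unlist(lapply(seq_len(nrow(trna)), function(i)
    featurePositions(trna[i, ], L))))
  acPos <- unique(unlist(lapply(trna$anticodon_start, function(s)
    circ_index(s + 0:2, L))))
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  inTrna <- snv$pos %in% trnaPos
  nTrna <- sum(inTrna)
  observed <- sum(snv$pos[inTrna] %in% acPos)
  if (nTrna == 0)
    return(list(observed = 0L, expected = 0, n_trna = 0L, p.value = 1))
  siteRate <- function(positions) {
    st <- siteClassTable(ref, positions, nclass = sig@nclass)
    sum(sig@rates[st$class])
  }
  wAll <- siteRate(trnaPos)
  wAc <- siteRate(intersect(acPos, trnaPos))
  expected <- nTrna * (if (wAll > 0) wAc / wAll else 0)
  p <- min(1, 2 * min(ppois(observed, expected),
                      ppois(observed - 1, expected, lower.tail = FALSE)))
  list(observed = observed, expected = expected, n_trna = nTrna,
       p.value = p)
}

#' Recurrence of somatic substitutions vs a null placement model
#'
#' A mutation is recurrent when its position (or position+allele with
#' \code{key = "allele"}) occurs in more than one sample. The expectation
#' under chance is obtained by Monte-Carlo placement of the same number of
#' mutations, uniformly or in proportion to signature-weighted site
#' mutability.
#'
#' @param variants Variant \code{data.frame} with \code{sample},
#'   \code{pos} (and \code{alt} for allele keying).
#' @param ref An \linkS4class{MtReference}.
#' @param nullModel \code{"uniform"} or \code{"signature"}.
#' @param sig \linkS4class{SignatureTable} for the signature null.
#' @param nSims Number of Monte-Carlo placements (>= 100).
#' @param key Recurrence identity.
#' @param seed RNG seed.
#' @return List with \code{n_recurrent}, \code{n_positions},
#'   \code{expected}, \code{fold_enrichment}, \code{p.value}.
#' @export
recurrenceAnalysis <- function(variants, ref,
                               nullModel = c("uniform", "signature"),
                               sig = NULL, nSims = 1000L,
                               key = c("position", "allele"), seed = 1L) {
  nullModel <- match.arg(nullModel)
  key <- match.arg(key)
  if (nSims < 100) stop_data("nSims must be >= 100")
  ids <- if (key == "position") variants$pos else
    paste(variants$pos, variants$alt)
  tab <- table(ids)
  n_rec <- sum(tab[tab > 1])
  n_pos <- sum(tab > 1)
  n <- length(ids)
  L <- length(ref)
  prob <- NULL
  if (nullModel == "signature") {
    if (is.null(sig)) stop_data("signature null requires sig")
    st <- siteClassTable(ref, nclass = sig@nclass)
    w <- sig@rates[st$class]
    prob <- vapply(split(w, st$pos), sum, numeric(1))[as.character(seq_len(L))]
    prob[is.na(prob)] <- 0
  }
  nullRec <- with_seed(seed, vapply(seq_len(nSims), function(i) {
    p <- sample.int(L, n, replace = TRUE, prob = prob)
    t2 <- tabulate(p, nbins = L)
    sum(t2[t2 > 1])
  }, numeric(1)))
  expd <- mean(nullRec)
  list(n_recurrent = n_rec, n_positions = n_pos, expected = expd,
       fold_enrichment = if (expd > 0) n_rec / expd else
         (if (n_rec > 0) Inf else 0),
       p.value = (1 + sum(nullRec >= n_rec)) / (nSims + 1))
}

#' Compare recurrence rates between consequence groups by resampling
#'
#' Repeatedly draws \code{nDraw} substitutions from each group, counts how
#' many of the drawn substitutions share a position within the draw, and
#' compares the per-iteration counts across groups by one-way ANOVA.
#'
#' @param groups Named list of variant \code{data.frame}s (each with
#'   \code{pos}); e.g. silent third-base, missense first-base, missense
#'   second-base substitutions.
#' @param nDraw Substitutions drawn per group per iteration (default 100).
#' @param nIter Iterations (default 300).
#' @param seed RNG seed.
#' @return List with \code{counts} (iteration x group \code{data.frame}),
#'   \code{group_means}, \code{anova_p}.
#' @export
recurrenceResample <- function(groups, nDraw = 100L, nIter = 300L,
                               seed = 1L) {
  small <- names(groups)[vapply(groups, nrow, integer(1)) < nDraw]
  if (length(small))
    stop_data("group(s) smaller than nDraw: ", paste(small, collapse = ", "))
  counts <- with_seed(seed, {
    sapply(groups, function(g) {
      vapply(seq_len(nIter), function(i) {
        pos <- sample(g$pos, nDraw)
        t2 <- table(pos)
        sum(t2[t2 > 1])
      }, numeric(1))
    })
  })
  counts <- as.data.frame(counts)
  long <- data.frame(count = unlist(counts, use.names = FALSE),
                     group = rep(names(counts), each = nIter))
  p <- if (sd(long$count) == 0) 1 else
    summary(aov(count ~ group, data = long))[[1]][["Pr(>F)"]][1]
  list(counts = counts, group_means = colMeans(counts), anova_p = p)
}

#' VAF comparison across consequence groups
#'
#' Nearly neutral mutations drift freely toward homoplasmy while
#' deleterious ones are held at low heteroplasmy, so group VAF
#' distributions carry a selection signal. Group means are reported with
#' two-sided Wilcoxon rank-sum tests between all pairs.
#'
#' @param variants \code{data.frame} with \code{vaf} and a grouping column
#'   \code{consequence}.
#' @param minGroup Groups smaller than this are dropped with a warning.
#' @return List with \code{means} (named vector) and \code{pairwise}
#'   (\code{data.frame} of group pairs and p-values).
#' @export
vafSelectionTest <- function(variants, minGroup = 2L) {
  sp <- split(variants$vaf, variants$consequence)
  small <- names(sp)[vapply(sp, length, integer(1)) < minGroup]
  if (length(small)) {
    warning("dropping group(s) with fewer than ", minGroup, " variants: ",
            paste(small, collapse = ", "))
    sp <- sp[!names(sp) %in% small]
  }
  if (length(sp) < 2) stop_data("need at least two groups")
  means <- vapply(sp, mean, numeric(1))
  pairs <- utils::combn(names(sp), 2)
  pairwise <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p.value = apply(pairs, 2, function(g)
      suppressWarnings(wilcox.test(sp[[g[1]]], sp[[g[2]]])$p.value)),
    stringsAsFactors = FALSE)
  list(means = means, pairwise = pairwise)
}
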