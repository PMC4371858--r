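test_that("opportunity counts for a single ATG codon match brute force", {
  # pad so the gene sits mid-sequence; gene = single codon ATG + stop
  ref <- MtReference("CCCCATGTAACCCC")
  ann <- data.frame(gene = "G1", start = 5, end = 10, coding_strand = "L",
                    feature = "protein", frame_offset = 0L,
                    anticodon_start = NA_integer_, stringsAsFactors = FALSE)
  opp <- opportunityCounts(ref, ann, nclass = 12L)
  # ATG alone: ATA silent (Met), AGG nonsense, 7 missense; the TAA stop
  # codon contributes stop-lost and silent (TAA<->TAG) changes
  atgOnly <- local({
    refOne <- MtReference("CCCCATGCCCCCC")
    annOne <- data.frame(gene = "G1", start = 5, end = 7,
                         coding_strand = "L", feature = "protein",
                         frame_offset = 0L, anticodon_start = NA_integer_)
    opportunityCounts(refOne, annOne, nclass = 12L)
  })
  expect_equal(sum(atgOnly$L_syn), 1)
  expect_equal(sum(atgOnly$L_non), 1)
  expect_equal(sum(atgOnly$L_mis), 7)
  expect_equal(unname(atgOnly$L_syn[atgOnly$class == "G>A"]), 1)  # ATG>ATA
  expect_equal(unname(atgOnly$L_non[atgOnly$class == "T>G"]), 1)  # ATG>AGG
  # totals: 3 changes per coding position
  expect_equal(sum(opp$L_syn + opp$L_mis + opp$L_non + opp$L_stoploss),
               3 * 6)
})

test_that("opportunities double for a tandem-duplicated gene and match brute force", {
  sim <- tinyGenome()
  prot <- sim$annotation[sim$annotation$feature == "protein", ][1, ]
  single <- opportunityCounts(sim$ref, prot, nclass = 192L)
  dup <- rbind(prot, transform(prot, gene = "G1b"))
  doubled <- opportunityCounts(sim$ref, dup, nclass = 192L)
  expect_equal(doubled$L_syn, 2 * single$L_syn)
  expect_equal(doubled$L_mis, 2 * single$L_mis)
  expect_equal(doubled$L_non, 2 * single$L_non)

  len <- sum(vapply(which(sim$annotation$feature == "protein"),
                    function(i) length(featurePositions(
                      sim$annotation[i, ], length(sim$ref))), integer(1)))
  allOpp <- opportunityCounts(sim$ref, sim$annotation, nclass = 192L)
  expect_equal(sum(allOpp$L_syn + allOpp$L_mis + allOpp$L_non +
                     allOpp$L_stoploss), 3 * len)

  # consequence split agrees with the brute-force enumerator per gene
  oracle <- bruteForceConsequences(sim$ref, prot)
  expect_equal(sum(single$L_syn), unname(oracle[["silent"]]))
  expect_equal(sum(single$L_mis), unname(oracle[["missense"]]))
  expect_equal(sum(single$L_non), unname(oracle[["nonsense"]]))
})

test_that("a neutral construction fits w = 1 with a null LRT", {
  sim <- tinyGenome()
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  # counts exactly equal to opportunities: the neutral model with r = 1
  obs <- data.frame(class = opp$class,
                    N_syn = opp$L_syn, N_mis = opp$L_mis,
                    N_non = opp$L_non, N_stoploss = opp$L_stoploss)
  fit <- fitDnds(obs, opp)
  expect_equal(selectionWMis(fit), 1, tolerance = 1e-5)
  expect_lt(fit@lrtStat, 1e-6)
})

test_that("doubled missense counts fit w about 2, matching the grid-search oracle", {
  sim <- tinyGenome()
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  obs <- simulateSelectionCounts(opp, rates = 0.08, wMis = 2, seed = 71)
  fit <- fitDnds(obs, opp)
  oracle <- gridSearchWMis(obs, opp)
  expect_equal(selectionWMis(fit), oracle, tolerance = 1e-3)
  expect_lt(abs(selectionWMis(fit) - 2), 0.5)
  ci <- selectionCI(fit)
  expect_true(ci[1] < selectionWMis(fit) && selectionWMis(fit) < ci[2])
  # likelihood at the optimum is at least the neutral likelihood
  expect_gte(fit@lrtStat, 0)
})

test_that("the nonsense selection coefficient is fitted when requested", {
  sim <- tinyGenome()
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  set.seed(72)
  obs <- data.frame(class = opp$class,
                    N_syn = rpois(nrow(opp), 0.2 * opp$L_syn),
                    N_mis = rpois(nrow(opp), 0.2 * opp$L_mis),
                    N_non = rpois(nrow(opp), 0.2 * 0.2 * opp$L_non),
                    N_stoploss = 0L)
  fit <- fitDnds(obs, opp, fitWNon = TRUE)
  expect_lt(selectionWNon(fit), 0.6)
  expect_gt(selectionWMis(fit), 0.6)
})

test_that("12- and 192-rate models agree without context dependence", {
  sim <- tinyGenome()
  opp12 <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  opp192 <- opportunityCounts(sim$ref, sim$annotation, nclass = 192L)
  sim191 <- simulateSelectionCounts(opp192, rates = 0.15, wMis = 1.5,
                                    seed = 73)
  # collapse the 192-class draw to 12 classes for the simple model
  sub12 <- sub("^.\\[(.>.)\\].$", "\\1", sim191$class)
  agg <- function(col) as.numeric(tapply(sim191[[col]], sub12, sum)[
    opp12$class])
  obs12 <- data.frame(class = opp12$class, N_syn = agg("N_syn"),
                      N_mis = agg("N_mis"), N_non = agg("N_non"),
                      N_stoploss = agg("N_stoploss"))
  obs12[is.na(obs12)] <- 0
  fit12 <- fitDnds(obs12, opp12)
  fit192 <- fitDnds(sim191, opp192)
  expect_lt(abs(selectionWMis(fit12) - selectionWMis(fit192)), 0.2)
  ci <- selectionCI(fit12)
  expect_true(selectionWMis(fit192) > ci[1] &&
                selectionWMis(fit192) < ci[2])
})

test_that("profile CIs cover the true selection strength", {
  sim <- tinyGenome()
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  hits <- 0L; total <- 0L
  for (w in c(0.5, 1, 2)) {
    for (i in 1:10) {
      obs <- simulateSelectionCounts(opp, rates = 0.1, wMis = w,
                                     seed = 1000 * w + i)
      fit <- fitDnds(obs, opp)
      ci <- selectionCI(fit)
      total <- total + 1L
      if (!anyNA(ci) && ci[1] <= w && w <= ci[2]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.85)
})

test_that("unidentifiable or inconsistent inputs error out", {
  sim <- tinyGenome()
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = 12L)
  obs <- data.frame(class = opp$class, N_syn = 0, N_mis = 5,
                    N_non = 0, N_stoploss = 0)
  expect_error(fitDnds(obs, opp), "unidentifiable")
})

test_that("tRNA anticodon expectation is proportional to signature mass", {
  sim <- simulateReference(3000, seed = 81)
  ann <- sim$annotation
  trna <- ann[ann$feature == "tRNA", ]
  # uniform signature: expectation = count * anticodon share of tRNA bases
  uni <- computeSignature(
    data.frame(pos = integer(0), ref = character(0), alt = character(0)),
    sim$ref, nclass = 12L)
  uni@rates <- setNames(rep(1, 12), signatureClasses(12L))
  L <- length(sim$ref)
  trnaPos <- unique(unlist(lapply(seq_len(nrow(trna)), function(i)
    featurePositions(trna[i, ], L))))
  set.seed(82)
  pos <- sample(trnaPos, 100, replace = TRUE)
  b <- referenceBases(sim$ref)
  vars <- data.frame(pos = pos, ref = b[pos],
                     alt = vapply(b[pos], function(x)
                       setdiff(c("A", "C", "G", "T"), x)[1], character(1)))
  res <- trnaAnticodonTest(vars, sim$ref, ann, uni)
  acShare <- length(unique(unlist(lapply(trna$anticodon_start, function(s)
    ((s + 0:2 - 1) %% L) + 1)))) / length(trnaPos)
  expect_equal(res$expected, res$n_trna * acShare, tolerance = 1e-9)

  # zero tRNA mutations: expectation 0, p = 1
  none <- trnaAnticodonTest(vars[0, ], sim$ref, ann, uni)
  expect_equal(none$expected, 0)
  expect_equal(none$p.value, 1)

  # observed 0 with expectation around 7.6: small two-sided Poisson p
  vars2 <- vars[!vars$pos %in% unlist(lapply(trna$anticodon_start,
    function(s) ((s + 0:2 - 1) %% L) + 1)), ]
  res2 <- trnaAnticodonTest(vars2, sim$ref, ann, uni)
  expect_equal(res2$observed, 0)
  if (res2$expected > 5) expect_lt(res2$p.value, 0.05)
})

test_that("recurrence analysis matches the occupancy closed form", {
  sim <- simulateReference(1000, seed = 91)
  L <- length(sim$ref)
  set.seed(92)
  n <- 300
  pos <- sample.int(L, n, replace = TRUE)
  b <- referenceBases(sim$ref)
  vars <- data.frame(sample = paste0("S", seq_len(n)), pos = pos,
                     ref = b[pos], alt = "A")
  res <- recurrenceAnalysis(vars, sim$ref, nullModel = "uniform",
                            nSims = 2000, seed = 93)
  # occupancy statistics: E[non-singleton mutations] = n - n(1-1/L)^(n-1)
  closed <- n - n * (1 - 1 / L)^(n - 1)
  expect_lt(abs(res$expected - closed) / closed, 0.05)
  # uniformly placed variants show no enrichment
  expect_lt(res$fold_enrichment, 2)
  expect_gt(res$p.value, 0.01)

  # all-distinct variants: zero recurrence
  distinct <- data.frame(sample = paste0("S", 1:50), pos = 1:50,
                         ref = b[1:50], alt = "A")
  res0 <- recurrenceAnalysis(distinct, sim$ref, nSims = 200, seed = 94)
  expect_equal(res0$n_recurrent, 0)
  expect_equal(res0$fold_enrichment, 0)

  # a hotspot cohort is enriched vs the uniform null
  hot <- data.frame(sample = paste0("S", 1:60),
                    pos = rep(c(10L, 20L, 30L), each = 20),
                    ref = b[rep(c(10L, 20L, 30L), each = 20)], alt = "A")
  resH <- recurrenceAnalysis(hot, sim$ref, nSims = 500, seed = 95)
  expect_gt(resH$fold_enrichment, 3)
  expect_lt(resH$p.value, 0.01)
})

test_that("recurrence resampling separates real from null recurrence differences", {
  # identical groups drawn exhaustively: constant counts, no difference
  set.seed(96)
  g <- data.frame(pos = sample.int(100, 80, replace = TRUE))
  same <- recurrenceResample(list(a = g, b = g, c = g), nDraw = 80,
                             nIter = 20, seed = 1)
  expect_equal(same$anova_p, 1)
  expect_equal(dim(same$counts), c(20L, 3L))

  # exchangeable groups from one cohort are mostly non-significant, while
  # a genuinely hotspot-rich group is flagged
  mkGroup <- function(n, pool) data.frame(
    pos = sample.int(pool, n, replace = TRUE))
  nullP <- vapply(1:8, function(run) {
    set.seed(200 + run)
    recurrenceResample(list(a = mkGroup(400, 2000), b = mkGroup(400, 2000),
                            c = mkGroup(400, 2000)),
                       nDraw = 100, nIter = 50, seed = run)$anova_p
  }, numeric(1))
  expect_gte(mean(nullP > 0.01), 0.7)

  set.seed(300)
  hotP <- recurrenceResample(list(a = mkGroup(400, 2000),
                                  hot = mkGroup(400, 120)),
                             nDraw = 100, nIter = 50, seed = 2)$anova_p
  expect_lt(hotP, 1e-6)

  expect_error(recurrenceResample(list(a = mkGroup(50, 500),
                                       b = mkGroup(200, 500)),
                                  nDraw = 100), "smaller than nDraw")
})

test_that("VAF comparisons separate truncating from tolerated mutations", {
  set.seed(98)
  v <- data.frame(
    vaf = c(runif(200, 0, 1), runif(200, 0, 1), runif(200, 0, 0.3)),
    consequence = rep(c("missense", "silent", "nonsense"), each = 200))
  res <- vafSelectionTest(v)
  expect_lt(res$means[["nonsense"]], res$means[["missense"]])
  p <- res$pairwise$p.value[res$pairwise$group1 == "missense" &
                              res$pairwise$group2 == "nonsense" |
                              res$pairwise$group1 == "nonsense" &
                              res$pairwise$group2 == "missense"]
  expect_lt(p, 0.01)
  pSame <- res$pairwise$p.value[
    (res$pairwise$group1 == "missense" & res$pairwise$group2 == "silent") |
    (res$pairwise$group1 == "silent" & res$pairwise$group2 == "missense")]
  expect_gt(pSame, 0.05)

  # identical groups: p = 1
  same <- data.frame(vaf = rep(c(0.1, 0.4, 0.9), 2),
                     consequence = rep(c("a", "b"), each = 3))
  expect_equal(vafSelectionTest(same)$pairwise$p.value, 1)
})
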