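test_that("signature counting conserves totals and normalises by opportunity", {
  # toy circular sequence engineered to contain ACA contexts on the L strand
  ref <- MtReference("ACAGACATACAGACAT")  # ACA at 1,5,9,13 (L strand)
  expect_equal(sum(trinucleotideContext(ref, 1:16, "L") == "ACA"), 4)
  vars <- data.frame(pos = c(2L, 6L), ref = c("C", "C"), alt = c("T", "T"),
                     stringsAsFactors = FALSE)
  sig <- computeSignature(vars, ref, nclass = 192L)
  expect_equal(unname(sig@counts[["L:A[C>T]A"]]), 2)
  expect_equal(unname(sig@opportunities[["L:A[C>T]A"]]), 4)
  expect_equal(unname(sig@rates[["L:A[C>T]A"]]), 0.5)
  expect_equal(sum(sig@counts), nrow(vars))

  empty <- computeSignature(vars[0, ], ref)
  expect_equal(sum(empty@counts), 0)
  expect_true(all(empty@rates == 0))
})

test_that("variants outside the region are skipped with a message", {
  ref <- MtReference("ACAGACATACAGACAT")
  vars <- data.frame(pos = c(2L, 6L), ref = c("C", "C"), alt = c("T", "T"))
  expect_message(sig <- computeSignature(vars, ref, region = 1:4),
                 "outside region")
  expect_equal(sum(sig@counts), 1)
})

test_that("strand bias summary reproduces the fold identity", {
  sim <- simulateReference(3000, seed = 51)
  truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 100,
                          mutationRate = 10, seed = 52)
  sig <- computeSignature(truth$variants, sim$ref, nclass = 12L)
  sb <- strandBiasSummary(sig)
  for (i in seq_len(nrow(sb$by_class))) {
    row <- sb$by_class[i, ]
    if (is.na(row$rate_fold) || row$h_share %in% c(0, 1)) next
    expect_equal(row$rate_fold,
                 row$h_share / (1 - row$h_share) * row$comp_ratio,
                 tolerance = 1e-9)
  }
  expect_gt(sb$by_class$h_share[sb$by_class$sub == "C>T"], 0.8)
  expect_lt(sb$by_class$h_share[sb$by_class$sub == "T>C"], 0.3)
  expect_lt(sb$chisq$p.value, 1e-6)
})

test_that("the printed strand-bias arithmetic holds: share 0.841, composition 2.4 gives fold about 12.7", {
  # direct check of the identity linking mutation share, base composition
  # and the per-strand rate ratio
  hShare <- 0.841; comp <- 2.4
  fold <- hShare / (1 - hShare) * comp
  expect_equal(fold, 12.70, tolerance = 0.01)
})

test_that("symmetric counts and opportunities give fold 1", {
  ref <- MtReference(paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  # complement-symmetric sequence: equal C on both strands
  vars <- data.frame(pos = c(2L, 3L), ref = c("C", "G"), alt = c("T", "A"))
  sig <- computeSignature(vars, ref, nclass = 12L)
  sb <- strandBiasSummary(sig)
  row <- sb$by_class[sb$by_class$sub == "C>T", ]
  expect_equal(row$rate_fold, 1, tolerance = 1e-9)
})

test_that("recoding variants to the opposite strand inverts rate folds exactly", {
  sim <- simulateReference(2000, seed = 53)
  truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 60,
                          mutationRate = 8, seed = 54)
  v <- truth$variants
  sig <- computeSignature(v, sim$ref, nclass = 12L)
  sb <- strandBiasSummary(sig)$by_class
  # complement the reference: swaps which strand carries each pyrimidine
  refC <- MtReference(paste(unname(c(A = "T", C = "G", G = "C",
                                     T = "A")[referenceBases(sim$ref)]),
                            collapse = ""))
  vC <- data.frame(pos = v$pos,
                   ref = unname(c(A = "T", C = "G", G = "C", T = "A")[v$ref]),
                   alt = unname(c(A = "T", C = "G", G = "C", T = "A")[v$alt]))
  sbC <- strandBiasSummary(computeSignature(vC, refC, nclass = 12L))$by_class
  for (s in sb$sub) {
    f1 <- sb$rate_fold[sb$sub == s]
    f2 <- sbC$rate_fold[sbC$sub == s]
    if (is.na(f1) || is.na(f2) || f1 == 0) next
    expect_equal(f2, 1 / f1, tolerance = 1e-9)
  }
})

test_that("inside plus outside the origin segment equals the whole genome", {
  sim <- simulateReference(3000, seed = 55)
  truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 80,
                          mutationRate = 8, seed = 56)
  parts <- dloopSegmentSignature(truth$variants, sim$ref,
                                 oriB = sim$oriB, oH = sim$oH)
  whole <- computeSignature(truth$variants, sim$ref)
  expect_equal(parts$inside@counts + parts$outside@counts, whole@counts)
  expect_equal(parts$inside@opportunities + parts$outside@opportunities,
               whole@opportunities)
  # segment membership: wraps the origin
  expect_true(all(inOriSegment(c(sim$oriB, length(sim$ref), 1, sim$oH),
                               sim$oriB, sim$oH)))
  expect_false(inOriSegment(sim$oH + 50, sim$oriB, sim$oH))
  expect_error(dloopSegmentSignature(truth$variants, sim$ref,
                                     oriB = 2, oH = 1), "whole genome")
})

test_that("rCRS segment defaults place positions as printed", {
  expect_true(inOriSegment(16300, 16197, 191))
  expect_true(inOriSegment(16197, 16197, 191))
  expect_true(inOriSegment(191, 16197, 191))
  expect_false(inOriSegment(1000, 16197, 191))
})

test_that("large cohorts recover the generating rates (cosine >= 0.95)", {
  sim <- simulateReference(3000, seed = 57)
  truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 120,
                          mutationRate = 45, seed = 58)
  expect_gte(nrow(truth$variants), 5000)
  sig <- computeSignature(truth$variants, sim$ref, nclass = 192L)
  cs <- sum(sig@rates * truth$signature_rates) /
    sqrt(sum(sig@rates^2) * sum(truth$signature_rates^2))
  expect_gte(cs, 0.95)
})

test_that("the inverted origin segment is detected as strand-swapped", {
  sim <- simulateReference(3000, seed = 59)
  truth <- simulateCohort(sim$ref, sim$annotation, nSamples = 300,
                          mutationRate = 20, dloopInversion = TRUE,
                          oriB = sim$oriB, oH = sim$oH, seed = 60)
  parts <- dloopSegmentSignature(truth$variants, sim$ref,
                                 oriB = sim$oriB, oH = sim$oH)
  rIn <- parts$inside@rates
  rOut <- parts$outside@rates
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  direct <- cos(rIn, rOut)
  swapped <- cos(rIn, swapStrandLabels(rOut))
  expect_gt(swapped, direct)
  expect_gt(swapped, 0.8)
})

test_that("the strand-model comparison discriminates replication- from transcription-coupled cohorts", {
  # Strategy mirrors the field's test: build the background from genes
  # coded on the L strand (where the two labellings coincide) and score
  # the H-strand-coded gene subset under both labellings.
  sim <- simulateReference(3000, seed = 61)
  ann <- sim$annotation
  genes <- ann[ann$feature %in% c("protein", "tRNA", "rRNA"), ]
  L <- length(sim$ref)
  posOf <- function(rows) unique(unlist(lapply(
    which(rows), function(i) featurePositions(genes[i, ], L))))
  lPos <- posOf(genes$coding_strand == "L")
  hPos <- posOf(genes$coding_strand == "H")
  b <- referenceBases(sim$ref)

  scoreHGene <- function(variants) {
    background <- computeSignature(
      variants[variants$pos %in% lPos, ], sim$ref, region = lPos,
      nclass = 12L, regionLabel = "L genes")
    compareStrandModels(variants[variants$pos %in% hPos, ], sim$ref, ann,
                        background, region = hPos)
  }

  # replication-coupled cohort: classes follow the physical strand
  truthRep <- simulateCohort(sim$ref, ann, nSamples = 400,
                             mutationRate = 15, seed = 63)
  cmp <- scoreHGene(truthRep$variants)
  expect_equal(cmp$preferred, "replicative")

  # transcription-coupled cohort: mutated pyrimidine always on the coding
  # strand (C>T), mimicking transcription-linked damage
  strandOf <- rep(NA_character_, L)
  for (i in seq_len(nrow(genes)))
    strandOf[featurePositions(genes[i, ], L)] <- genes$coding_strand[i]
  genePos <- c(lPos, hPos)
  pyrStrand <- ifelse(b %in% c("C", "T"), "L", "H")
  codingPyr <- genePos[pyrStrand[genePos] == strandOf[genePos] &
                         b[genePos] %in% c("C", "G")]
  set.seed(64)
  pos <- unique(sample(codingPyr, 600, replace = TRUE))
  vTrans <- data.frame(pos = pos, ref = b[pos],
                       alt = ifelse(b[pos] == "C", "T", "A"),
                       stringsAsFactors = FALSE)
  cmp2 <- scoreHGene(vTrans)
  expect_lt(cmp2$transcriptional$statistic, cmp2$replicative$statistic)
})
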