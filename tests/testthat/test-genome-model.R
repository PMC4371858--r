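test_that("FASTA loading validates and round-trips", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">toy description", "acgtacgtaa"), fa)
  ref <- loadReference(fa)
  expect_s4_class(ref, "MtReference")
  expect_equal(length(ref), 10L)
  expect_equal(referenceName(ref), "toy")
  expect_equal(referenceBases(ref)[1:4], c("A", "C", "G", "T"))

  out <- tempfile(fileext = ".fa")
  writeReference(ref, out)
  expect_equal(as.character(loadReference(out)@sequence),
               as.character(ref@sequence))

  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(loadReference(empty), "no records|invalid")

  multi <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), multi)
  expect_error(loadReference(multi), "single")

  expect_error(MtReference("ACGU"), "A/C/G/T/N")
  expect_error(MtReference("AC"), "3 bp")
})

test_that("trinucleotide context wraps circularly and respects strand", {
  ref <- MtReference("ACGTA")
  expect_equal(trinucleotideContext(ref, 1, "L"), "AAC")
  expect_equal(trinucleotideContext(ref, 1, "H"), "GTT")
  expect_equal(trinucleotideContext(ref, 3, "L"), "CGT")
  expect_equal(trinucleotideContext(ref, 5, "L"), "TAA")
  expect_error(trinucleotideContext(ref, 6, "L"), "out of range")
})

test_that("H context is the reverse complement of the L context everywhere", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    ref <- MtReference(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = ""))
    pos <- seq_len(n)
    ctxL <- trinucleotideContext(ref, pos, "L")
    ctxH <- trinucleotideContext(ref, pos, "H")
    rc <- vapply(strsplit(ctxL, ""), function(x)
      paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[x])),
            collapse = ""), character(1))
    expect_equal(ctxH, rc)
  }
})

test_that("contexts are invariant under rotation of the circular sequence", {
  set.seed(7)
  n <- 80
  s <- sample(c("A", "C", "G", "T"), n, TRUE)
  shift <- 31
  rot <- c(s[(shift + 1):n], s[1:shift])
  refA <- MtReference(paste(s, collapse = ""))
  refB <- MtReference(paste(rot, collapse = ""))
  for (p in c(1, 5, 40, n)) {
    p2 <- ((p - shift - 1) %% n) + 1
    expect_equal(trinucleotideContext(refA, p, "L"),
                 trinucleotideContext(refB, p2, "L"))
  }
})

test_that("consequence annotation follows the vertebrate mitochondrial code", {
  # gene with codons ATG TGG CGA TAA on the L strand; circular padding
  ref <- MtReference(paste0("AAAA", "ATGTGGCGATAA", "AAAA"))
  ann <- data.frame(gene = "G1", start = 5, end = 16, coding_strand = "L",
                    feature = "protein", frame_offset = 0L,
                    anticodon_start = NA_integer_,
                    stringsAsFactors = FALSE)
  # TGG -> TGA: Trp -> Trp under the mito code, silent
  cq <- annotateConsequence(ref, ann, 10, "G", "A")
  expect_equal(cq$category, "silent")
  expect_equal(cq$codon_change, "TGG>TGA")
  # CGA -> AGA: Arg -> stop (AGA is a mitochondrial stop)
  cq <- annotateConsequence(ref, ann, 11, "C", "A")
  expect_equal(cq$category, "nonsense")
  # TAA -> CAA: stop lost
  cq <- annotateConsequence(ref, ann, 14, "T", "C")
  expect_equal(cq$category, "stop_lost")
  # outside any feature
  cq <- annotateConsequence(ref, ann, 2, "A", "G")
  expect_equal(cq$category, "intergenic")
  # indels
  expect_equal(annotateConsequence(ref, ann, 7, "G", "GA")$category,
               "frameshift")
  expect_equal(annotateConsequence(ref, ann, 7, "GTGG", "G")$category,
               "inframe_indel")
})

test_that("tRNA annotation flags anticodon hits only inside the span", {
  sim <- tinyGenome()
  trna <- sim$annotation[sim$annotation$feature == "tRNA" &
                           sim$annotation$coding_strand == "L", ][1, ]
  acStart <- trna$anticodon_start
  refb <- referenceBases(sim$ref)
  inHit <- annotateConsequence(sim$ref, sim$annotation, acStart + 1,
                               refb[acStart + 1], setdiff(c("A", "C"),
                                                          refb[acStart + 1])[1])
  row <- inHit[inHit$gene == trna$gene, ]
  expect_equal(row$category, "tRNA")
  expect_true(row$anticodon_hit)
  outPos <- trna$start
  outHit <- annotateConsequence(sim$ref, sim$annotation, outPos,
                                refb[outPos], setdiff(c("A", "C"),
                                                      refb[outPos])[1])
  row <- outHit[outHit$gene == trna$gene, ]
  expect_false(row$anticodon_hit)
})

test_that("classifying every change in a gene matches brute-force enumeration", {
  sim <- tinyGenome()
  for (g in which(sim$annotation$feature == "protein")) {
    f <- sim$annotation[g, ]
    oracle <- bruteForceConsequences(sim$ref, f)
    pos <- featurePositions(f, length(sim$ref))
    b <- referenceBases(sim$ref)
    got <- character(0)
    for (p in pos) {
      for (a in setdiff(c("A", "C", "G", "T"), b[p])) {
        cq <- annotateConsequence(sim$ref, sim$annotation, p, b[p], a)
        got <- c(got, cq$category[cq$gene == f$gene])
      }
    }
    gotTab <- table(got)
    expect_equal(sum(gotTab), 3 * length(pos))
    for (cat in names(oracle))
      expect_equal(unname(gotTab[[cat]]), unname(oracle[[cat]]),
                   label = paste(f$gene, cat))
  }
})

test_that("annotation reader validates schema and round-trips", {
  sim <- tinyGenome()
  path <- tempfile(fileext = ".tsv")
  writeGeneAnnotation(sim$annotation, path)
  back <- readGeneAnnotation(path)
  expect_equal(back$gene, sim$annotation$gene)
  expect_equal(back$start, sim$annotation$start)

  bad <- sim$annotation
  bad$feature[1] <- "exon"
  badPath <- tempfile(fileext = ".tsv")
  write.table(bad, badPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGeneAnnotation(badPath), "unknown feature")
})

test_that("variant tables round-trip through TSV and VCF", {
  v <- data.frame(sample = c("S1", "S2"), pos = c(10L, 20L),
                  ref = c("C", "T"), alt = c("T", "C"),
                  vaf = c(0.25, 0.9),
                  consequence = c("missense", "silent"),
                  gene = c("G1", NA),
                  filters_failed = c("", "blacklist,min_vaf"),
                  stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  writeVariantsTsv(v, tsv)
  expect_equal(readVariantsTsv(tsv)$pos, v$pos)

  vcf <- tempfile(fileext = ".vcf")
  writeVariantsVcf(v, vcf,
                   ref = MtReference(strrep("ACGTT", 6), name = "chrM"))
  back <- readVariantsVcf(vcf)
  expect_equal(back$pos, v$pos)
  expect_equal(back$alt, v$alt)
  expect_equal(back$vaf, v$vaf, tolerance = 1e-6)
  expect_equal(back$filters_failed, c("", "blacklist,min_vaf"))
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
})
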