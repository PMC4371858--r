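#' Load a circular mitochondrial reference from FASTA
#'
#' Reads a single-record FASTA file, uppercases the sequence and returns it
#' as a circular \linkS4class{MtReference}. The stored sequence is taken to
#' be the light (L) strand, the mtDNA community convention.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return An \linkS4class{MtReference}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGTAA"), fa)
#' loadReference(fa)
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop_data("invalid FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop_data("FASTA contains no records: ", path)
  if (length(set) > 1L)
    stop_data("expected a single FASTA record, found ", length(set))
  nm <- sub("\\s.*$", "", names(set)[1])
  MtReference(as.character(set[[1]]), name = nm)
}

#' Write an MtReference to FASTA
#'
#' @param ref An \linkS4class{MtReference}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeReference <- function(ref, path) {
  set <- Biostrings::DNAStringSet(as.character(ref@sequence))
  names(set) <- referenceName(ref)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Trinucleotide context at a position, on either strand
#'
#' Returns the base at \code{position} with its immediate 5' and 3'
#' neighbours. Neighbours wrap around the circular genome. For the H strand
#' the returned context is the reverse complement of the L-strand context,
#' so it reads 5' to 3' on the H strand.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param position 1-based position(s).
#' @param strand \code{"L"} or \code{"H"}.
#' @return Character vector of 3-letter contexts.
#' @examples
#' ref <- MtReference("ACGTA")
#' trinucleotideContext(ref, 1, "L")  # "AAC": 5' neighbour wraps
#' trinucleotideContext(ref, 1, "H")  # "GTT"
#' @export
trinucleotideContext <- function(ref, position, strand = c("L", "H")) {
  strand <- match.arg(strand)
  L <- length(ref)
  position <- as.integer(position)
  if (any(position < 1L | position > L))
    stop_data("position out of range 1..", L)
  b <- referenceBases(ref)
  ctx <- paste0(b[circ_index(position - 1L, L)], b[position],
                b[circ_index(position + 1L, L)])
  if (strand == "H") ctx <- revcomp(ctx)
  ctx
}

# ---- gene annotation ---------------------------------------------------

ANN_FEATURES <- c("protein", "tRNA", "rRNA", "dloop", "intergenic")

#' Read a gene annotation table
#'
#' Tab-separated file with columns \code{gene}, \code{start}, \code{end},
#' \code{coding_strand} (\code{L} or \code{H}: the strand whose sequence
#' equals the mRNA sense), \code{feature} (\code{protein}, \code{tRNA},
#' \code{rRNA}, \code{dloop}, \code{intergenic}), and optionally
#' \code{frame_offset} (default 0) and \code{anticodon_start} (genomic
#' position of the first of the 3 anticodon bases, tRNAs only; \code{NA}
#' otherwise). Coordinates are 1-based inclusive; features with
#' \code{end < start} wrap the origin circularly.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} (one row per feature).
#' @export
readGeneAnnotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  validateAnnotation(ann)
}

#' @rdname readGeneAnnotation
#' @param ann Annotation \code{data.frame}.
#' @export
writeGeneAnnotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateAnnotation <- function(ann) {
  need <- c("gene", "start", "end", "coding_strand", "feature")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_data("annotation missing columns: ", paste(miss, collapse = ", "))
  if (is.null(ann$frame_offset)) ann$frame_offset <- 0L
  if (is.null(ann$anticodon_start)) ann$anticodon_start <- NA_integer_
  if (!all(ann$feature %in% ANN_FEATURES))
    stop_data("unknown feature type(s): ",
              paste(setdiff(ann$feature, ANN_FEATURES), collapse = ", "))
  if (!all(ann$coding_strand %in% c("L", "H")))
    stop_data("coding_strand must be 'L' or 'H'")
  ann
}

#' Genomic positions covered by a feature, in coding order
#'
#' Positions run 5' to 3' along the coding strand: for an L-strand gene
#' they ascend (wrapping the origin when \code{end < start}); for an
#' H-strand gene the same interval is returned reversed, since the H-strand
#' sense runs against L-strand coordinates.
#'
#' @param feature One row of an annotation \code{data.frame}.
#' @param genomeLength Total genome length.
#' @return Integer vector of genomic positions.
#' @export
featurePositions <- function(feature, genomeLength) {
  s <- as.integer(feature$start); e <- as.integer(feature$end)
  pos <- if (e >= s) s:e else c(s:genomeLength, 1:e)
  if (identical(feature$coding_strand, "H")) pos <- rev(pos)
  pos
}

#' Coding-strand sequence of a feature
#'
#' @param ref An \linkS4class{MtReference}.
#' @param feature One annotation row.
#' @return Character scalar: the feature sequence read 5' to 3' on its
#'   coding strand (complemented for H-strand features).
#' @export
featureSequence <- function(ref, feature) {
  pos <- featurePositions(feature, length(ref))
  b <- referenceBases(ref)[pos]
  if (identical(feature$coding_strand, "H")) b <- comp_base(b)
  paste(b, collapse = "")
}

# positions (circular) covered by a feature, unordered membership test
featureContains <- function(feature, position, genomeLength) {
  s <- as.integer(feature$start); e <- as.integer(feature$end)
  if (e >= s) position >= s & position <= e
  else position >= s | position <= e
}

CONSEQ_SEVERITY <- c(nonsense = 1, stop_lost = 2, frameshift = 3,
                     missense = 4, inframe_indel = 5, silent = 6,
                     tRNA = 7, rRNA = 8, intergenic = 9)

#' Annotate the consequence of a variant
#'
#' Classifies a substitution or indel against every containing feature.
#' Protein-coding changes are translated with the vertebrate mitochondrial
#' genetic code (NCBI table 2: TGA = Trp, ATA = Met, AGA/AGG = stop) on the
#' coding strand of the gene. Variants inside overlapping genes get one row
#' per gene; \code{\link{worstConsequence}} picks the most severe.
#'
#' @param ref An \linkS4class{MtReference}.
#' @param ann Annotation \code{data.frame} (see
#'   \code{\link{readGeneAnnotation}}).
#' @param position 1-based variant position.
#' @param refAllele,altAllele Alleles as strings. Unequal lengths are
#'   treated as an indel (frameshift when the length difference is not a
#'   multiple of 3).
#' @return A \code{data.frame} with columns \code{category}, \code{gene},
#'   \code{codon_change}, \code{anticodon_hit}; one row per containing
#'   feature, or a single \code{intergenic} row.
#' @export
annotateConsequence <- function(ref, ann, position, refAllele, altAllele) {
  ann <- validateAnnotation(ann)
  position <- as.integer(position)
  L <- length(ref)
  if (position < 1L || position > L) stop_data("position out of range")
  if (!grepl("^[ACGTN]+$", refAllele) || !grepl("^[ACGTN]+$", altAllele))
    stop_data("alleles must be nucleotide strings")
  hit <- which(vapply(seq_len(nrow(ann)), function(i)
    featureContains(ann[i, ], position, L), logical(1)))
  is_indel <- nchar(refAllele) != nchar(altAllele)
  if (length(hit) == 0L) {
    return(data.frame(category = if (is_indel) "intergenic" else "intergenic",
                      gene = NA_character_, codon_change = NA_character_,
                      anticodon_hit = FALSE, stringsAsFactors = FALSE))
  }
  rows <- lapply(hit, function(i) {
    f <- ann[i, ]
    anticodon_hit <- FALSE
    if (identical(f$feature, "tRNA") && !is.na(f$anticodon_start)) {
      span <- circ_index(f$anticodon_start + 0:2, L)
      anticodon_hit <- position %in% span
    }
    if (!identical(f$feature, "protein")) {
      cat_ <- switch(f$feature, tRNA = "tRNA", rRNA = "rRNA", "intergenic")
      return(data.frame(category = cat_, gene = f$gene,
                        codon_change = NA_character_,
                        anticodon_hit = anticodon_hit,
                        stringsAsFactors = FALSE))
    }
    if (is_indel) {
      cat_ <- if ((abs(nchar(refAllele) - nchar(altAllele)) %% 3L) != 0L)
        "frameshift" else "inframe_indel"
      return(data.frame(category = cat_, gene = f$gene,
                        codon_change = NA_character_, anticodon_hit = FALSE,
                        stringsAsFactors = FALSE))
    }
    cc <- codonChange(ref, f, position, altAllele)
    data.frame(category = cc$category, gene = f$gene,
               codon_change = cc$codon_change, anticodon_hit = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# single-base substitution inside one protein feature
codonChange <- function(ref, feature, position, altAllele) {
  L <- length(ref)
  pos <- featurePositions(feature, L)
  off <- as.integer(feature$frame_offset %||% 0L)
  idx <- match(position, pos)
  cds_idx <- idx - off
  if (is.na(idx) || cds_idx < 1L)
    return(list(category = "intergenic", codon_change = NA_character_))
  codon_i <- ((cds_idx - 1L) %/% 3L)
  within <- ((cds_idx - 1L) %% 3L) + 1L
  codon_pos <- pos[off + codon_i * 3L + 1:3]
  if (anyNA(codon_pos))  # trailing partial codon
    return(list(category = "intergenic", codon_change = NA_character_))
  b <- referenceBases(ref)[codon_pos]
  alt <- altAllele
  if (identical(feature$coding_strand, "H")) {
    b <- comp_base(b)
    alt <- comp_base(alt)
  }
  codon_ref <- paste(b, collapse = "")
  b[within] <- alt
  codon_alt <- paste(b, collapse = "")
  aa_ref <- translate_codons(codon_ref)
  aa_alt <- translate_codons(codon_alt)
  category <-
    if (aa_ref == aa_alt) "silent"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  list(category = category,
       codon_change = paste0(codon_ref, ">", codon_alt))
}

#' Most severe consequence of a multi-gene annotation
#'
#' @param conseq Output of \code{\link{annotateConsequence}}.
#' @return Single row of \code{conseq} with the most severe category
#'   (nonsense > stop_lost > frameshift > missense > inframe_indel >
#'   silent > tRNA > rRNA > intergenic).
#' @export
worstConsequence <- function(conseq) {
  conseq[which.min(CONSEQ_SEVERITY[conseq$category]), , drop = FALSE]
}

# ---- variant table I/O -------------------------------------------------

#' Read and write somatic variant tables
#'
#' Variants travel as a \code{data.frame} with at least \code{sample},
#' \code{pos}, \code{ref}, \code{alt}, and optionally \code{vaf},
#' \code{consequence}, \code{gene}, \code{filters_failed},
#' \code{rescue_tags}. \code{writeVariantsVcf} emits a minimal VCF v4.2
#' with INFO keys \code{VAF}, \code{CONSEQ}, \code{GENE} and the failed
#' filters in FILTER; \code{readVariantsVcf} reads that dialect back.
#'
#' @param path File path.
#' @param variants Variant \code{data.frame}.
#' @param ref Optional \linkS4class{MtReference} used for the VCF header.
#' @return \code{readVariantsTsv}/\code{readVariantsVcf} return a
#'   \code{data.frame}; writers return \code{path} invisibly.
#' @export
readVariantsTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readVariantsTsv
#' @export
writeVariantsTsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readVariantsTsv
#' @export
writeVariantsVcf <- function(variants, path, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
    if (!is.null(ref))
      paste0("##contig=<ID=", referenceName(ref), ",length=", length(ref), ">"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence category\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  chrom <- if (!is.null(ref)) referenceName(ref) else "MT"
  filt <- variants$filters_failed %||% rep("", nrow(variants))
  filt <- ifelse(is.na(filt) | filt == "", "PASS", gsub(",", ";", filt))
  info <- paste0(
    "VAF=", signif(variants$vaf %||% rep(NA_real_, nrow(variants)), 6),
    ";CONSEQ=", variants$consequence %||% rep(".", nrow(variants)),
    ";GENE=", ifelse(is.na(variants$gene %||% rep(NA, nrow(variants))), ".",
                     variants$gene %||% rep(".", nrow(variants))),
    ";SAMPLE=", variants$sample %||% rep(".", nrow(variants)))
  body <- paste(chrom, variants$pos, ".", variants$ref, variants$alt, ".",
                filt, info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname readVariantsTsv
#' @export
readVariantsVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_data("VariantAnnotation is required to read VCF")
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L)
    return(data.frame(sample = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vaf = numeric(), stringsAsFactors = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  asChr <- function(x) {
    if (is.null(x)) return(rep(NA_character_, n))
    vapply(as.list(x), function(v)
      if (length(v) && as.character(v)[1] != ".") as.character(v)[1]
      else NA_character_, character(1))
  }
  filt <- as.character(rr$FILTER)
  data.frame(
    sample = asChr(info$SAMPLE),
    pos = as.integer(GenomicRanges::start(rr)),
    ref = as.character(rr$REF),
    alt = vapply(seq_len(n), function(i)
      as.character(rr$ALT[[i]])[1], character(1)),
    vaf = as.numeric(info$VAF),
    consequence = asChr(info$CONSEQ),
    gene = asChr(info$GENE),
    filters_failed = ifelse(filt %in% c("PASS", "."), "",
                            gsub(";", ",", filt)),
    stringsAsFactors = FALSE)
}
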