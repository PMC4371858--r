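# End-to-end orchestration: synthetic data (or user inputs) -> QC ->
# somatic calling -> signature -> selection, with per-stage outputs, a
# machine-readable summary, and per-filter count reconciliation.

#' Default pipeline configuration
#'
#' All thresholds of the filter chain and QC are surfaced here with their
#' standard values: minimum VAF 0.03, minimum 4 variant reads at Q20,
#' swap-rate threshold 0.1, 5x contamination VAF floor with a 0.10
#' fallback, and the 13-site blacklist enabled.
#'
#' @return Named list of configuration entries.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    # synthetic stage
    synthetic = TRUE,
    genome_length = 3000L,
    n_samples = 20L,
    mutation_rate = 5,
    depth = 1000,
    error_rate = 0.001,
    contamination = 0,
    # QC
    swap_rate_threshold = 0.1,
    contamination_error_rate = 0.001,
    floor_factor = 5,
    # calling (see callingDefaults)
    min_vaf = 0.03, min_reads = 4L, rescue_reads = 3L, rescue_vaf = 0.20,
    strand_max = 0.90, strand_bias_diff = 0.1, normal_max_vaf = 0.01,
    fallback_floor = 0.10, blacklist = TRUE,
    # signature / selection
    nclass = 192L,
    fit_w_non = FALSE)
}

#' Read a key=value pipeline configuration file
#'
#' Plain-text lines of the form \code{key = value}; \code{#} starts a
#' comment. Values are parsed as logical, numeric, or string. Unknown keys
#' are an error; missing keys take defaults from
#' \code{\link{defaultPipelineConfig}}.
#'
#' @param path Path to the configuration file.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  defaults <- defaultPipelineConfig()
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  cfg <- defaults
  for (l in ln) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_data("bad config line: ", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults))
      stop_data("unknown configuration key: ", key)
    parsed <- if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else if (grepl("^-?[0-9.eE+-]+$", val)) as.numeric(val)
      else val
    cfg[[key]] <- parsed
  }
  cfg
}

#' Run the analysis pipeline end-to-end
#'
#' With \code{synthetic = TRUE}, generates a reference, cohort and
#' pileups, then runs QC (swap check, contamination estimate), the
#' somatic filter chain, signature extraction, strand-bias summary and
#' the dN/dS fit. Writes per-stage TSVs, a variants VCF and a JSON
#' summary to \code{outdir} when set. Fully deterministic given
#' \code{seed}.
#'
#' @param config Configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path to a config file.
#' @return List with per-stage results: \code{truth}, \code{qc},
#'   \code{calls}, \code{filter_counts}, \code{signature},
#'   \code{strand_bias}, \code{selection}, \code{summary}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  defaults <- defaultPipelineConfig()
  missing_keys <- setdiff(setdiff(names(defaults), "outdir"),
                          names(config))
  if (length(missing_keys))
    stop_data("configuration missing fields: ",
              paste(missing_keys, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  if (!isTRUE(cfg$synthetic))
    stop_data("external-input mode requires pileup paths; enable the ",
              "synthetic stage or call the stage functions directly")
  seed <- as.integer(cfg$seed)

  sim <- simulateReference(length = cfg$genome_length, seed = seed)
  truth <- simulateCohort(sim$ref, sim$annotation,
                          nSamples = cfg$n_samples,
                          mutationRate = cfg$mutation_rate,
                          contamination = cfg$contamination,
                          seed = seed + 1L)
  piles <- simulatePileups(truth, depth = cfg$depth,
                           errorRate = cfg$error_rate, seed = seed + 2L)

  # QC: swap check on a matched panel, contamination per sample
  panel <- simulateGenotypePanel(swapped = FALSE, seed = seed + 3L)
  swap <- genotypeMismatchRate(panel[["N_hom"]], panel[["N_het"]],
                               panel[["N_wt"]],
                               threshold = cfg$swap_rate_threshold)
  samples <- unique(piles$tumor$sample)
  floors <- vapply(seq_along(samples), function(i) {
    hs <- simulateHomSites(contamination = truth$contamination[
      min(i, length(truth$contamination))],
      errorRate = cfg$contamination_error_rate, seed = seed + 10L + i)
    estimateContamination(hs, errorRate = cfg$contamination_error_rate,
                          floorFactor = cfg$floor_factor)$vaf_floor
  }, numeric(1))
  names(floors) <- samples

  params <- callingDefaults()
  for (k in names(params)) if (!is.null(cfg[[k]])) params[[k]] <- cfg[[k]]
  calls <- callSomatic(piles$tumor, piles$normal, vafFloor = floors,
                       blacklist = if (isTRUE(cfg$blacklist))
                         defaultBlacklist() else NULL,
                       params = params, keepFiltered = TRUE)
  passed <- calls[calls$filters_failed == "", , drop = FALSE]
  filter_counts <- filterReconciliation(calls)

  sig <- computeSignature(passed, sim$ref, nclass = cfg$nclass)
  sig12 <- computeSignature(passed, sim$ref, nclass = 12L)
  bias <- strandBiasSummary(sig12)

  passed$consequence <- vapply(seq_len(nrow(passed)), function(i) {
    worstConsequence(annotateConsequence(sim$ref, sim$annotation,
                                         passed$pos[i], passed$ref[i],
                                         passed$alt[i]))$category
  }, character(1))
  opp <- opportunityCounts(sim$ref, sim$annotation, nclass = cfg$nclass)
  obsc <- observedCounts(passed, sim$ref, sim$annotation,
                         nclass = cfg$nclass)
  fit <- tryCatch(
    fitDnds(obsc, opp, fitWNon = isTRUE(cfg$fit_w_non), seed = seed),
    error = function(e) e)

  summary <- list(
    seed = seed,
    n_true_variants = nrow(truth$variants),
    n_candidates = nrow(calls),
    n_called = nrow(passed),
    swap_rate = swap$rate,
    swap_flag = swap$swap_flag,
    vaf_floors = as.list(floors),
    filter_counts = as.list(filter_counts),
    signature_cosine_vs_truth = if (nrow(passed) > 0)
      cosine_similarity(sig@rates, truth$signature_rates /
                          sum(truth$signature_rates)) else NA_real_,
    w_mis = if (is(fit, "SelectionFit")) fit@wMis else NA_real_)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    writeVariantsTsv(passed, file.path(cfg$outdir, "calls.tsv"))
    writeVariantsVcf(calls, file.path(cfg$outdir, "calls.vcf"),
                     ref = sim$ref)
    writeSignatureTsv(sig, file.path(cfg$outdir, "signature.tsv"))
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(truth = truth, qc = list(swap = swap, vaf_floors = floors),
       calls = calls, passed = passed, filter_counts = filter_counts,
       signature = sig, strand_bias = bias, selection = fit,
       summary = summary)
}

#' Reconcile per-filter failure counts
#'
#' Every candidate is either passed or attributed to each filter it
#' failed: \code{n_candidates = n_passed + |union of failures|}, with
#' multi-failures counted under every failed rule.
#'
#' @param calls Output of \code{\link{callSomatic}} with
#'   \code{keepFiltered = TRUE}.
#' @return Named integer vector: \code{candidates}, \code{passed}, then
#'   one entry per filter rule.
#' @export
filterReconciliation <- function(calls) {
  failed <- strsplit(calls$filters_failed, ",", fixed = TRUE)
  rules <- sort(unique(unlist(failed)))
  rules <- rules[nzchar(rules)]
  out <- c(candidates = nrow(calls),
           passed = sum(calls$filters_failed == ""))
  for (r in rules)
    out[[r]] <- sum(vapply(failed, function(f) r %in% f, logical(1)))
  out
}
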