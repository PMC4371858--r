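# Wright-Fisher drift of mitochondrial genomes within a cell: a fixed
# population of M genome copies, binomial resampling each cell generation,
# absorbing boundaries at X = 0 (loss) and X = M (homoplasmy), and new
# mutations entering on single genome copies at rate mu per bp per
# division. Sites segregate independently (the marginal single-site
# model).

#' Simulate Wright-Fisher drift of mtDNA mutations in a cell
#'
#' Each replicate follows a cell lineage for \code{T} generations. Every
#' generation, each segregating site's mutant copy number is resampled as
#' Binomial(M, X/M); new mutations arise as Poisson(mu * L * M) events,
#' each starting at X = 1 on one genome copy (one site per mutation;
#' multiple hits at a site are not modelled). Absorption at 0 or M is
#' permanent.
#'
#' @param M Mitochondrial genome copies per cell (fixed population size).
#' @param mu Mutation rate per base pair per cell division.
#' @param L Genome length in bp.
#' @param T Number of cell generations.
#' @param reps Monte-Carlo replicates.
#' @param initX Integer vector of initial mutant copy numbers for alleles
#'   present at generation 0 (tracked separately from new mutations).
#' @param seed RNG seed.
#' @return List of class \code{DriftResult}: \code{n_homoplasmic}
#'   (per-replicate count of new mutations fixed at M by generation T),
#'   \code{n_segregating} (heteroplasmic sites at T),
#'   \code{init_fixed} (replicate x initial-allele logical matrix),
#'   \code{init_fix_time} (generation of fixation, NA if lost or still
#'   segregating) and the parameters.
#' @export
wfSimulate <- function(M, mu = 0, L = 1L, T = 100L, reps = 100L,
                       initX = integer(0), seed = 1L) {
  stopifnot(M >= 1, mu >= 0, mu <= 1, L >= 1, T >= 0, reps >= 1)
  initX <- as.integer(initX)
  if (any(initX < 0 | initX > M)) stop_data("initX must lie in [0, M]")
  with_seed(seed, {
    n_hom <- integer(reps)
    n_seg <- integer(reps)
    init_fixed <- matrix(FALSE, reps, length(initX))
    init_time <- matrix(NA_real_, reps, length(initX))
    for (r in seq_len(reps)) {
      X <- initX
      isInit <- rep(TRUE, length(initX))
      initIdx <- seq_along(initX)
      for (g in seq_len(T)) {
        nNew <- rpois(1L, mu * L * M)
        if (nNew > 0) {
          X <- c(X, rep(1L, nNew))
          isInit <- c(isInit, rep(FALSE, nNew))
          initIdx <- c(initIdx, rep(NA_integer_, nNew))
        }
        seg <- X > 0L & X < M
        if (any(seg)) X[seg] <- rbinom(sum(seg), M, X[seg] / M)
        just_fixed <- which(seg & X == M & isInit)
        if (length(just_fixed))
          init_time[r, initIdx[just_fixed]] <- g
        # drop lost non-tracked sites to keep the state small
        drop <- X == 0L & !isInit
        if (any(drop)) {
          X <- X[!drop]; isInit <- isInit[!drop]; initIdx <- initIdx[!drop]
        }
      }
      n_hom[r] <- sum(X == M & !isInit)
      n_seg[r] <- sum(X > 0L & X < M)
      if (length(initX))
        init_fixed[r, ] <- vapply(seq_along(initX), function(i) {
          j <- which(initIdx == i)
          length(j) == 1 && X[j] == M
        }, logical(1))
    }
    structure(list(n_homoplasmic = n_hom, n_segregating = n_seg,
                   init_fixed = init_fixed, init_fix_time = init_time,
                   M = M, mu = mu, L = L, T = T, reps = reps, seed = seed),
              class = "DriftResult")
  })
}

#' @export
print.DriftResult <- function(x, ...) {
  cat("DriftResult: M =", x$M, ", mu =", x$mu, ", L =", x$L,
      ", T =", x$T, ",", x$reps, "replicates\n")
  cat("  mean homoplasmic new mutations:", mean(x$n_homoplasmic), "\n")
  if (ncol(x$init_fixed))
    cat("  fixation fraction of tracked alleles:",
        mean(x$init_fixed), "\n")
  invisible(x)
}

#' Expected number of homoplasmic mutations after T generations
#'
#' Closed-form approximation \eqn{E[N] = \mu L (T - 2M)}: neutral
#' mutations accumulate at rate \eqn{\mu L} per generation and need about
#' 2M generations to drift to fixation, delaying the onset of
#' accumulation. Returns 0 (with a warning) when \code{T < 2M}, where the
#' delayed-accumulation approximation has not started.
#'
#' @param mu Mutation rate per bp per cell division.
#' @param L Genome length in bp.
#' @param T Cell generations.
#' @param M Mitochondrial genome copies per cell.
#' @return Expected homoplasmic mutation count.
#' @examples
#' expectedHomoplasmic(1e-7, 16569, 1000, 100)  # 1.3255
#' @export
expectedHomoplasmic <- function(mu, L, T, M) {
  if (mu < 0 || L < 0 || T < 0 || M < 0) stop_data("negative input")
  if (T < 2 * M) {
    warning("T < 2M: before the fixation delay has elapsed; returning 0")
    return(0)
  }
  mu * L * (T - 2 * M)
}

#' Monte-Carlo check of the conditional fixation time
#'
#' Simulates new mutants (one copy among M) to absorption and reports the
#' mean absorption-at-M time conditioned on fixation, which for the
#' Wright-Fisher process is approximately 2M generations.
#'
#' @param M Population size (>= 2); with M = 1 every mutation is
#'   instantly homoplasmic (time 0).
#' @param reps Replicates.
#' @param seed RNG seed.
#' @param maxGenerations Safety cap on each trajectory.
#' @return List with \code{mean_time}, \code{se}, \code{n_fixed},
#'   \code{reference} (= 2M).
#' @export
fixationTimeCheck <- function(M, reps = 10000L, seed = 1L,
                              maxGenerations = NULL) {
  stopifnot(M >= 1, reps >= 1)
  if (M == 1)
    return(list(mean_time = 0, se = 0, n_fixed = reps, reference = 2))
  if (is.null(maxGenerations)) maxGenerations <- 200L * M
  with_seed(seed, {
    X <- rep(1L, reps)
    t_fix <- rep(NA_real_, reps)
    active <- seq_len(reps)
    for (g in seq_len(maxGenerations)) {
      X[active] <- rbinom(length(active), M, X[active] / M)
      fixed <- active[X[active] == M]
      if (length(fixed)) t_fix[fixed] <- g
      active <- active[X[active] > 0L & X[active] < M]
      if (!length(active)) break
    }
    times <- t_fix[!is.na(t_fix)]
    if (!length(times)) {
      warning("no fixation events; increase reps")
      return(list(mean_time = NA_real_, se = NA_real_, n_fixed = 0L,
                  reference = 2 * M))
    }
    list(mean_time = mean(times), se = sd(times) / sqrt(length(times)),
         n_fixed = length(times), reference = 2 * M)
  })
}

#' Fixation fraction of an allele starting at X0 copies
#'
#' Under neutral drift the fixation probability is the starting frequency,
#' rho = X0/M. Simulates to absorption and reports the fixed fraction
#' with its Monte-Carlo standard error.
#'
#' @param M Population size.
#' @param X0 Initial mutant copies.
#' @param reps Replicates.
#' @param seed RNG seed.
#' @return List with \code{fraction}, \code{se}, \code{expected}
#'   (= X0/M).
#' @export
fixationFraction <- function(M, X0, reps = 10000L, seed = 1L) {
  stopifnot(M >= 1, X0 >= 0, X0 <= M)
  with_seed(seed, {
    X <- rep(as.integer(X0), reps)
    active <- which(X > 0L & X < M)
    while (length(active)) {
      X[active] <- rbinom(length(active), M, X[active] / M)
      active <- active[X[active] > 0L & X[active] < M]
    }
    frac <- mean(X == M)
    list(fraction = frac, se = sqrt(frac * (1 - frac) / reps),
         expected = X0 / M)
  })
}
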