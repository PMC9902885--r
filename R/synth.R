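#' Build a simulation configuration
#'
#' Convenience constructor for [SimulationConfig-class]. `rg` may be given
#' as a full T x T matrix or as a single scalar applied to every off-diagonal
#' pair; `crossIntercept` likewise. Scalar `sampleSizes`, `h2`, and
#' `interceptA` are recycled across traits.
#'
#' Defaults mirror a small LDSC-style study: LD scores are 1 plus a
#' gamma(shape = 2, scale = 20) draw (mean 41, long right tail, as reference
#' panel LD scores are), minor-allele frequencies uniform on [0.01, 0.5], 2%
#' of SNPs inside the MHC stand-in window and 5% withheld from the
#' include-list so the QC filters always have work to do.
#'
#' @param nTraits number of traits T.
#' @param nSnps number of SNPs M.
#' @param sampleSizes per-trait sample sizes (recycled).
#' @param h2 per-trait SNP heritabilities in [0, 1] (recycled).
#' @param rg genetic correlation matrix, or a scalar off-diagonal value.
#' @param interceptA per-trait confounding inflation a_t; the LDSC intercept
#'   of trait t is 1 + a_t.
#' @param crossIntercept sample-overlap cross-intercept matrix, or a scalar
#'   applied off-diagonal.
#' @param ldscoreShape,ldscoreScale gamma parameters of l_j - 1.
#' @param mafRange simulated MAF range.
#' @param mhcFrac fraction of SNPs placed in the MHC stand-in region.
#' @param includeDropFrac fraction of SNPs withheld from the include-list.
#' @param seed integer seed for all simulator randomness.
#' @param labels trait names (default trait1..traitT).
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nTraits = 3, nSnps = 1000, sampleSizes = 20000,
#'                  h2 = 0.4, rg = 0.5)
#' cfg
#' @export
simConfig <- function(nTraits, nSnps, sampleSizes, h2, rg = 0,
                      interceptA = 0, crossIntercept = 0,
                      ldscoreShape = 2, ldscoreScale = 20,
                      mafRange = c(0.01, 0.5), mhcFrac = 0.02,
                      includeDropFrac = 0.05, seed = 1L,
                      labels = paste0("trait", seq_len(nTraits))) {
  T <- as.integer(nTraits)
  if (is.null(dim(rg))) {
    stopifnot(length(rg) == 1)
    rgM <- matrix(rg, T, T)
    diag(rgM) <- 1
  } else rgM <- as.matrix(rg)
  if (is.null(dim(crossIntercept))) {
    stopifnot(length(crossIntercept) == 1)
    ciM <- matrix(crossIntercept, T, T)
    diag(ciM) <- 0
  } else ciM <- as.matrix(crossIntercept)
  methods::new("SimulationConfig",
    nTraits = T, nSnps = as.integer(nSnps), labels = as.character(labels),
    sampleSizes = rep_len(as.numeric(sampleSizes), T),
    h2 = rep_len(as.numeric(h2), T), rg = rgM,
    interceptA = rep_len(as.numeric(interceptA), T), crossIntercept = ciM,
    ldscoreShape = as.numeric(ldscoreShape),
    ldscoreScale = as.numeric(ldscoreScale),
    mafRange = as.numeric(mafRange), mhcFrac = as.numeric(mhcFrac),
    includeDropFrac = as.numeric(includeDropFrac), seed = as.integer(seed))
}

# MHC stand-in window used throughout: the conventional LDSC exclusion
# region on chromosome 6 (1-based, inclusive).
MHC_REGION <- list(chr = 6L, start = 26e6, end = 34e6)

#' Simulate an LD-score table
#'
#' Draws per-SNP LD scores l_j = 1 + gamma(shape, scale) and assigns
#' deterministic genomic coordinates: SNPs cycle over chromosomes 1..22 at
#' increasing positions, except for a seeded `mhcFrac` fraction placed inside
#' the MHC stand-in window (chr6:26,000,000-34,000,000) so that
#' region-exclusion filters are exercised. Rows are in genomic order with
#' unique SNP ids.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `SNP`, `CHR`, `BP`, `L2`.
#' @examples
#' ld <- simulateLDScores(simConfig(2, 500, 1e4, 0.3))
#' head(ld)
#' @export
simulateLDScores <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  M <- config@nSnps
  withSeed(config@seed, {
    l2 <- 1 + stats::rgamma(M, shape = config@ldscoreShape,
                            scale = config@ldscoreScale)
    nMhc <- floor(config@mhcFrac * M)
    mhcIdx <- if (nMhc > 0) sort(sample.int(M, nMhc)) else integer()
    chr <- rep_len(1:22, M)
    bp <- 1e6 + 1000 * (seq_len(M) %/% 22)
    # keep ordinary chr6 SNPs clear of the MHC stand-in window
    shift <- chr == 6 & bp >= MHC_REGION$start & bp <= MHC_REGION$end
    bp[shift] <- bp[shift] + (MHC_REGION$end - MHC_REGION$start) + 1e6
    if (nMhc > 0) {
      chr[mhcIdx] <- MHC_REGION$chr
      bp[mhcIdx] <- round(seq(MHC_REGION$start + 1, MHC_REGION$end - 1,
                              length.out = nMhc))
    }
    ord <- order(chr, bp, seq_len(M))
    out <- data.frame(SNP = paste0("rs", seq_len(M)),
                      CHR = as.integer(chr[ord]),
                      BP = as.integer(bp[ord]),
                      L2 = l2[ord],
                      stringsAsFactors = FALSE)
    out
  })
}

#' Simulate an include-list (HapMap3 stand-in)
#'
#' Withholds a seeded `includeDropFrac` fraction of the panel's SNP ids and
#' returns the remainder, emulating the down-sampling of summary statistics
#' to a reference SNP list.
#'
#' @param config a [SimulationConfig-class].
#' @param ldscores LD-score table from [simulateLDScores()].
#' @return Character vector of retained SNP ids.
#' @export
simulateIncludeList <- function(config, ldscores) {
  stopifnot(methods::is(config, "SimulationConfig"))
  ids <- ldscores$SNP
  nDrop <- floor(config@includeDropFrac * length(ids))
  if (nDrop == 0) return(ids)
  withSeed(config@seed + 31L, {
    drop <- sample.int(length(ids), nDrop)
    ids[-drop]
  })
}

# Intercept part A = I + diag(a) + C and polygenic part B = D Rg D of the
# per-SNP z covariance Sigma_j = A + (l_j / M) B.
simCovParts <- function(config) {
  A <- diag(1 + config@interceptA, config@nTraits) + config@crossIntercept
  d <- sqrt(config@sampleSizes * config@h2)
  B <- config@rg * outer(d, d)
  list(A = A, B = B)
}

eigMin <- function(M) {
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Simulate multi-trait GWAS summary statistics
#'
#' For each SNP j, draws the T-vector of association z-scores from a
#' multivariate normal with mean zero and covariance
#' \deqn{\Sigma_j[t,t] = 1 + a_t + N_t h^2_t \ell_j / M,\qquad
#'   \Sigma_j[t,u] = c_{tu} + \sqrt{N_t N_u}\,(\ell_j/M)\,
#'   r_{G,tu}\sqrt{h^2_t h^2_u},}
#' i.e. the moment structure of univariate and bivariate LD-score regression
#' with confounding intercepts \eqn{1 + a_t} and sample-overlap
#' cross-intercepts \eqn{c_{tu}}. SNPs are independent given their LD
#' scores; there is no realized LD between rows, so the LDSC estimand is
#' exact and the block jackknife remains valid. MAF and HWE p-values are
#' decorative QC fields, independent of z, that exist to exercise filters.
#'
#' Because \eqn{\Sigma_j} is affine in \eqn{\ell_j}, it is positive
#' semidefinite for every SNP iff the intercept part A and polygenic part B
#' are; when they are, sampling is vectorized through their symmetric square
#' roots. Otherwise the offending SNP is named in the error (or, in the
#' rare case every individual \eqn{\Sigma_j} is still PSD, a slow per-SNP
#' path is used).
#'
#' @param config a [SimulationConfig-class].
#' @param ldscores LD-score table with `nSnps` rows (from
#'   [simulateLDScores()]).
#' @return Named list of per-trait data.frames with columns `SNP`, `CHR`,
#'   `BP`, `A1`, `A2`, `Z`, `N`, `MAF`, `HWE_P`.
#' @examples
#' cfg <- simConfig(2, 1000, 2e4, 0.4, rg = 0.5)
#' ld <- simulateLDScores(cfg)
#' ss <- simulateSumstats(cfg, ld)
#' str(ss$trait1)
#' @export
simulateSumstats <- function(config, ldscores) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  M <- config@nSnps
  T <- config@nTraits
  if (nrow(ldscores) != M)
    stop("ldscores has ", nrow(ldscores), " rows; config expects ", M)
  parts <- simCovParts(config)
  l2 <- ldscores$L2
  tol <- 1e-8
  fastOK <- eigMin(parts$A) >= -tol && eigMin(parts$B) >= -tol
  if (!fastOK) {
    for (j in seq_len(M)) {
      Sj <- parts$A + (l2[j] / M) * parts$B
      if (eigMin(Sj) < -tol)
        stop("per-SNP z covariance is not positive semidefinite at SNP ",
             ldscores$SNP[j], " (l2 = ", signif(l2[j], 4), ")")
    }
  }
  bases <- c("A", "C", "G", "T")
  withSeed(config@seed + 7L, {
    if (fastOK) {
      sqA <- symSqrt(parts$A)
      sqB <- symSqrt(parts$B)
      Z <- matrix(stats::rnorm(M * T), M, T) %*% sqA +
        (sqrt(l2 / M) * matrix(stats::rnorm(M * T), M, T)) %*% sqB
    } else {
      # every Sigma_j individually PSD despite indefinite parts: sample
      # SNP by SNP (rare, small configs only)
      Z <- matrix(0, M, T)
      for (j in seq_len(M)) {
        Sj <- parts$A + (l2[j] / M) * parts$B
        Z[j, ] <- stats::rnorm(T) %*% symSqrt(Sj)
      }
    }
    maf <- stats::runif(M, config@mafRange[1], config@mafRange[2])
    hwe <- stats::runif(M)
    a1 <- sample(bases, M, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
    out <- lapply(seq_len(T), function(t) {
      data.frame(SNP = ldscores$SNP, CHR = ldscores$CHR, BP = ldscores$BP,
                 A1 = a1, A2 = unname(a2), Z = Z[, t],
                 N = config@sampleSizes[t], MAF = maf, HWE_P = hwe,
                 stringsAsFactors = FALSE)
    })
    names(out) <- config@labels
    out
  })
}

#' Simulate a complete study panel
#'
#' Bundles [simulateLDScores()], [simulateIncludeList()], and
#' [simulateSumstats()] into one call, returning the pieces together with
#' the ground-truth parameters.
#'
#' @param config a [SimulationConfig-class].
#' @return List with elements `ldscores`, `includeList`, `sumstats` (named
#'   list of per-trait tables), and `truth` (ground-truth parameter list).
#' @export
simulateStudy <- function(config) {
  ld <- simulateLDScores(config)
  list(ldscores = ld,
       includeList = simulateIncludeList(config, ld),
       sumstats = simulateSumstats(config, ld),
       truth = list(labels = config@labels,
                    sampleSizes = config@sampleSizes, h2 = config@h2,
                    rg = config@rg, interceptA = config@interceptA,
                    crossIntercept = config@crossIntercept,
                    nSnps = config@nSnps, seed = config@seed))
}

#' Write a simulated study to disk
#'
#' Writes per-trait summary statistics as TSV (`<label>.sumstats.tsv` with
#' header SNP, CHR, BP, A1, A2, Z, N, MAF, HWE_P), LD scores as
#' `ldscores.tsv` (SNP, CHR, BP, L2), the include-list as one SNP id per
#' line, and the ground-truth parameters as a JSON sidecar.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (label in names(study$sumstats)) {
    p <- file.path(dir, paste0(label, ".sumstats.tsv"))
    writeSumstats(study$sumstats[[label]], p)
    paths <- c(paths, p)
  }
  pLd <- file.path(dir, "ldscores.tsv")
  writeLDScores(study$ldscores, pLd)
  pInc <- file.path(dir, "include_list.txt")
  writeLines(study$includeList, pInc)
  pTruth <- file.path(dir, "truth.json")
  writeJSON(study$truth, pTruth)
  invisible(c(paths, pLd, pInc, pTruth))
}
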