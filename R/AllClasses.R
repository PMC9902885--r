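#' Configuration of the multi-trait summary-statistic simulator
#'
#' Holds the ground truth of a simulated multi-trait GWAS panel: per-trait
#' sample sizes and SNP heritabilities, the genetic correlation matrix, the
#' confounding (population-stratification) intercept inflation per trait, and
#' the cross-trait intercept terms induced by sample overlap. LD scores are
#' drawn as 1 plus a gamma variate; a configurable fraction of SNPs is placed
#' in an MHC stand-in region and a fraction withheld from the include-list so
#' downstream filters have casualties.
#'
#' Per-SNP z-score vectors are multivariate normal with covariance
#' \deqn{\Sigma_j = A + (\ell_j / M)\, B,} where
#' \eqn{A = I + \mathrm{diag}(a) + C} collects the intercept terms and
#' \eqn{B = D\,R_G\,D} with \eqn{D = \mathrm{diag}(\sqrt{N_t h^2_t})} the
#' polygenic part — the moment structure LD-score regression estimates.
#'
#' @slot nTraits number of traits T.
#' @slot nSnps number of SNPs M.
#' @slot labels trait names, length T.
#' @slot sampleSizes per-trait GWAS sample sizes N_t.
#' @slot h2 per-trait SNP heritability in [0, 1].
#' @slot rg T x T genetic correlation matrix (unit diagonal, PSD).
#' @slot interceptA per-trait confounding inflation a_t (>= 0); the LDSC
#'   intercept of trait t is 1 + a_t.
#' @slot crossIntercept T x T sample-overlap cross-intercept matrix (zero
#'   diagonal, symmetric).
#' @slot ldscoreShape,ldscoreScale gamma parameters of \eqn{\ell_j - 1}.
#' @slot mafRange range of the simulated minor-allele frequencies.
#' @slot mhcFrac fraction of SNPs placed inside the MHC stand-in region.
#' @slot includeDropFrac fraction of SNPs withheld from the include-list.
#' @slot seed integer seed; all simulator randomness derives from it.
#' @seealso [simConfig()], [simulateLDScores()], [simulateSumstats()]
#' @export
setClass("SimulationConfig", representation(
  nTraits = "integer", nSnps = "integer", labels = "character",
  sampleSizes = "numeric", h2 = "numeric", rg = "matrix",
  interceptA = "numeric", crossIntercept = "matrix",
  ldscoreShape = "numeric", ldscoreScale = "numeric",
  mafRange = "numeric", mhcFrac = "numeric", includeDropFrac = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  T <- object@nTraits
  msg <- character()
  if (T < 1L) msg <- c(msg, "nTraits must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (length(object@labels) != T) msg <- c(msg, "labels must have length nTraits")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(object@sampleSizes) != T || any(object@sampleSizes <= 0))
    msg <- c(msg, "sampleSizes must be positive, length nTraits")
  if (length(object@h2) != T || any(object@h2 < 0) || any(object@h2 > 1))
    msg <- c(msg, "h2 must lie in [0, 1], length nTraits")
  if (!all(dim(object@rg) == c(T, T))) {
    msg <- c(msg, "rg must be T x T")
  } else {
    if (max(abs(object@rg - t(object@rg))) > 1e-8)
      msg <- c(msg, "rg must be symmetric")
    if (max(abs(diag(object@rg) - 1)) > 1e-8)
      msg <- c(msg, "rg must have unit diagonal")
    ev <- eigen((object@rg + t(object@rg)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8) msg <- c(msg, "rg must be positive semidefinite")
  }
  if (length(object@interceptA) != T || any(object@interceptA < 0))
    msg <- c(msg, "interceptA must be >= 0, length nTraits")
  if (!all(dim(object@crossIntercept) == c(T, T)) ||
      max(abs(object@crossIntercept - t(object@crossIntercept))) > 1e-8 ||
      any(abs(diag(object@crossIntercept)) > 1e-12))
    msg <- c(msg, "crossIntercept must be symmetric T x T with zero diagonal")
  if (object@ldscoreShape <= 0 || object@ldscoreScale <= 0)
    msg <- c(msg, "gamma parameters ldscoreShape/ldscoreScale must be > 0")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing pair in (0, 0.5]")
  if (object@mhcFrac < 0 || object@mhcFrac > 1 ||
      object@includeDropFrac < 0 || object@includeDropFrac > 1)
    msg <- c(msg, "mhcFrac/includeDropFrac must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-rule accounting of a summary-statistic filter pass
#'
#' Each removed SNP is attributed to the first failing rule in the fixed
#' order MAF, then HWE, then excluded region, then include-list, which makes
#' the counts deterministic. Removed plus retained equals the input rows.
#'
#' @slot nInput rows seen.
#' @slot nMaf,nHwe,nRegion,nInclude rows removed by each rule (first-failure
#'   attribution).
#' @slot nRetained rows surviving all rules.
#' @export
setClass("FilterReport", representation(
  nInput = "integer", nMaf = "integer", nHwe = "integer",
  nRegion = "integer", nInclude = "integer", nRetained = "integer"
))

setValidity("FilterReport", function(object) {
  tot <- object@nMaf + object@nHwe + object@nRegion + object@nInclude +
    object@nRetained
  if (tot != object@nInput)
    return("removed + retained must equal input rows")
  TRUE
})

#' Delete-a-block jackknife result
#'
#' Contiguous equal-as-possible blocks; pseudovalue_b = B * full - (B-1) *
#' leave-block-b-out. The jackknife estimate is the mean of the pseudovalues
#' and its standard error is sqrt(var(pseudovalues)/B) (sample variance,
#' B - 1 denominator).
#'
#' @slot estimate mean of the pseudovalues.
#' @slot se jackknife standard error.
#' @slot pseudovalues length-B pseudovalue vector.
#' @slot loo length-B leave-one-block-out estimates.
#' @slot blockSizes row counts per block (contiguous, genomic order).
#' @export
setClass("JackknifeResult", representation(
  estimate = "numeric", se = "numeric", pseudovalues = "numeric",
  loo = "numeric", blockSizes = "integer"
))

setValidity("JackknifeResult", function(object) {
  msg <- character()
  if (length(object@pseudovalues) != length(object@blockSizes))
    msg <- c(msg, "pseudovalues and blockSizes must have equal length")
  if (length(object@blockSizes) < 2L) msg <- c(msg, "need >= 2 blocks")
  if (is.finite(object@se) && object@se < 0) msg <- c(msg, "se must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Univariate LD-score regression fit
#'
#' SNP heritability, its jackknife standard error, and the regression
#' intercept (1 in the absence of confounding) from the regression of
#' chi-square statistics on LD scores. The per-block jackknife series are
#' retained so that bivariate fits can jackknife the genetic-correlation
#' ratio on the same block partition, and so that the cross-pair sampling
#' covariance of all estimates can be formed.
#'
#' @slot label trait name.
#' @slot h2 SNP heritability estimate (slope * M / N-bar).
#' @slot h2Se,zH2,pH2 jackknife SE, z-statistic, two-sided normal p.
#' @slot intercept,interceptSe LDSC intercept and its jackknife SE.
#' @slot meanChi2 mean chi-square of the regression SNPs.
#' @slot nSnps,nBlocks regression SNP count and jackknife block count.
#' @slot m reference SNP count M used for scaling (defaults to nSnps).
#' @slot h2Weight clamped pass-1 heritability used inside the pass-2
#'   regression weights; bivariate fits reuse it so that a trait's
#'   correlation with itself is exactly 1.
#' @slot h2Loo,h2Pseudo leave-block-out estimates and pseudovalues of h2.
#' @slot interceptPseudo pseudovalues of the intercept.
#' @slot snpIds regression SNP ids in genomic order (block partition anchor).
#' @export
setClass("UnivariateFit", representation(
  label = "character", h2 = "numeric", h2Se = "numeric", zH2 = "numeric",
  pH2 = "numeric", intercept = "numeric", interceptSe = "numeric",
  meanChi2 = "numeric", nSnps = "integer", nBlocks = "integer",
  m = "numeric", h2Weight = "numeric", h2Loo = "numeric",
  h2Pseudo = "numeric",
  interceptPseudo = "numeric", snpIds = "character"
))

setValidity("UnivariateFit", function(object) {
  msg <- character()
  if (object@nSnps <= object@nBlocks || object@nBlocks < 2L)
    msg <- c(msg, "need nSnps > nBlocks >= 2")
  if (any(c(object@h2Se, object@interceptSe) < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bivariate LD-score regression fit
#'
#' Genetic covariance and correlation of a harmonized trait pair from the
#' regression of z-score products on LD scores. The cross-trait intercept
#' absorbs sample overlap. rg is the ratio gcov / sqrt(h2_1 * h2_2) and is
#' jackknifed as a whole (the ratio is recomputed per leave-block-out); it
#' may legitimately fall outside [-1, 1] in small samples and is then
#' flagged, never clamped. When either heritability is non-positive rg is
#' undefined (`rgDefined = FALSE`), not an error.
#'
#' @slot label1,label2 trait names.
#' @slot gcov,gcovSe genetic covariance and jackknife SE.
#' @slot crossIntercept,crossInterceptSe cross-trait intercept and SE.
#' @slot rg,rgSe,pRg genetic correlation, jackknife SE, two-sided normal p.
#' @slot rgDefined FALSE when either h2 <= 0.
#' @slot rgOutOfRange TRUE when |rg| > 1.
#' @slot nSnps,nBlocks regression SNP count and block count.
#' @slot rgLoo,rgPseudo leave-block-out rg estimates and pseudovalues.
#' @export
setClass("BivariateFit", representation(
  label1 = "character", label2 = "character", gcov = "numeric",
  gcovSe = "numeric", crossIntercept = "numeric",
  crossInterceptSe = "numeric", rg = "numeric", rgSe = "numeric",
  pRg = "numeric", rgDefined = "logical", rgOutOfRange = "logical",
  nSnps = "integer", nBlocks = "integer", rgLoo = "numeric",
  rgPseudo = "numeric"
))

#' Genetic correlation matrix with sampling covariance
#'
#' The T x T genetic correlation matrix S assembled from all pairwise
#' bivariate fits, together with the K x K sampling covariance V of vech(S)
#' (K = T(T+1)/2; lower triangle, column-major, diagonal included — see
#' [vech()]), per-pair p-values, FDR q-values, and the per-trait flip flags
#' set by [alignSigns()]. Diagonal vech entries carry zero sampling variance
#' (the correlation diagonal is fixed at 1), but they occupy index space so
#' that 44 traits give the full 990-dimensional covariance.
#'
#' @slot labels trait names.
#' @slot S T x T correlation matrix, unit diagonal; undefined pairs are NA.
#' @slot V K x K sampling covariance of vech(S).
#' @slot pvals,qvals T x T symmetric matrices of per-pair p/q values (NA
#'   diagonal).
#' @slot flipped per-trait logical: TRUE when the trait's correlations were
#'   negated by the reverse-coding rule.
#' @slot nBlocks jackknife block count behind V.
#' @export
setClass("GenCorrMatrix", representation(
  labels = "character", S = "matrix", V = "matrix", pvals = "matrix",
  qvals = "matrix", flipped = "logical", nBlocks = "integer"
))

setValidity("GenCorrMatrix", function(object) {
  T <- length(object@labels)
  K <- T * (T + 1) / 2
  msg <- character()
  if (!all(dim(object@S) == c(T, T))) msg <- c(msg, "S must be T x T")
  else {
    if (max(abs(object@S - t(object@S)), na.rm = TRUE) > 1e-8)
      msg <- c(msg, "S must be symmetric")
    if (max(abs(diag(object@S) - 1)) > 1e-8)
      msg <- c(msg, "S must have unit diagonal")
  }
  if (!all(dim(object@V) == c(K, K)))
    msg <- c(msg, sprintf("V must be %d x %d", K, K))
  else if (max(abs(object@V - t(object@V)), na.rm = TRUE) > 1e-6)
    msg <- c(msg, "V must be symmetric")
  if (length(object@flipped) != T)
    msg <- c(msg, "flipped must have length T")
  if (length(msg)) msg else TRUE
})

#' Undirected weighted trait graph
#'
#' Edge triples (from, to, weight) over a fixed vertex set; at most one edge
#' per unordered pair, no self-edges, finite weights. Vertices with no edges
#' remain in `labels` so partitions always cover every trait.
#'
#' @slot labels vertex (trait) names.
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @export
setClass("EdgeList", representation(
  labels = "character", edges = "data.frame"
))

setValidity("EdgeList", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "edges needs columns from, to, weight")
  else {
    if (!all(c(e$from, e$to) %in% object@labels))
      msg <- c(msg, "edge endpoints must be in labels")
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (any(!is.finite(e$weight))) msg <- c(msg, "weights must be finite")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "at most one edge per pair")
  }
  if (length(msg)) msg else TRUE
})

#' Trait partition from community detection
#'
#' Cluster membership (dense integer ids from 1) for every trait, and the
#' modularity q of the partition on the graph it was fit to.
#'
#' @slot labels trait names.
#' @slot membership named integer vector, one dense cluster id per trait.
#' @slot q modularity of the partition (in [-1, 1]).
#' @export
setClass("Partition", representation(
  labels = "character", membership = "integer", q = "numeric"
))

setValidity("Partition", function(object) {
  msg <- character()
  if (length(object@membership) != length(object@labels))
    msg <- c(msg, "membership must cover every trait exactly once")
  if (!identical(names(object@membership), object@labels))
    msg <- c(msg, "membership names must equal labels")
  if (is.finite(object@q) && (object@q < -1 - 1e-8 || object@q > 1 + 1e-8))
    msg <- c(msg, "q must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Pairwise cluster-concordance matrix
#'
#' C[i, j] is the fraction of resampled re-clusterings in which traits i and
#' j land in the same community; the paper-style focal summary (co-cluster
#' frequency of one named trait with every other) is carried alongside.
#'
#' @slot labels trait names.
#' @slot concordance T x T symmetric matrix in [0, 1], unit diagonal.
#' @slot nResamples number of resamples counted.
#' @slot focal focal trait name (NA when none was requested).
#' @slot focalFreq named co-cluster frequencies of the focal trait.
#' @export
setClass("ConcordanceMatrix", representation(
  labels = "character", concordance = "matrix", nResamples = "integer",
  focal = "character", focalFreq = "numeric"
))

setValidity("ConcordanceMatrix", function(object) {
  T <- length(object@labels)
  msg <- character()
  if (!all(dim(object@concordance) == c(T, T)))
    msg <- c(msg, "concordance must be T x T")
  else {
    if (max(abs(object@concordance - t(object@concordance))) > 1e-12)
      msg <- c(msg, "concordance must be symmetric")
    if (any(object@concordance < -1e-12) ||
        any(object@concordance > 1 + 1e-12))
      msg <- c(msg, "concordance entries must lie in [0, 1]")
    if (max(abs(diag(object@concordance) - 1)) > 1e-12)
      msg <- c(msg, "concordance must have unit diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' Effective number of independent tests
#'
#' Spectral summary of a correlation matrix: its eigenvalues, their
#' variance, the implied effective degrees of freedom Meff, and the
#' Bonferroni-style corrected alpha = alpha / Meff.
#'
#' @slot m number of columns (tests).
#' @slot eigenvalues spectrum of the correlation matrix.
#' @slot varLambda variance of the eigenvalues (m - 1 denominator).
#' @slot meff effective degrees of freedom, in [1, m].
#' @slot alphaIn,alphaCorrected input and corrected significance levels.
#' @slot method "nyholt" or "liji".
#' @export
setClass("EffDfResult", representation(
  m = "integer", eigenvalues = "numeric", varLambda = "numeric",
  meff = "numeric", alphaIn = "numeric", alphaCorrected = "numeric",
  method = "character"
))

setValidity("EffDfResult", function(object) {
  msg <- character()
  if (object@meff < 1 - 1e-8 || object@meff > object@m + 1e-8)
    msg <- c(msg, "meff must lie in [1, m]")
  if (abs(object@alphaCorrected - object@alphaIn / object@meff) > 1e-12)
    msg <- c(msg, "alphaCorrected must equal alphaIn / meff")
  if (length(msg)) msg else TRUE
})
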