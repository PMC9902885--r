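#' Read and validate a pipeline run configuration
#'
#' A single JSON document drives the whole chain. Top-level fields:
#' \describe{
#'   \item{seed}{global integer seed; every stage derives its substream
#'     from it.}
#'   \item{outDir}{output directory.}
#'   \item{simulate}{simulator settings passed to [simConfig()] (nTraits,
#'     nSnps, sampleSizes, h2, rg, interceptA, crossIntercept, ...);
#'     omit it to read existing inputs from `paths`.}
#'   \item{paths}{when not simulating: `sumstats` (directory of
#'     `<label>.sumstats.tsv` files), `ldscores`, optional `includeList`,
#'     optional `zmat`.}
#'   \item{filter}{mafMin, hwePMin, excludeRegions, useIncludeList.}
#'   \item{ldsc}{nBlocks, mOverride.}
#'   \item{cluster}{seed, linkage.}
#'   \item{stability}{n, seed, focal.}
#'   \item{effdf}{alpha, method.}
#' }
#'
#' @param path JSON file path.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg config list (already parsed).
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$outDir)) stop("config needs outDir")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  if (is.null(cfg$simulate)) {
    p <- cfg$paths
    if (is.null(p$sumstats) || is.null(p$ldscores))
      stop("config without a simulate block needs paths$sumstats ",
           "and paths$ldscores")
    for (f in c(p$sumstats, p$ldscores, p$includeList, p$zmat))
      if (!is.null(f) && !file.exists(f))
        stop("configured path does not exist: ", f)
  }
  if (!is.null(cfg$paths$zmat) && !file.exists(cfg$paths$zmat))
    stop("configured path does not exist: ", cfg$paths$zmat)
  cfg
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis chain
#'
#' Executes simulate, filter, ldsc, corr, cluster, stability, and effdf in
#' order, writing every intermediate artifact in its documented format
#' (TSV tables/matrices, JSON structures) under `outDir`, plus a
#' `manifest.json` recording per-stage outputs with md5 hashes, record
#' counts, the seeds used, and package/R versions. Rerunning with the same
#' config reproduces byte-identical outputs. Any stage error aborts with
#' the stage name; artifacts of completed stages are preserved.
#'
#' When the config has no simulate block, sumstats/LD scores are read from
#' `paths`. The effdf stage consumes `paths$zmat` when given; otherwise it
#' applies the spectral estimator to the assembled genetic correlation
#' matrix itself, i.e. reports the effective number of independent traits.
#'
#' @param config config list (see [readRunConfig()]) or path to a JSON
#'   config file.
#' @return Invisibly, the manifest list.
#' @export
runAll <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  outDir <- cfg$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  manifest <- list(seed = seed,
                   package = as.character(utils::packageVersion("gencorrnet")),
                   rversion = as.character(getRversion()),
                   stages = list())
  note <- function(name, files, counts = list(), seeds = list()) {
    files <- files[file.exists(files)]
    manifest$stages[[name]] <<- list(
      name = name, files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      counts = counts, seeds = seeds)
  }

  # -- simulate ------------------------------------------------------------
  simDir <- file.path(outDir, "simulated")
  if (!is.null(cfg$simulate)) {
    runStage("simulate", {
      s <- cfg$simulate
      simSeed <- as.integer(s$seed %||% (seed + 11L))
      scfg <- simConfig(
        nTraits = s$nTraits, nSnps = s$nSnps,
        sampleSizes = s$sampleSizes, h2 = s$h2, rg = s$rg %||% 0,
        interceptA = s$interceptA %||% 0,
        crossIntercept = s$crossIntercept %||% 0,
        ldscoreShape = s$ldscoreShape %||% 2,
        ldscoreScale = s$ldscoreScale %||% 20,
        mafRange = s$mafRange %||% c(0.01, 0.5),
        mhcFrac = s$mhcFrac %||% 0.02,
        includeDropFrac = s$includeDropFrac %||% 0.05,
        seed = simSeed,
        labels = s$labels %||% paste0("trait", seq_len(s$nTraits)))
      study <- simulateStudy(scfg)
      files <- writeStudy(study, simDir)
      note("simulate", files,
           counts = list(nTraits = scfg@nTraits, nSnps = scfg@nSnps),
           seeds = list(simulate = simSeed))
      sumstats <- study$sumstats
      ldscores <- study$ldscores
      includeList <- study$includeList
    })
  } else {
    runStage("simulate", {
      p <- cfg$paths
      files <- list.files(p$sumstats, pattern = "\\.sumstats\\.tsv$",
                          full.names = TRUE)
      if (length(files) < 2) stop("need >= 2 sumstats files in ", p$sumstats)
      sumstats <- lapply(files, readSumstats)
      names(sumstats) <- sub("\\.sumstats\\.tsv$", "", basename(files))
      ldscores <- readLDScores(p$ldscores)
      includeList <- if (!is.null(p$includeList)) readLines(p$includeList)
                     else NULL
      note("simulate", c(files, p$ldscores),
           counts = list(nTraits = length(sumstats), nSnps = nrow(ldscores)))
    })
  }

  # -- filter --------------------------------------------------------------
  filtered <- NULL
  runStage("filter", {
    f <- cfg$filter
    fcfg <- snpFilterConfig(
      mafMin = f$mafMin %||% 0.01, hwePMin = f$hwePMin %||% 1e-8,
      includeList = if (isFALSE(f$useIncludeList)) NULL else includeList,
      excludeRegions = f$excludeRegions %||% "6:26000000-34000000")
    filtered <- lapply(sumstats, filterSumstats, cfg = fcfg)
    filtDir <- file.path(outDir, "filtered")
    dir.create(filtDir, showWarnings = FALSE)
    files <- character()
    reports <- list()
    for (label in names(filtered)) {
      p <- file.path(filtDir, paste0(label, ".sumstats.tsv"))
      writeSumstats(filtered[[label]]$stats, p)
      files <- c(files, p)
      r <- filtered[[label]]$report
      reports[[label]] <- list(input = r@nInput, maf = r@nMaf, hwe = r@nHwe,
                               region = r@nRegion, includeList = r@nInclude,
                               retained = r@nRetained)
    }
    pr <- file.path(filtDir, "filter_report.json")
    writeJSON(reports, pr)
    note("filter", c(files, pr),
         counts = list(retained = vapply(filtered, function(x)
           x$report@nRetained, 1L)))
  })

  # -- ldsc ----------------------------------------------------------------
  uniFits <- NULL; bivFits <- NULL
  runStage("ldsc", {
    nBlocks <- cfg$ldsc$nBlocks %||% 200
    mOverride <- cfg$ldsc$mOverride
    labels <- names(filtered)
    tabs <- lapply(filtered, `[[`, "stats")
    # one shared SNP panel so every fit rides the same block partition
    common <- Reduce(intersect, lapply(tabs, `[[`, "SNP"))
    common <- intersect(common, ldscores$SNP)
    tabs <- lapply(tabs, function(x) x[match(common, x$SNP), , drop = FALSE])
    uniFits <- lapply(labels, function(l)
      fitUnivariate(tabs[[l]], ldscores, label = l,
                    mOverride = mOverride, nBlocks = nBlocks))
    names(uniFits) <- labels
    pairs <- utils::combn(labels, 2, simplify = FALSE)
    bivFits <- lapply(pairs, function(pr) {
      h <- harmonizePair(tabs[[pr[1]]], tabs[[pr[2]]])
      fitBivariate(h$stats1, h$stats2, ldscores,
                   uniFits[[pr[1]]], uniFits[[pr[2]]],
                   mOverride = mOverride, nBlocks = nBlocks)
    })
    ldscDir <- file.path(outDir, "ldsc")
    dir.create(ldscDir, showWarnings = FALSE)
    uniJson <- lapply(uniFits, function(f) list(
      label = f@label, h2 = f@h2, h2Se = f@h2Se, zH2 = f@zH2, pH2 = f@pH2,
      intercept = f@intercept, interceptSe = f@interceptSe,
      meanChi2 = f@meanChi2, nSnps = f@nSnps, nBlocks = f@nBlocks))
    bivJson <- lapply(bivFits, function(f) list(
      label1 = f@label1, label2 = f@label2, gcov = f@gcov,
      gcovSe = f@gcovSe, crossIntercept = f@crossIntercept,
      crossInterceptSe = f@crossInterceptSe, rg = f@rg, rgSe = f@rgSe,
      pRg = f@pRg, rgDefined = f@rgDefined,
      rgOutOfRange = f@rgOutOfRange, nSnps = f@nSnps))
    p1 <- file.path(ldscDir, "univariate.json")
    p2 <- file.path(ldscDir, "bivariate.json")
    writeJSON(uniJson, p1)
    writeJSON(bivJson, p2)
    # per-pair log table mirroring a standard LDSC log
    logTab <- do.call(rbind, lapply(bivJson, as.data.frame))
    p3 <- file.path(ldscDir, "pairs.log.tsv")
    utils::write.table(logTab, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("ldsc", c(p1, p2, p3),
         counts = list(nUnivariate = length(uniFits),
                       nBivariate = length(bivFits),
                       nSnps = length(common)))
  })

  # -- corr ----------------------------------------------------------------
  gcm <- NULL
  runStage("corr", {
    gcm <- alignSigns(assembleGenCorr(uniFits, bivFits))
    corrDir <- file.path(outDir, "corr")
    dir.create(corrDir, showWarnings = FALSE)
    labels <- gcm@labels
    pS <- file.path(corrDir, "S.tsv")
    pV <- file.path(corrDir, "V.tsv")
    pP <- file.path(corrDir, "pvals.tsv")
    pQ <- file.path(corrDir, "qvals.tsv")
    pF <- file.path(corrDir, "flips.json")
    writeMatrixTSV(gcm@S, pS, labels)
    writeMatrixTSV(gcm@V, pV, paste0("v", seq_len(nrow(gcm@V))))
    writeMatrixTSV(gcm@pvals, pP, labels)
    writeMatrixTSV(gcm@qvals, pQ, labels)
    writeJSON(as.list(stats::setNames(gcm@flipped, labels)), pF)
    note("corr", c(pS, pV, pP, pQ, pF),
         counts = list(nTraits = length(labels),
                       vechDim = nrow(gcm@V),
                       nFlipped = sum(gcm@flipped)))
  })

  # -- cluster -------------------------------------------------------------
  runStage("cluster", {
    clSeed <- as.integer(cfg$cluster$seed %||% (seed + 23L))
    linkage <- cfg$cluster$linkage %||% "average"
    g <- buildClusterGraph(gcm)
    part <- louvainCluster(g, seed = clSeed)
    ord <- hclustOrder(gcm, linkage = linkage)
    disp <- displayGraph(gcm)
    clDir <- file.path(outDir, "cluster")
    dir.create(clDir, showWarnings = FALSE)
    pPart <- file.path(clDir, "partition.tsv")
    utils::write.table(
      data.frame(trait = part@labels, cluster = part@membership),
      pPart, sep = "\t", quote = FALSE, row.names = FALSE)
    pOrd <- file.path(clDir, "ordering.txt")
    writeLines(ord, pOrd)
    pEdges <- file.path(clDir, "display_edges.tsv")
    utils::write.table(disp$edges@edges, pEdges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pCent <- file.path(clDir, "centrality.tsv")
    utils::write.table(
      data.frame(trait = names(disp$centrality),
                 centrality = formatC(disp$centrality, digits = 17,
                                      format = "g")),
      pCent, sep = "\t", quote = FALSE, row.names = FALSE)
    pQjson <- file.path(clDir, "modularity.json")
    writeJSON(list(q = part@q,
                   nClusters = length(unique(part@membership))), pQjson)
    note("cluster", c(pPart, pOrd, pEdges, pCent, pQjson),
         counts = list(nClusters = length(unique(part@membership)),
                       nDisplayEdges = nrow(disp$edges@edges)),
         seeds = list(cluster = clSeed))
  })

  # -- stability -----------------------------------------------------------
  runStage("stability", {
    stSeed <- as.integer(cfg$stability$seed %||% (seed + 37L))
    nRes <- cfg$stability$n %||% 1000
    focal <- cfg$stability$focal
    conc <- stabilityRun(gcm, n = nRes, seed = stSeed, focal = focal)
    stDir <- file.path(outDir, "stability")
    dir.create(stDir, showWarnings = FALSE)
    pC <- file.path(stDir, "concordance.tsv")
    writeMatrixTSV(conc@concordance, pC, conc@labels)
    files <- pC
    if (!is.na(conc@focal)) {
      pFoc <- file.path(stDir, "focal.json")
      writeJSON(list(focal = conc@focal,
                     coClusterFrequency = as.list(conc@focalFreq)), pFoc)
      files <- c(files, pFoc)
    }
    note("stability", files,
         counts = list(nResamples = conc@nResamples),
         seeds = list(stability = stSeed))
  })

  # -- effdf ---------------------------------------------------------------
  runStage("effdf", {
    alpha <- cfg$effdf$alpha %||% 0.05
    method <- cfg$effdf$method %||% "nyholt"
    if (!is.null(cfg$paths$zmat)) {
      zmat <- readZMatrix(cfg$paths$zmat)
      corr <- pairwiseCompleteCorr(zmat)
      source <- "zmat"
    } else {
      corr <- gcm@S
      corr[is.na(corr)] <- 0
      source <- "genetic correlation matrix"
    }
    res <- effectiveDf(corr, alpha = alpha, method = method)
    pE <- file.path(outDir, "effdf.json")
    writeJSON(list(source = source, m = res@m, meff = res@meff,
                   varLambda = res@varLambda, alpha = res@alphaIn,
                   alphaCorrected = res@alphaCorrected,
                   method = res@method,
                   eigenvalues = res@eigenvalues), pE)
    note("effdf", pE, counts = list(m = res@m))
  })

  pM <- file.path(outDir, "manifest.json")
  writeJSON(manifest, pM)
  invisible(manifest)
}
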