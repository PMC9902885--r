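SUMSTATS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N", "MAF", "HWE_P")
LDSCORE_COLS <- c("SNP", "CHR", "BP", "L2")

#' Read GWAS summary statistics or LD scores
#'
#' Tab-separated with a header. Summary statistics need columns SNP, CHR,
#' BP, A1, A2, Z, N (MAF and HWE_P are optional QC fields; absent or NA
#' values pass the corresponding filter). Rows with missing or non-finite Z
#' are dropped with a message. LD-score tables need SNP, CHR, BP, L2.
#'
#' @param path file path.
#' @return A typed data.frame.
#' @export
readSumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("summary-statistics file ", path,
         " is missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("MAF", "HWE_P")) if (!col %in% names(df)) df[[col]] <- NA_real_
  df$Z <- suppressWarnings(as.numeric(df$Z))
  bad <- !is.finite(df$Z)
  if (any(bad)) {
    message("readSumstats: dropped ", sum(bad),
            " row(s) with missing/non-finite Z")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$SNP)) stop("duplicate SNP ids in ", path)
  if (any(!is.finite(df$N)) || any(df$N <= 0)) stop("N must be > 0 in ", path)
  rownames(df) <- NULL
  df[, SUMSTATS_COLS]
}

#' @rdname readSumstats
#' @export
readLDScores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(LDSCORE_COLS, names(df))
  if (length(miss))
    stop("LD-score file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$SNP)) stop("duplicate SNP ids in ", path)
  if (any(!is.finite(df$L2))) stop("non-finite L2 in ", path)
  rownames(df) <- NULL
  df[, LDSCORE_COLS]
}

#' Write summary statistics or LD scores as TSV
#'
#' @param x data.frame in the package's column layout.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeSumstats <- function(x, path) {
  utils::write.table(x[, SUMSTATS_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
writeLDScores <- function(x, path) {
  utils::write.table(x[, LDSCORE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' SNP filter configuration
#'
#' QC thresholds matching the LDSC-style settings MAF > 0.01 and
#' HWE p > 1e-8 "insofar available" (rows with a missing QC field pass that
#' rule), an optional include-list (HapMap3 stand-in), and genomic exclusion
#' regions given as "chr:start-end" strings, 1-based inclusive. The default
#' region is the conventional MHC window chr6:26,000,000-34,000,000.
#'
#' @param mafMin retain rows with MAF strictly above this.
#' @param hwePMin retain rows with HWE p strictly above this.
#' @param includeList character vector of SNP ids, or NULL for no
#'   include-list restriction.
#' @param excludeRegions character vector of "chr:start-end" regions;
#'   use `character()` for none.
#' @param dropAmbiguous drop strand-ambiguous (A/T, C/G) SNPs. Default
#'   FALSE: simulated alleles are under the package's control.
#' @return A list of class `SNPFilterConfig`.
#' @export
snpFilterConfig <- function(mafMin = 0.01, hwePMin = 1e-8,
                            includeList = NULL,
                            excludeRegions = "6:26000000-34000000",
                            dropAmbiguous = FALSE) {
  stopifnot(mafMin >= 0, mafMin < 0.5, hwePMin >= 0, hwePMin < 1)
  regions <- lapply(excludeRegions, parseRegion)
  structure(list(mafMin = mafMin, hwePMin = hwePMin,
                 includeList = includeList, excludeRegions = regions,
                 dropAmbiguous = dropAmbiguous),
            class = "SNPFilterConfig")
}

parseRegion <- function(s) {
  m <- regmatches(s, regexec("^([0-9XYxy]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4)
    stop("malformed region '", s, "'; expected chr:start-end")
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (start > end) stop("malformed region '", s, "': start > end")
  list(chr = m[2], start = start, end = end)
}

inRegions <- function(chr, bp, regions) {
  hit <- rep(FALSE, length(chr))
  for (r in regions)
    hit <- hit | (as.character(chr) == r$chr & bp >= r$start & bp <= r$end)
  hit
}

#' Filter summary statistics
#'
#' Retains rows with MAF > mafMin AND HWE p > hwePMin AND outside every
#' exclusion region AND (no include-list, or SNP id on it). Missing MAF or
#' HWE p passes that rule ("insofar available"). The report attributes each
#' removed SNP to the first failing rule in the fixed order
#' maf, hwe, region, include-list. Filtering is idempotent. An empty result
#' raises a warning, not an error.
#'
#' @param stats summary-statistics data.frame (see [readSumstats()]).
#' @param cfg a [snpFilterConfig()].
#' @return List with elements `stats` (retained rows) and `report`
#'   (a [FilterReport-class]).
#' @examples
#' cfg <- simConfig(1, 300, 1e4, 0.3)
#' ss <- simulateStudy(cfg)
#' out <- filterSumstats(ss$sumstats[[1]],
#'                       snpFilterConfig(includeList = ss$includeList))
#' out$report
#' @export
filterSumstats <- function(stats, cfg = snpFilterConfig()) {
  if (nrow(stats) == 0) stop("empty summary statistics")
  stopifnot(inherits(cfg, "SNPFilterConfig"))
  failMaf <- !is.na(stats$MAF) & stats$MAF <= cfg$mafMin
  failHwe <- !is.na(stats$HWE_P) & stats$HWE_P <= cfg$hwePMin
  failRegion <- inRegions(stats$CHR, stats$BP, cfg$excludeRegions)
  failInclude <- if (is.null(cfg$includeList)) rep(FALSE, nrow(stats))
                 else !(stats$SNP %in% cfg$includeList)
  if (isTRUE(cfg$dropAmbiguous)) {
    pair <- paste(pmin(stats$A1, stats$A2), pmax(stats$A1, stats$A2))
    failInclude <- failInclude | pair %in% c("A T", "C G")
  }
  # first-failing-rule attribution
  nMaf <- sum(failMaf)
  nHwe <- sum(!failMaf & failHwe)
  nRegion <- sum(!failMaf & !failHwe & failRegion)
  nInclude <- sum(!failMaf & !failHwe & !failRegion & failInclude)
  keep <- !(failMaf | failHwe | failRegion | failInclude)
  if (!any(keep)) warning("all SNPs removed by filtering")
  report <- methods::new("FilterReport",
    nInput = nrow(stats), nMaf = as.integer(nMaf), nHwe = as.integer(nHwe),
    nRegion = as.integer(nRegion), nInclude = as.integer(nInclude),
    nRetained = as.integer(sum(keep)))
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(stats = out, report = report)
}

#' Harmonize a summary-statistic pair
#'
#' Intersects two tables on SNP id and aligns trait 2's effect alleles to
#' trait 1's: where trait 2 carries the same alleles in swapped order, its z
#' is negated; where the allele sets differ entirely, the SNP is dropped
#' with a logged count. Output tables are row-aligned in trait 1's order, as
#' required before regressing products of z-scores.
#'
#' @param stats1,stats2 QC'd summary-statistics tables.
#' @return List with `stats1`, `stats2` (row-aligned), `nFlipped`,
#'   `nDropped`.
#' @export
harmonizePair <- function(stats1, stats2) {
  common <- intersect(stats1$SNP, stats2$SNP)
  if (length(common) == 0) stop("no SNPs in common between the two tables")
  s1 <- stats1[match(common, stats1$SNP), , drop = FALSE]
  s2 <- stats2[match(common, stats2$SNP), , drop = FALSE]
  same <- s1$A1 == s2$A1 & s1$A2 == s2$A2
  swapped <- s1$A1 == s2$A2 & s1$A2 == s2$A1
  mismatch <- !(same | swapped)
  if (any(swapped)) {
    s2$Z[swapped] <- -s2$Z[swapped]
    tmp <- s2$A1[swapped]
    s2$A1[swapped] <- s2$A2[swapped]
    s2$A2[swapped] <- tmp
  }
  if (any(mismatch))
    message("harmonizePair: dropped ", sum(mismatch),
            " SNP(s) with irreconcilable alleles")
  keep <- !mismatch
  s1 <- s1[keep, , drop = FALSE]
  s2 <- s2[keep, , drop = FALSE]
  rownames(s1) <- rownames(s2) <- NULL
  list(stats1 = s1, stats2 = s2,
       nFlipped = sum(swapped), nDropped = sum(mismatch))
}
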