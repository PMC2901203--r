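#' Write study data as tab-separated text
#'
#' Two files: a haplotype file with one row per individual (`id`, maternal
#' haplotype string, paternal haplotype string, phenotype; `NA` when
#' phenotypes are unset) and a marker map file (`marker`, `positionCM`).
#'
#' @param study a [StudyData-class].
#' @param haplotypeFile,mapFile output paths.
#' @return Invisibly, the two paths.
#' @export
writeStudy <- function(study, haplotypeFile, mapFile) {
  stopifnot(is(study, "StudyData"))
  n <- nIndividuals(study)
  y <- phenotypes(study)
  df <- data.frame(
    id = seq_len(n),
    maternal = apply(maternalHaplotypes(study), 1, paste, collapse = ""),
    paternal = apply(paternalHaplotypes(study), 1, paste, collapse = ""),
    phenotype = if (length(y)) y else rep(NA_real_, n))
  write.table(df, haplotypeFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  mp <- data.frame(marker = paste0("mk", seq_len(nMarkers(study))),
                   positionCM = positionsCM(study))
  write.table(mp, mapFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(haplotypeFile, mapFile))
}

.ioError <- function(file, line, msg) {
  stop(sprintf("%s:%d: %s", file, line, msg), call. = FALSE)
}

.parseHapString <- function(s, nMarkers, file, line, what) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) != nMarkers)
    .ioError(file, line, sprintf(
      "%s haplotype string has %d alleles but the map lists %d markers",
      what, length(chars), nMarkers))
  if (!all(chars %in% c("0", "1")))
    .ioError(file, line, sprintf(
      "%s haplotype contains codes other than 0/1 (unphased or invalid)",
      what))
  as.integer(chars)
}

#' Read study data from tab-separated text
#'
#' Counterpart of [writeStudy()]. Phenotypes may live in the haplotype
#' file's `phenotype` column or in a separate single-column file. Allele
#' codes must be phased 0/1 strings; format errors report the offending
#' line number.
#'
#' @param haplotypeFile path to the haplotype table (`id`, `maternal`,
#'   `paternal`[, `phenotype`]).
#' @param mapFile path to the marker map (`marker`, `positionCM`).
#' @param phenotypeFile optional path to a one-phenotype-per-line file
#'   overriding the `phenotype` column.
#' @return A [StudyData-class].
#' @export
readStudy <- function(haplotypeFile, mapFile, phenotypeFile = NULL) {
  mp <- read.table(mapFile, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("marker", "positionCM") %in% names(mp)))
    .ioError(mapFile, 1L, "map file must have columns marker, positionCM")
  if (!is.numeric(mp$positionCM) || anyNA(mp$positionCM))
    .ioError(mapFile, 1L, "positionCM must be numeric")
  m <- nrow(mp)
  hp <- read.table(haplotypeFile, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (!all(c("id", "maternal", "paternal") %in% names(hp)))
    .ioError(haplotypeFile, 1L,
             "haplotype file must have columns id, maternal, paternal")
  n <- nrow(hp)
  maternal <- matrix(0L, n, m)
  paternal <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    # +1 for the header line in reported line numbers
    maternal[i, ] <- .parseHapString(hp$maternal[i], m, haplotypeFile,
                                     i + 1L, "maternal")
    paternal[i, ] <- .parseHapString(hp$paternal[i], m, haplotypeFile,
                                     i + 1L, "paternal")
  }
  y <- numeric(0)
  if (!is.null(phenotypeFile)) {
    yc <- readLines(phenotypeFile)
    y <- suppressWarnings(as.numeric(yc))
    if (anyNA(y))
      .ioError(phenotypeFile, which(is.na(y))[1L],
               "non-numeric phenotype value")
    if (length(y) != n)
      .ioError(phenotypeFile, length(y),
               "phenotype count does not match the number of individuals")
  } else if ("phenotype" %in% names(hp) && !all(hp$phenotype == "NA")) {
    y <- suppressWarnings(as.numeric(hp$phenotype))
    if (anyNA(y))
      .ioError(haplotypeFile, which(is.na(y))[1L] + 1L,
               "non-numeric phenotype value")
  }
  new("StudyData",
      maternal = maternal, paternal = paternal,
      qtlGenotype = integer(0), phenotypes = y,
      X = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
      qtlVarianceFraction = NA_real_,
      markerPositionsCM = mp$positionCM,
      qtlPositionCM = NA_real_, poolQtlFreq = NA_real_)
}

#' Export window genotypes as a minimal phased VCF
#'
#' One record per window marker with phased `GT` fields (`0|1` style, `|`
#' separator). Positions are encoded as integer base-pair coordinates at
#' 1 cM = 1 Mb (`POS = round(positionCM * 1e4) * 100 + 1`), which keeps the
#' grid exact for spacings down to 0.01 cM.
#'
#' @param study a [StudyData-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeStudyVcf <- function(study, file) {
  stopifnot(is(study, "StudyData"))
  n <- nIndividuals(study)
  m <- nMarkers(study)
  gt <- matrix("", m, n)
  mat <- maternalHaplotypes(study)
  pat <- paternalHaplotypes(study)
  for (j in seq_len(m))
    gt[j, ] <- paste0(mat[, j], "|", pat[, j])
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("ind", seq_len(n))),
                    collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", format(round(positionsCM(study)[j] * 1e4) * 100 + 1,
                        scientific = FALSE),
            paste0("mk", j), "A", "B", ".", "PASS", ".", "GT", gt[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Write retained chain samples as TSV
#'
#' @param chain a [PosteriorChain-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeChainTsv <- function(chain, file) {
  stopifnot(is(chain, "PosteriorChain"))
  s <- chainSamples(chain)
  df <- data.frame(iteration = chain@burnIn +
                     seq_len(nrow(s)) * chain@thinning, s)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a scan table as TSV
#'
#' @param scan a [ScanResult-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeScanTsv <- function(scan, file) {
  stopifnot(is(scan, "ScanResult"))
  write.table(scanTable(scan), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

.configSchema <- list(
  seed = NULL,
  demography = c("phase1Size", "phase1Generations", "phase2Size",
                 "phase2Generations", "mutationRate"),
  panel = c("markerSpacingCM"),
  study = c("sampleSize", "qtlVarianceFraction"),
  method = c("k", "sigma2Mu", "nuE", "s2E", "sigma2X", "sigma2XProp",
             "sigma2MuProp", "sigma2EProp", "adapt", "nIterations",
             "burnIn", "thinning"),
  experiment = c("methods", "nNullReps", "nPowerReps", "level",
                 "reuseHistory")
)

#' Read and validate a declarative run configuration
#'
#' A single YAML file holds the demography, panel, study, sampler and
#' experiment settings plus the master seed. Unknown keys anywhere in the
#' file are rejected, so typos fail loudly instead of being silently
#' ignored.
#'
#' @param file path to a YAML configuration.
#' @return A named list with elements `seed`, `demo`
#'   ([DemographyConfig-class]), `panel`, `study`, `prior`
#'   ([PriorConfig-class]), `proposal` ([ProposalConfig-class]), `chain`
#'   ([ChainConfig-class]), `k`, and `experiment`.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(.configSchema)) {
    if (is.null(.configSchema[[sec]]) || is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  getOr <- function(section, key, default) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) default else v
  }
  demo <- demographyConfig(
    getOr("demography", "phase1Size", 500L),
    getOr("demography", "phase1Generations", 1000L),
    getOr("demography", "phase2Size", 100L),
    getOr("demography", "phase2Generations", 50L),
    getOr("demography", "mutationRate", 2.5e-5))
  list(
    seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed),
    demo = demo,
    panel = list(markerSpacingCM = getOr("panel", "markerSpacingCM", 0.1)),
    study = list(n = as.integer(getOr("study", "sampleSize", 500L)),
                 qtlVarianceFraction = getOr("study", "qtlVarianceFraction",
                                             0.05)),
    k = as.integer(getOr("method", "k", 1L)),
    prior = priorConfig(getOr("method", "sigma2Mu", 1),
                        getOr("method", "nuE", 4),
                        getOr("method", "s2E", 0.5),
                        getOr("method", "sigma2X", 1)),
    proposal = proposalConfig(getOr("method", "sigma2XProp", 0.25),
                              getOr("method", "sigma2MuProp", 0.01),
                              getOr("method", "sigma2EProp", 0.01),
                              getOr("method", "adapt", TRUE)),
    chain = chainConfig(getOr("method", "nIterations", 20000L),
                        getOr("method", "burnIn", 5000L),
                        getOr("method", "thinning", 5L)),
    experiment = list(
      methods = getOr("experiment", "methods", "LSR1"),
      nNullReps = as.integer(getOr("experiment", "nNullReps", 100L)),
      nPowerReps = as.integer(getOr("experiment", "nPowerReps", 100L)),
      level = getOr("experiment", "level", 0.10),
      reuseHistory = isTRUE(getOr("experiment", "reuseHistory", FALSE))))
}
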