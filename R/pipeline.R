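#' Orchestrated pipeline runs
#'
#' Executes simulate -> (map) -> score / interact from a single
#' configuration, persisting every intermediate table plus a
#' machine-readable run summary (all thresholds in effect, seed, package
#' version). Identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config a list, or path to a YAML/JSON file, with fields:
#'   \code{seed} (required), \code{mode} (\code{"single"} or
#'   \code{"dual"}), optional \code{sim} (overrides for [simConfig()]),
#'   optional \code{thresholds} (minInitial, scale, cap, fdr,
#'   minDifferential, minNeg, minPairs, minValid, expectedMode), and for
#'   dual mode an optional \code{uncoupling} block (\code{enabled},
#'   \code{nDesigned}) switching on cassette-read simulation, mapping and
#'   uncoupling estimation.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the run summary list. On stage failure a FAILED
#'   marker file naming the stage is left in \code{outdir} and the error is
#'   re-raised.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$seed)) stop("invalid config: missing field 'seed'")
  mode <- config$mode %||% "single"
  if (!mode %in% c("single", "dual"))
    stop("invalid config: 'mode' must be 'single' or 'dual'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  th <- config$thresholds %||% list()
  thresholds <- list(
    minInitial = th$minInitial %||% 50, scale = th$scale %||% 1e6,
    cap = th$cap %||% 100, fdr = th$fdr %||% 0.05,
    minDifferential = th$minDifferential %||% 2.5,
    minNeg = th$minNeg %||% 4, minPairs = th$minPairs %||% 8,
    minValid = th$minValid %||% 2,
    expectedMode = th$expectedMode %||% "additive")

  stage <- "simulate"
  summary <- list(
    package = "duoscreen",
    version = as.character(utils::packageVersion("duoscreen")),
    mode = mode, seed = config$seed, thresholds = thresholds)
  res <- tryCatch({
    cfg <- do.call(simConfig, c(list(seed = config$seed),
                                config$sim %||% list()))
    if (mode == "single") {
      sim <- simulateSingleScreen(cfg)
      writeAnnotation(sim$annotation, file.path(outdir, "annotation.tsv"))
      writeCountTable(sim$counts, file.path(outdir, "counts.tsv"))
      writeAnnotation(sim$truth, file.path(outdir, "truth.tsv"))
      stage <- "score"
      sc <- scoreScreen(sim$counts, sim$annotation,
                        minInitial = thresholds$minInitial,
                        scale = thresholds$scale, cap = thresholds$cap)
      writeAnnotation(sc$lfc, file.path(outdir, "lfc.tsv"))
      writeAnnotation(sc$domainScores, file.path(outdir, "domain_scores.tsv"))
      summary$n_guides <- nrow(sim$annotation)
      summary$n_removed_low_initial <- length(sc$removed)
      summary$n_domains_scored <- nrow(sc$domainScores)
    } else {
      sim <- simulateDualScreen(cfg)
      writeAnnotation(sim$annotation, file.path(outdir, "annotation.tsv"))
      writeAnnotation(sim$cassettes, file.path(outdir, "cassettes.tsv"))
      writeCountTable(sim$counts, file.path(outdir, "counts.tsv"))
      writeAnnotation(sim$truth, file.path(outdir, "truth.tsv"))
      unc <- config$uncoupling %||% list()
      if (isTRUE(unc$enabled)) {
        stage <- "map"
        ann <- sim$annotation
        spacers <- stats::setNames(ann$spacer, ann$guide_id)
        nDes <- unc$nDesigned %||% min(168L, length(spacers)^2)
        des <- enumerateDualLibrary(
          data.frame(guide_id = ann$guide_id, spacer = ann$spacer))
        des <- des[seq_len(nDes), c("cassette_id", "pos1", "pos2")]
        ref <- cassetteReference(des, spacers)
        reads <- simulateCassetteReads(cfg, ref)
        writeFastq(reads$reads, file.path(outdir, "cassette_reads.fastq"))
        full <- expandRecombinants(ref)
        cc <- countCassettes(reads$reads, full)
        uf <- uncouplingFrequency(cc$counts, full)
        summary$mapping <- cc$summary
        summary$uncoupling_percent <- uf$percent
      }
      stage <- "interact"
      ia <- analyzeDualScreen(sim$counts, sim$annotation,
                              minInitial = thresholds$minInitial,
                              scale = thresholds$scale, cap = thresholds$cap,
                              minNeg = thresholds$minNeg,
                              minPairs = thresholds$minPairs,
                              minValid = thresholds$minValid,
                              fdr = thresholds$fdr,
                              minDifferential = thresholds$minDifferential,
                              expectedMode = thresholds$expectedMode)
      writeAnnotation(ia$lfc, file.path(outdir, "cassette_lfc.tsv"))
      writeAnnotation(ia$pairs, file.path(outdir, "pair_results.tsv"))
      writeAnnotation(ia$guideFits, file.path(outdir, "guide_fits.tsv"))
      summary$n_cassettes <- nrow(sim$cassettes)
      summary$n_removed_guides <- length(ia$removedGuides)
      summary$n_pairs_tested <- nrow(ia$pairs)
      summary$n_hits <- sum(ia$pairs$hit)
      summary$hits <- if (summary$n_hits > 0)
        paste(ia$pairs$geneA[ia$pairs$hit], ia$pairs$geneB[ia$pairs$hit],
              sep = "&") else character(0)
    }
    summary
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(e)
  })
  jsonlite::write_json(res, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
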