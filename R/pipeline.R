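# End-to-end orchestration: comparative statistics -> Diversity-Gap
# window ranking -> allele profiling of top candidates -> diagnostic-rule
# derivation and classification, from a single configuration, with
# deterministic TSV/JSON/BED artifacts and a consolidated report.

#' Default pipeline parameters
#' @return named list of every tunable stage parameter.
#' @export
defaultPipelineParams <- function() {
  list(windowLen = 200L, step = 50L, homopolymerMax = 8L, flankLen = 20L,
       flankMaxPi = 0, minCov = 10L, minSites = 20L, aggregate = "max",
       topK = 5L, minIdentity = 0.9, fragmentLen = 600L,
       recruitIdentity = 0.8, recruitHitLen = 50L, minCount = 1L,
       maxBackgroundDivergence = 0.15, ssrThresholds = defaultSsrThresholds(),
       repeatMinLen = 30L)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file with optional elements `genomes` (FASTA
#'   paths), `alignment` (aligned FASTA path), `reads` (named
#'   species -> FASTQ/FASTA path map), `outDir`, `stages` (logical map),
#'   `params` (overrides of [defaultPipelineParams]).
#' @return config list for [runPipeline].
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c(cfg$genomes, cfg$alignment, unlist(cfg$reads)))
    if (!file.exists(f)) stop("config references missing file: ", f)
  cfg
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the enabled stages in order comparative -> divgap ->
#' profile -> classify and writes stage artifacts under
#' `outDir/<stage>/`. All coordinates in TSV reports are 1-based
#' inclusive; BED output is 0-based half-open. Re-running with the same
#' inputs yields byte-identical outputs.
#'
#' @param genomes named list of [GenomeRecord-class] (or a config via
#'   `config`).
#' @param alignment a [GenomeAlignment-class] of the genomes.
#' @param readSets named list of [ReadSet-class] per species (names
#'   matching alignment rows).
#' @param outDir output directory (created); `NULL` writes nothing.
#' @param stages named logical: which of comparative/divgap/profile/
#'   classify run. Disabling a stage never changes upstream outputs.
#' @param params overrides of [defaultPipelineParams].
#' @param config optional path to a YAML/JSON config; file inputs are
#'   loaded, and explicit arguments win over the config.
#' @return report list with sections `comparative`, `divgap`, `profile`,
#'   `classify`, `provenance` and collected `warnings`.
#' @export
runPipeline <- function(genomes = NULL, alignment = NULL, readSets = NULL,
                        outDir = NULL,
                        stages = c(comparative = TRUE, divgap = TRUE,
                                   profile = TRUE, classify = TRUE),
                        params = list(), config = NULL) {
  checks <- character(0)
  if (!is.null(config)) {
    cfg <- readPipelineConfig(config)
    if (is.null(genomes) && !is.null(cfg$genomes)) {
      genomes <- unlist(lapply(cfg$genomes, readFasta, circular = TRUE),
                        recursive = FALSE)
      names(genomes) <- vapply(genomes, genomeId, "")
      checks <- c(checks, unlist(cfg$genomes))
    }
    if (is.null(alignment) && !is.null(cfg$alignment)) {
      alignment <- readAlignmentFasta(cfg$alignment)
      checks <- c(checks, cfg$alignment)
    }
    if (is.null(readSets) && !is.null(cfg$reads)) {
      readSets <- lapply(names(cfg$reads), function(sp)
        readReads(cfg$reads[[sp]], sp))
      names(readSets) <- names(cfg$reads)
      checks <- c(checks, unlist(cfg$reads))
    }
    if (is.null(outDir)) outDir <- cfg$outDir
    if (!is.null(cfg$stages))
      stages[names(cfg$stages)] <- unlist(cfg$stages)
    if (!is.null(cfg$params)) params <- utils::modifyList(cfg$params, params)
  }
  p <- utils::modifyList(defaultPipelineParams(), params)
  warnings <- character(0)
  report <- list(provenance = list(
    package = "plastomeDivGap",
    version = as.character(utils::packageVersion("plastomeDivGap")),
    params = p,
    inputChecksums = if (length(checks))
      as.list(tools::md5sum(checks)) else list()))

  mkStageDir <- function(stage) {
    if (is.null(outDir)) return(NULL)
    d <- file.path(outDir, stage)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  grab <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings <<- c(warnings, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  if (isTRUE(stages[["comparative"]])) {
    report$comparative <- grab("comparative", {
      d <- mkStageDir("comparative")
      summ <- do.call(rbind, lapply(genomes, function(g)
        cbind(genome = genomeId(g), plastomeSummary(g))))
      rownames(summ) <- NULL
      ssrs <- do.call(rbind, lapply(genomes, function(g) {
        h <- findSSRs(genomeSeq(g), p$ssrThresholds, genomeFeatures(g))
        if (nrow(h)) cbind(genome = genomeId(g), h)
      }))
      reps <- do.call(rbind, lapply(genomes, function(g) {
        h <- findRepeats(genomeSeq(g), p$repeatMinLen)
        if (nrow(h)) cbind(genome = genomeId(g), h)
      }))
      vars <- callVariants(alignment,
                           features = genomeFeatures(genomes[[1]]))
      if (!is.null(d)) {
        .writeTsv(summ, file.path(d, "summary.tsv"))
        if (!is.null(ssrs)) {
          u <- ssrs; u$start <- u$start + 1L   # 1-based inclusive
          .writeTsv(u, file.path(d, "ssr.tsv"))
        }
        if (!is.null(reps)) {
          u <- reps; u$start1 <- u$start1 + 1L; u$start2 <- u$start2 + 1L
          .writeTsv(u, file.path(d, "repeats.tsv"))
        }
        snp <- vars$snps
        if (nrow(snp)) {
          vcfish <- data.frame(CHROM = genomeId(genomes[[1]]),
                               POS = snp$refPos + 1L,
                               REF = snp[[names(genomes)[1]]],
                               ALT = apply(snp[names(genomes)[-1]], 1,
                                           function(z) paste(unique(z),
                                                             collapse = ",")))
          .writeTsv(vcfish, file.path(d, "snp_sites.tsv"))
        }
        if (nrow(vars$indels)) {
          u <- vars$indels; u$start <- u$start + 1L
          .writeTsv(u, file.path(d, "indels.tsv"))
        }
        if (!is.null(vars$featureTallies))
          jsonlite::write_json(vars$featureTallies,
                               file.path(d, "feature_tallies.json"),
                               dataframe = "rows", digits = NA)
      }
      list(summary = summ, ssrs = ssrs, repeats = reps, variants = vars)
    })
  }

  pileups <- NULL
  if (isTRUE(stages[["divgap"]])) {
    report$divgap <- grab("divgap", {
      d <- mkStageDir("divgap")
      pileups <- lapply(names(genomes), function(sp)
        pileupFromReads(readSets[[sp]], genomes[[sp]],
                        minIdentity = p$minIdentity))
      names(pileups) <- names(genomes)
      rk <- rankWindows(alignment, pileups, windowLen = p$windowLen,
                        step = p$step, homopolymerMax = p$homopolymerMax,
                        flankLen = p$flankLen, flankMaxPi = p$flankMaxPi,
                        minCov = p$minCov, minSites = p$minSites,
                        aggregate = p$aggregate, topK = p$topK)
      if (!is.null(d)) {
        w <- rk$windows; w$start <- w$start + 1L
        .writeTsv(w, file.path(d, "windows.tsv"))
        if (nrow(rk$candidates)) {
          bed <- data.frame(chrom = "alignment",
                            chromStart = rk$candidates$start,
                            chromEnd = rk$candidates$end,
                            name = paste0("candidate", rk$candidates$rank),
                            score = round(1000 * rk$candidates$G))
          utils::write.table(bed, file.path(d, "candidates.bed"),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             col.names = FALSE)
          jsonlite::write_json(rk$candidates,
                               file.path(d, "candidates.json"),
                               dataframe = "rows", digits = NA)
        }
      }
      rk
    })
  }

  if (isTRUE(stages[["profile"]]) && !is.null(report$divgap) &&
      nrow(report$divgap$candidates)) {
    report$profile <- grab("profile", {
      d <- mkStageDir("profile")
      cand <- report$divgap$candidates[1, ]
      tables <- list()
      for (sp in names(genomes)) {
        iv <- alignmentToSeqCoords(alignment, sp, cand$start, cand$end)
        frag <- extractTargetFragment(genomes[[sp]], iv[1], iv[2],
                                      fragmentLen = p$fragmentLen)
        rec <- recruitReads(frag, readSets[[sp]],
                            minIdentity = p$recruitIdentity,
                            minHitLen = p$recruitHitLen)
        tables[[sp]] <- tabulateAlleles(rec, frag, minCount = p$minCount)
        if (!is.null(d))
          .writeTsv(alleleRecords(tables[[sp]]),
                    file.path(d, paste0("alleles_", sp, ".tsv")))
      }
      if (!is.null(d))
        jsonlite::write_json(
          lapply(tables, function(t) list(species = t@speciesLabel,
                                          totalMapped = totalMapped(t))),
          file.path(d, "totals.json"), auto_unbox = TRUE, digits = NA)
      tables
    })
  }

  if (isTRUE(stages[["classify"]]) && !is.null(report$profile)) {
    report$classify <- grab("classify", {
      d <- mkStageDir("classify")
      dom <- vapply(report$profile, function(t)
        alleleRecords(t)$allele[1], "")
      dom <- gsub("-", "", dom)
      rules <- tryCatch(deriveRules(dom), error = function(e) {
        # a marker that does not separate every species pair is a data
        # outcome, not a configuration error
        warning("rank-1 marker not diagnostic for all species: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(rules)) list(rules = NULL, calls = NULL)
      else {
        calls <- lapply(names(dom), function(sp)
          classifyQuery(dom[[sp]], rules,
                        maxBackgroundDivergence = p$maxBackgroundDivergence))
        names(calls) <- names(dom)
        if (!is.null(d)) {
          writeRules(rules, file.path(d, "rules.json"))
          .writeTsv(data.frame(query = names(dom),
                               label = vapply(calls, `[[`, "", "label")),
                    file.path(d, "classifications.tsv"))
        }
        list(rules = rules, calls = calls)
      }
    })
  }

  report$warnings <- warnings
  if (!is.null(outDir))
    jsonlite::write_json(
      c(report$provenance, list(warnings = warnings)),
      file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  report
}
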