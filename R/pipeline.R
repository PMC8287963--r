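#' @include synthetic.R
NULL

#' Assemble a pipeline run configuration
#'
#' Collects every input and parameter of a full scan / context /
#' permutation run into one serializable list, so a saved configuration
#' re-runs to identical outputs. A YAML file with the same keys can be
#' loaded with [readRunConfig()]; flags given here override file values.
#'
#' @param genomeFasta Path to the genome FASTA (multi-record assemblies
#'   supported: chromosome plus plasmids).
#' @param annotation Optional path to a GFF3 or BED annotation.
#' @param annotationDialect "gff3" or "bed".
#' @param tssTables Character vector of TSS table paths (one per source).
#' @param motifs Character vector of motif strings in bipartite notation.
#' @param width Promoter window width (default 50).
#' @param B Permutation replicates (default 10000).
#' @param seed Global seed; per-stage seeds are split from it.
#' @param mode Overlap mode, "span" or "start".
#' @param statistic Permutation statistic, "windows" or "pairs".
#' @param mTests Bonferroni multiplier; defaults to
#'   `length(motifs) * length(tssTables)`.
#' @param restrictToLargest Count sites on the largest record only
#'   (chromosome-only mode) instead of summing across records.
#' @param outDir Output directory.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(genomeFasta, annotation = NULL,
                      annotationDialect = "gff3",
                      tssTables = character(0), motifs, width = 50L,
                      B = 10000L, seed = 1L,
                      mode = c("span", "start"),
                      statistic = c("windows", "pairs"), mTests = NULL,
                      restrictToLargest = FALSE, outDir = ".") {
  cfg <- list(genomeFasta = genomeFasta, annotation = annotation,
              annotationDialect = annotationDialect,
              tssTables = as.character(tssTables),
              motifs = as.character(motifs), width = as.integer(width),
              B = as.integer(B), seed = as.integer(seed),
              mode = match.arg(mode), statistic = match.arg(statistic),
              mTests = if (is.null(mTests)) NULL else as.integer(mTests),
              restrictToLargest = isTRUE(restrictToLargest),
              outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [runConfig()]
#'   arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

# one global seed expands into per-(motif x TSS-set) permutation seeds
.splitSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full site-distribution pipeline
#'
#' Orchestrates scan, genomic context and the circular-shift permutation
#' test: scans every motif on the genome (summing duplex site counts
#' across records, or chromosome-only), classifies sites as genic or
#' intergenic against the annotation, computes the ORF promoter-site
#' fraction, and runs the rotation permutation test for every motif x
#' TSS-source pair with Bonferroni correction across the whole grid.
#' Writes per-motif site BED files, a context summary TSV, an enrichment
#' results TSV and a JSON run manifest (seed, package version,
#' configuration hash) into `outDir`. Progress is logged to standard
#' error; results go to files and the returned object only. Identical
#' configuration and seed reproduce the outputs byte for byte.
#'
#' @param config A `"RunConfig"` from [runConfig()] or [readRunConfig()].
#' @return Invisibly, a list with `sites` (per motif), `summary` (context
#'   data frame), `enrichment` (results data frame) and `results` (the
#'   [EnrichmentResult-class] objects).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  message("reading genome: ", config$genomeFasta)
  genomes <- readFasta(config$genomeFasta)
  lens <- vapply(genomes, genomeLength, integer(1))
  main <- genomes[[which.max(lens)]]
  L <- genomeLength(main)
  motifs <- lapply(config$motifs, parseMotif)

  features <- NULL
  if (!is.null(config$annotation)) {
    message("reading annotation: ", config$annotation)
    features <- readAnnotation(config$annotation,
                               config$annotationDialect)
  }
  tssSets <- lapply(config$tssTables, readTssTable,
                    genomeId = genomeId(main))

  message("scanning ", length(motifs), " motif(s)")
  useGenomes <- if (config$restrictToLargest) list(main) else genomes
  siteTabs <- lapply(motifs, function(m) {
    do.call(rbind, lapply(useGenomes, scanGenome, motif = m))
  })
  names(siteTabs) <- vapply(motifs, motifLabel, character(1))
  for (lab in names(siteTabs)) {
    bed <- file.path(config$outDir,
                     paste0("sites_", gsub("[^A-Za-z0-9]+", "_", lab),
                            ".bed"))
    writeSitesBed(siteTabs[[lab]], bed, L = L)
  }

  mainSites <- lapply(siteTabs, function(s)
    s[s$genome_id == genomeId(main), , drop = FALSE])
  summary <- if (!is.null(features)) {
    contextSummary(do.call(rbind, mainSites), features,
                   width = config$width, L = L,
                   circular = isCircular(main), mode = config$mode,
                   labels = names(siteTabs))
  } else {
    data.frame(motif_label = names(siteTabs),
               n_sites = vapply(siteTabs, nrow, integer(1)),
               n_genic = NA_integer_, n_intergenic = NA_integer_,
               n_promoter_hits = NA_integer_,
               fraction_orfs_with_promoter_site = NA_real_,
               stringsAsFactors = FALSE)
  }
  write.table(summary, file.path(config$outDir, "context_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  grid <- expand.grid(motif = seq_along(motifs),
                      tss = seq_along(tssSets))
  m <- config$mTests %||% max(1L, nrow(grid))
  seeds <- .splitSeeds(config$seed, max(1L, nrow(grid)))
  results <- list()
  enrichment <- NULL
  if (nrow(grid) > 0L) {
    message("permutation test: ", nrow(grid), " motif x TSS-set pairs, B = ",
            config$B)
    results <- lapply(seq_len(nrow(grid)), function(i) {
      mi <- grid$motif[i]; ti <- grid$tss[i]
      runPermutation(mainSites[[mi]], tssSets[[ti]], L = L,
                     width = config$width, B = config$B,
                     seed = seeds[i], mode = config$mode,
                     statistic = config$statistic, mTests = m,
                     label = names(siteTabs)[mi])
    })
    enrichment <- do.call(rbind, lapply(results, function(r)
      data.frame(motif = r@motifLabel, tss_source = r@tssSource,
                 observed = r@observed, B = r@B, k_le = r@kLe,
                 k_ge = r@kGe, p_depletion = r@pDepletion,
                 p_enrichment = r@pEnrichment, p_adjusted = r@pAdjusted,
                 m_tests = r@mTests, seed = r@seed,
                 stringsAsFactors = FALSE)))
    write.table(enrichment,
                file.path(config$outDir, "enrichment_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(
    package = "MethylSites",
    version = as.character(utils::packageVersion("MethylSites")),
    seed = config$seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    genome_records = setNames(as.list(lens), names(genomes)),
    site_counts = setNames(lapply(siteTabs, nrow), names(siteTabs)))
  unlink(tmp)
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  message("done; outputs in ", config$outDir)
  invisible(list(sites = siteTabs, summary = summary,
                 enrichment = enrichment, results = results))
}
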