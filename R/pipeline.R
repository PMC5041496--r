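## End-to-end orchestration: read inputs, run every analysis stage, write
## result tables plus a reproducibility manifest.

#' Assemble a pipeline configuration
#'
#' @param counts,samples Paths to the count table and sample sheet TSVs.
#' @param genome,genes Paths to the genome FASTA and gene-model BED12
#'   (required for the RNA-map and conservation stages).
#' @param events Path to an event table TSV (`event_id`, `gene_id`,
#'   `exon_index`) mapping count-table events to gene models.
#' @param maf,tree Paths to the MAF alignments and Newick species tree
#'   (required for the conservation and GO stages); `reference` names the
#'   reference species.
#' @param go Path to the gene-to-GO map TSV.
#' @param out Output directory.
#' @param reference Reference species for the MAF.
#' @param wt_group,dko_group,control_group Group labels of the wild-type,
#'   double-knockout and mock (GFP) samples.
#' @param homolog_groups Group labels of the homolog-reconstituted lines.
#' @param bf_min,dpsi_min,z_min Regulated-event thresholds.
#' @param window RNA-map intronic window (nt).
#' @param flank Conservation flank window (nt).
#' @param alpha,min_species Cross-species intersection parameters.
#' @param seed Integer seed recorded in the manifest.
#' @return Validated configuration list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(counts, samples, out,
                           genome = NULL, genes = NULL, events = NULL,
                           maf = NULL, tree = NULL, go = NULL,
                           reference = "ref",
                           wt_group = "WT", dko_group = "DKO",
                           control_group = "GFP",
                           homolog_groups = c("Hs", "Ci", "Dm", "Ce", "Ta"),
                           bf_min = 5, dpsi_min = 0.1, z_min = 1.5,
                           window = 250L, flank = 150L,
                           alpha = 0.01, min_species = 4L, seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(cfg$bf_min, cfg$dpsi_min, cfg$z_min, cfg$window, cfg$flank,
            cfg$alpha) <= 0))
    stop("thresholds must be positive")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()] arguments.
#' @return A `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: quantification and regulated-event calling (WT vs DKO, each
#' homolog vs mock), homolog agreement and rescue correlations, RNA-map
#' enrichment matrix, branch-length conservation scores, and GO
#' enrichment.  Stages whose inputs are absent from the configuration are
#' skipped.  Every output TSV is accompanied by a `manifest.json`
#' recording the configuration hash, seed and stage versions; re-running
#' with an identical configuration reproduces identical files.
#'
#' @param config A [pipelineConfig()] (or path to its YAML file).
#' @return Invisibly, a named list of the result objects.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  thresholds <- list(bf_min = config$bf_min, dpsi_min = config$dpsi_min,
                     z_min = config$z_min)

  sc <- .stage("splice_quant", {
    ct <- readCountTable(config$counts)
    ss <- readSampleSheet(config$samples)
    SpliceCounts(ct, ss)
  })
  results$psi <- .stage("splice_quant", quantifyPsi(sc))
  .writeTsv(results$psi, file.path(config$out, "psi.tsv"))

  refCalls <- .stage("splice_quant",
                     compareGroups(sc, config$wt_group, config$dko_group,
                                   thresholds))
  homGroups <- intersect(config$homolog_groups,
                         unique(colData(sc)$group))
  homCalls <- lapply(homGroups, function(h)
    .stage("splice_quant",
           compareGroups(sc, h, config$control_group, thresholds)))
  names(homCalls) <- homGroups
  allCalls <- rbind(refCalls, do.call(rbind, homCalls))
  results$calls <- allCalls
  .writeTsv(allCalls[, c("event_id", "comparison", "delta_psi", "z",
                         "bf", "direction", "significant")],
            file.path(config$out, "calls.tsv"))

  results$agreement <- .stage("splice_quant",
                              agreementSummary(refCalls, homCalls))
  .writeTsv(results$agreement, file.path(config$out, "agreement.tsv"))

  results$correlations <- .stage("splice_quant", {
    do.call(rbind, lapply(homGroups, function(h) {
      hc <- homCalls[[h]]
      sig <- refCalls$significant | hc$significant
      if (sum(sig, na.rm = TRUE) < 3L) return(NULL)
      cc <- rescueCorrelation(refCalls$delta_psi[sig],
                              hc$delta_psi[sig],
                              paste0(h, "-rescue"))
      data.frame(comparison = cc$comparison, r_squared = cc$r_squared,
                 n_events = cc$n_events, stringsAsFactors = FALSE)
    }))
  })
  if (!is.null(results$correlations))
    .writeTsv(results$correlations,
              file.path(config$out, "correlations.tsv"))

  haveGenome <- !is.null(config$genome) && !is.null(config$genes) &&
    !is.null(config$events)
  genome <- NULL; gm <- NULL; eventTable <- NULL
  if (haveGenome) {
    genome <- .stage("formats_io", readGenomeFasta(config$genome))
    gm <- .stage("formats_io", readGeneModelsBed(config$genes))
    eventTable <- .stage("formats_io",
                         read.delim(config$events,
                                    stringsAsFactors = FALSE))
    results$rna_map <- .stage("motif_map", {
      strata <- stratifyEvents(refCalls, results$agreement)
      setsOf <- function(ids) {
        ids <- intersect(ids, eventTable$event_id)
        lapply(ids, function(ev) {
          row <- eventTable[eventTable$event_id == ev, ]
          extractRegions(gm, row$gene_id, row$exon_index, genome,
                         config$window, event_id = ev)
        })
      }
      byClass <- lapply(strata, setsOf)
      byClass <- byClass[vapply(byClass, length, integer(1)) > 0]
      if (!"unaffected" %in% names(byClass))
        stop("no unaffected events available for the RNA-map contrast")
      rnaMapMatrix(byClass)
    })
    write.table(cbind(class = rownames(results$rna_map),
                      as.data.frame(results$rna_map)),
                file.path(config$out, "rna_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (haveGenome && !is.null(config$maf) && !is.null(config$tree)) {
    cons <- .stage("phylo_conservation", {
      maf <- readMaf(config$maf, config$reference)
      tree <- readSpeciesTree(config$tree)
      conservationScores(gm, genome, maf, tree, flank = config$flank)
    })
    results$conservation <- cons
    .writeTsv(cons$gene_scores,
              file.path(config$out, "conservation_genes.tsv"))
    .writeTsv(cons$intron_scores,
              file.path(config$out, "conservation_introns.tsv"))

    if (!is.null(config$go)) {
      results$go <- .stage("go_enrich", {
        goMap <- readGoMap(config$go)
        dg <- setNames(cons$gene_scores$delta_gene,
                       cons$gene_scores$gene_id)
        goEnrichment(dg, goMap)
      })
      .writeTsv(results$go, file.path(config$out, "go_results.tsv"))
    }
  }

  manifest <- list(
    package = "mblsplice",
    version = as.character(utils::packageVersion("mblsplice")),
    seed = config$seed,
    config_hash = .configHash(config),
    stages = names(results),
    outputs = list.files(config$out, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(x)
                     paste(format(x), collapse = ","), character(1)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
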