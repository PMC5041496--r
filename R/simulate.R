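## Synthetic-data generator: genome and gene models, junction counts with
## planted regulated events and homolog rescue, RNA-map motif injection,
## tree-structured alignments with planted conserved motifs, and a GO map
## with a planted category.  Fully deterministic under a fixed seed.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study: a 3-vs-3
#' WT/DKO replicate design with five single-replicate homolog-reconstituted
#' lines and a GFP control, one skipped-exon event per gene, RNA-map motif
#' injection for regulated events, tree-structured intron-flank alignments
#' with planted conserved motifs, and a GO map with one planted category.
#'
#' @param seed Integer random seed.
#' @param n_genes Number of genes (one skipped-exon event each).
#' @param exons_per_gene Exons per gene (>= 3).
#' @param exon_length,intron_length,intergenic Gene geometry in nt.
#' @param fraction_regulated Fraction of events truly MBNL-regulated.
#' @param true_dpsi True WT-minus-DKO Psi difference of regulated events.
#' @param replicates Named integer vector: replicates for `WT` and `DKO`.
#' @param homolog_efficacy Named numeric vector of rescue efficacies in
#'   `[0, 1]` for the homolog lines (fraction of the WT-DKO difference
#'   restored).
#' @param depth Read depth (isoform draws) per event and sample.
#' @param psi_range Range of baseline Psi values.
#' @param tree_text Newick text of the species tree (branch lengths
#'   mandatory); the first leaf named `reference` must be present.
#' @param reference Reference species leaf label.
#' @param subst_prob Per-site substitution probability per branch for
#'   non-conserved positions.
#' @param gap_rate Per-site probability of a gap in a non-reference row.
#' @param motif_multiplier Target-motif frequency multiplier in the
#'   RNA-map injection regions of regulated events.
#' @param window RNA-map intronic window size (nt).
#' @param flank Conservation flank-window size (nt).
#' @param n_go_categories,go_category_size Random GO categories and their
#'   size.
#' @param n_planted Genes in the planted conserved-motif GO category.
#' @param n_conserved_motifs Target motifs injected into one intron flank
#'   of each planted gene (kept identical in all species).
#' @return Validated list with class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
    seed = 1L,
    n_genes = 500L,
    exons_per_gene = 5L,
    exon_length = 150L,
    intron_length = 700L,
    intergenic = 200L,
    fraction_regulated = 0.1,
    true_dpsi = 0.3,
    replicates = c(WT = 3L, DKO = 3L),
    homolog_efficacy = c(Hs = 1.0, Ci = 0.8, Dm = 0.6, Ce = 0.7, Ta = 0.5),
    depth = 100L,
    psi_range = c(0.15, 0.85),
    tree_text = paste0("(ref:0.08,(sp1:0.09,((sp2:0.18,sp3:0.17):0.05,",
                       "(sp4:0.35,sp5:0.5):0.08):0.04):0.03);"),
    reference = "ref",
    subst_prob = 0.3,
    gap_rate = 0.02,
    motif_multiplier = 3,
    window = 250L,
    flank = 150L,
    n_go_categories = 50L,
    go_category_size = 30L,
    n_planted = 30L,
    n_conserved_motifs = 3L) {
  cfg <- as.list(environment())
  rates <- c(cfg$fraction_regulated, cfg$subst_prob, cfg$gap_rate,
             cfg$homolog_efficacy, cfg$psi_range)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$depth < 1) stop("depth must be >= 1")
  if (cfg$exons_per_gene < 3) stop("genes need at least 3 exons")
  if (cfg$intron_length < 2) stop("infeasible geometry: intron shorter than 2 nt")
  if (cfg$true_dpsi <= 0 || cfg$true_dpsi > diff(cfg$psi_range))
    stop("true_dpsi must be positive and fit inside psi_range")
  tree <- ape::read.tree(text = cfg$tree_text)
  if (is.null(tree) || is.null(tree$edge.length))
    stop("tree_text must be Newick with branch lengths")
  if (!cfg$reference %in% tree$tip.label)
    stop("reference species must be a leaf of the tree")
  if (cfg$n_planted > cfg$n_genes)
    stop("n_planted cannot exceed n_genes")
  structure(cfg, class = "SimulationConfig")
}

.BASES <- c("A", "C", "G", "T")

#' Simulate a genome with gene models and skipped-exon events
#'
#' Generates an i.i.d. uniform background sequence carrying `n_genes` genes
#' on alternating strands, each with `exons_per_gene` exons, and flags one
#' skipped-exon event (the central exon) per gene with its ground-truth
#' regulation class and direction.
#'
#' @param config A [simulationConfig()].
#' @return List with `genome` (`DNAStringSet`), `gene_models`
#'   ([geneModels()]) and `events` (data frame: `event_id`, `gene_id`,
#'   `exon_index`, `class` in activated/repressed/unaffected).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 101L)
  nE <- config$exons_per_gene
  span <- nE * config$exon_length + (nE - 1L) * config$intron_length +
    config$intergenic
  total <- config$n_genes * span + config$intergenic
  chrom <- "chr1"
  seq <- paste(sample(.BASES, total, replace = TRUE), collapse = "")
  genome <- DNAStringSet(setNames(seq, chrom))
  rows <- list()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%04d", g)
    offset <- (g - 1L) * span + config$intergenic
    starts <- offset +
      (seq_len(nE) - 1L) * (config$exon_length + config$intron_length)
    rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = gid, chrom = chrom,
      strand = if (g %% 2L == 0L) "-" else "+",
      start = starts, end = starts + config$exon_length,
      stringsAsFactors = FALSE)
  }
  gm <- geneModels(do.call(rbind, rows))
  nReg <- round(config$fraction_regulated * config$n_genes)
  classes <- rep("unaffected", config$n_genes)
  if (nReg > 0) {
    regIdx <- sample(config$n_genes, nReg)
    classes[regIdx] <- sample(c("activated", "repressed"), nReg,
                              replace = TRUE)
  }
  skipIdx <- (nE + 1L) %/% 2L   # central exon is the cassette
  events <- data.frame(
    event_id = sprintf("ev%04d", seq_len(config$n_genes)),
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    exon_index = skipIdx, class = classes, stringsAsFactors = FALSE)
  list(genome = genome, gene_models = gm, events = events)
}

#' Ground-truth Psi per event and sample group
#'
#' Assigns each event a true Psi per group: unaffected events share one
#' baseline everywhere; regulated events differ by `true_dpsi` between WT
#' and DKO (sign by direction), and each homolog line restores its
#' efficacy fraction of the WT-DKO difference on top of the DKO level.
#' The GFP line matches DKO.
#'
#' @param config A [simulationConfig()].
#' @param events Event table from [simulateGenome()].
#' @return Data frame: `event_id`, one column per group (WT, DKO, GFP and
#'   each homolog).
#' @export
simulateTruePsi <- function(config, events) {
  set.seed(config$seed + 202L)
  n <- nrow(events)
  lo <- config$psi_range[1L]; hi <- config$psi_range[2L]
  d <- config$true_dpsi
  base <- runif(n, lo, hi - d)
  wt <- ifelse(events$class == "activated", base + d,
               ifelse(events$class == "repressed", base, base))
  dko <- ifelse(events$class == "activated", base,
                ifelse(events$class == "repressed", base + d, base))
  out <- data.frame(event_id = events$event_id, WT = wt, DKO = dko,
                    GFP = dko, stringsAsFactors = FALSE)
  for (h in names(config$homolog_efficacy)) {
    out[[h]] <- dko + config$homolog_efficacy[[h]] * (wt - dko)
  }
  out
}

#' Simulate a junction count table
#'
#' Draws, for each event and sample, the number of inclusion-isoform reads
#' from `Binomial(depth, truePsi)` and reports junction counts with the
#' junction weighting inverted (inclusion reads multiplied by the number
#' of inclusion junctions) so that [estimatePsi()] is unbiased.
#'
#' @param config A [simulationConfig()].
#' @param truePsi Data frame from [simulateTruePsi()].
#' @return List with `count_table` (long format, see [readCountTable()])
#'   and `sample_sheet` (`sample_id`, `group`).
#' @export
simulateCounts <- function(config, truePsi) {
  set.seed(config$seed + 303L)
  groups <- c(rep("WT", config$replicates[["WT"]]),
              rep("DKO", config$replicates[["DKO"]]),
              "GFP", names(config$homolog_efficacy))
  sampleIds <- c(
    paste0("WT_", seq_len(config$replicates[["WT"]])),
    paste0("DKO_", seq_len(config$replicates[["DKO"]])),
    "GFP_1", paste0(names(config$homolog_efficacy), "_1"))
  ss <- data.frame(sample_id = sampleIds, group = groups,
                   stringsAsFactors = FALSE)
  jw <- JUNCTION_WEIGHTS[JUNCTION_WEIGHTS$event_type == "SE", ]
  rows <- list()
  for (j in seq_along(sampleIds)) {
    psi <- truePsi[[groups[j]]]
    incIso <- rbinom(nrow(truePsi), config$depth, psi)
    rows[[j]] <- data.frame(
      event_id = truePsi$event_id, sample_id = sampleIds[j],
      inclusion_reads = incIso * jw$n_inc_junctions,
      exclusion_reads = (config$depth - incIso) * jw$n_exc_junctions,
      event_type = "SE", stringsAsFactors = FALSE)
  }
  list(count_table = do.call(rbind, rows), sample_sheet = ss)
}

## Write a motif (given on the sense strand of `strand`) into the genome at
## 0-based genomic position p.
.writeMotif <- function(genome, chrom, p, motif, strand) {
  g <- if (strand == "-") revComp(motif) else motif
  subseq(genome[[chrom]], p + 1L, p + nchar(g)) <- DNAString(g)
  genome
}

#' Inject MBNL target motifs into RNA-map regions of regulated events
#'
#' Writes target 4-mers at random non-overlapping positions inside the
#' RNA-map regions dictated by the MBNL RNA map: `skip_down` for activated
#' events; `exon` and `skip_up` for repressed events.  The number of
#' injected copies per region raises the expected target frequency to
#' `motif_multiplier` times the uniform background rate; positions never
#' cross the region (hence exon) boundaries.
#'
#' @param genome Named `DNAStringSet` (modified copy returned).
#' @param gm A [geneModels()] data frame.
#' @param events Event table from [simulateGenome()].
#' @param config A [simulationConfig()].
#' @param targets Target motifs (default [MBNL_TARGET_MOTIFS]).
#' @return The genome with motifs injected.
#' @export
injectMotifs <- function(genome, gm, events, config,
                         targets = MBNL_TARGET_MOTIFS) {
  set.seed(config$seed + 404L)
  bgRate <- length(targets) / 4^4          # expected occurrences per nt
  extraRate <- (config$motif_multiplier - 1) * bgRate
  reg <- events[events$class != "unaffected", , drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    co <- rnaMapRegionCoords(gm, reg$gene_id[i], reg$exon_index[i],
                             config$window)
    regionNames <- if (reg$class[i] == "activated") "skip_down"
                   else c("exon", "skip_up")
    for (rn in regionNames) {
      r <- co[co$region == rn, ]
      len <- r$end - r$start
      if (len < 4L) next
      nInject <- round(extraRate * len)
      if (nInject < 1L) next
      ## non-overlapping placement on a 4-nt grid inside the region
      slots <- seq.int(r$start, r$end - 4L, by = 4L)
      nInject <- min(nInject, length(slots))
      pos <- sample(slots, nInject)
      for (p in pos) {
        genome <- .writeMotif(genome, r$chrom, p,
                              sample(targets, 1L), r$strand)
      }
    }
  }
  genome
}

## Evolve a reference window sequence over the tree: BFS from the
## reference leaf, each traversed branch substituting every non-conserved
## site independently with probability substProb.
.evolveWindow <- function(refChars, tree, reference, substProb,
                          conservedMask) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  adj <- vector("list", nNode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  refTip <- match(reference, tree$tip.label)
  seqs <- vector("list", nNode)
  seqs[[refTip]] <- refChars
  queue <- refTip; visited <- logical(nNode); visited[refTip] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (visited[w]) next
      visited[w] <- TRUE
      child <- seqs[[v]]
      mut <- runif(length(child)) < substProb & !conservedMask
      if (any(mut)) {
        child[mut] <- vapply(child[mut], function(b)
          sample(setdiff(.BASES, b), 1L), character(1))
      }
      seqs[[w]] <- child
      queue <- c(queue, w)
    }
  }
  setNames(lapply(seq_len(nTip), function(i) seqs[[i]]), tree$tip.label)
}

#' Simulate intron-flank multiple alignments
#'
#' Builds one MAF block per conservation flank window of every gene.  The
#' reference row is the genome sequence; every other species' row is
#' evolved by per-site substitution with probability `subst_prob` per
#' branch along the tree, except at positions listed in
#' `conserved_positions`, which are copied unchanged in all species.
#' Non-reference rows additionally receive gaps at `gap_rate`.
#'
#' @param config A [simulationConfig()].
#' @param genome Named `DNAStringSet`.
#' @param gm A [geneModels()] data frame.
#' @param conserved_positions Integer vector of 0-based genomic positions
#'   held identical across species (e.g. planted motif spans).
#' @return List with `maf` (a [MafAlignments-class]) and `tree` (`phylo`).
#' @export
simulateAlignments <- function(config, genome, gm,
                               conserved_positions = integer()) {
  set.seed(config$seed + 505L)
  tree <- ape::read.tree(text = config$tree_text)
  reference <- config$reference
  conserved <- unique(conserved_positions)
  blocks <- list()
  chromLen <- setNames(Biostrings::width(genome), names(genome))
  for (g in unique(gm$gene_id)) {
    fw <- flankWindows(gm, g, size = config$flank)
    for (r in seq_len(nrow(fw))) {
      w <- fw[r, ]
      if (w$end <= w$start) next
      refChars <- strsplit(
        genomeSeq(genome, w$chrom, w$start, w$end, "+"), "")[[1L]]
      mask <- (w$start:(w$end - 1L)) %in% conserved
      tipSeqs <- .evolveWindow(refChars, tree, reference,
                               config$subst_prob, mask)
      rows <- lapply(names(tipSeqs), function(sp) {
        ch <- tipSeqs[[sp]]
        if (sp != reference && config$gap_rate > 0) {
          gaps <- runif(length(ch)) < config$gap_rate & !mask
          ch[gaps] <- "-"
        }
        txt <- paste(ch, collapse = "")
        size <- sum(ch != "-")
        data.frame(species = sp, chrom = w$chrom,
                   start = w$start, size = size, strand = "+",
                   src_size = unname(chromLen[w$chrom]), text = txt,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      ## reference first, as in UCSC MAF convention
      rows <- rows[order(rows$species != reference), , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        rows = rows, ref_chrom = w$chrom,
        ref_start = w$start, ref_end = w$end)
    }
  }
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "ref_start"))]
  list(maf = new("MafAlignments", blocks = blocks, reference = reference),
       tree = tree)
}

#' Plant conserved target motifs in a gene set
#'
#' Injects `n_conserved_motifs` target 4-mers into the first intron-flank
#' window of each planted gene and returns every genomic position covered
#' by a target-motif occurrence in any flank window of those genes, to be
#' held fixed across species by [simulateAlignments()].
#'
#' @param genome Named `DNAStringSet`.
#' @param gm A [geneModels()] data frame.
#' @param planted_genes Character vector of gene ids.
#' @param config A [simulationConfig()].
#' @param targets Target motifs.
#' @return List with `genome` (motifs injected) and `conserved_positions`
#'   (0-based genomic positions).
#' @export
plantConservedMotifs <- function(genome, gm, planted_genes, config,
                                 targets = MBNL_TARGET_MOTIFS) {
  set.seed(config$seed + 606L)
  for (g in planted_genes) {
    fw <- flankWindows(gm, g, size = config$flank)
    if (nrow(fw) == 0L) next
    w <- fw[1L, ]
    if (w$end - w$start < 4L) next
    slots <- seq.int(w$start, w$end - 4L, by = 4L)
    n <- min(config$n_conserved_motifs, length(slots))
    for (p in sample(slots, n)) {
      genome <- .writeMotif(genome, w$chrom, p, sample(targets, 1L),
                            w$strand)
    }
  }
  conserved <- integer()
  for (g in planted_genes) {
    fw <- flankWindows(gm, g, size = config$flank)
    for (r in seq_len(nrow(fw))) {
      w <- fw[r, ]
      if (w$end - w$start < 4L) next
      seq <- genomeSeq(genome, w$chrom, w$start, w$end, "+")
      gTargets <- unique(c(targets, revComp(targets)))
      for (m in gTargets) {
        hits <- start(matchPattern(m, DNAString(seq), fixed = TRUE))
        for (s in hits)
          conserved <- c(conserved, (w$start + s - 1L):(w$start + s + 2L))
      }
    }
  }
  list(genome = genome, conserved_positions = unique(conserved))
}

#' Simulate a gene-to-GO map with one planted category
#'
#' Random category memberships of fixed size, plus one planted category
#' whose members are exactly the supplied conserved-motif genes.
#'
#' @param config A [simulationConfig()].
#' @param gene_ids All gene ids.
#' @param planted_genes Members of the planted category.
#' @return Data frame (`gene_id`, `go_id`, `go_name`); the planted
#'   category id is `GO:PLANTED`.
#' @export
simulateGo <- function(config, gene_ids, planted_genes) {
  set.seed(config$seed + 707L)
  rows <- lapply(seq_len(config$n_go_categories), function(k) {
    data.frame(gene_id = sample(gene_ids,
                                min(config$go_category_size,
                                    length(gene_ids))),
               go_id = sprintf("GO:%07d", k),
               go_name = sprintf("random_category_%02d", k),
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    gene_id = planted_genes, go_id = "GO:PLANTED",
    go_name = "planted_conserved_set", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulate the complete synthetic study
#'
#' Runs every generator stage in order: genome and gene models, RNA-map
#' motif injection, planted conserved motifs, true Psi and junction
#' counts, intron-flank alignments, and the GO map.
#'
#' @param config A [simulationConfig()].
#' @param alignments Generate the (comparatively expensive) alignments and
#'   conservation inputs (default TRUE).
#' @return List with `config`, `genome`, `gene_models`, `events`,
#'   `true_psi`, `count_table`, `sample_sheet`, `maf`, `tree`, `go_map`,
#'   `planted_genes`.
#' @export
simulateStudy <- function(config = simulationConfig(), alignments = TRUE) {
  gen <- simulateGenome(config)
  genome <- injectMotifs(gen$genome, gen$gene_models, gen$events, config)
  set.seed(config$seed + 808L)
  planted <- sort(sample(unique(gen$gene_models$gene_id),
                         config$n_planted))
  maf <- NULL; tree <- ape::read.tree(text = config$tree_text)
  if (alignments) {
    pl <- plantConservedMotifs(genome, gen$gene_models, planted, config)
    genome <- pl$genome
    al <- simulateAlignments(config, genome, gen$gene_models,
                             pl$conserved_positions)
    maf <- al$maf; tree <- al$tree
  }
  truePsi <- simulateTruePsi(config, gen$events)
  cnt <- simulateCounts(config, truePsi)
  goMap <- simulateGo(config, unique(gen$gene_models$gene_id), planted)
  list(config = config, genome = genome, gene_models = gen$gene_models,
       events = gen$events, true_psi = truePsi,
       count_table = cnt$count_table, sample_sheet = cnt$sample_sheet,
       maf = maf, tree = tree, go_map = goMap, planted_genes = planted)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param study Output of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    tree = file.path(dir, "tree.nwk"),
    go = file.path(dir, "go_map.tsv"),
    events = file.path(dir, "events.tsv"))
  writeGenomeFasta(study$genome, paths["genome"])
  writeGeneModelsBed(study$gene_models, paths["genes"])
  writeCountTable(study$count_table, paths["counts"])
  write.table(study$sample_sheet, paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSpeciesTree(study$tree, paths["tree"])
  write.table(study$go_map, paths["go"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$events, paths["events"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(study$maf)) {
    paths["maf"] <- file.path(dir, "alignments.maf")
    writeMaf(study$maf, paths["maf"])
  }
  paths
}
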