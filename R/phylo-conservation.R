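## Branch-length conservation of MBNL-binding 4-mers in intronic flanks:
## flank windows, spanning branch length of conserving species,
## delta-intron and delta-gene scores.

#' Intronic flank windows around internal exons
#'
#' For each internal exon of a gene, the window of up to `size` nt of
#' intron immediately upstream and immediately downstream of the exon on
#' the sense strand.  The two windows of one intron never overlap: when an
#' intron is shorter than `2 * size` and carries windows on both ends, each
#' gets `floor(intron/2)` nt; a lone window is truncated to the intron.
#'
#' @param gm A [geneModels()] data frame.
#' @param gene_id Gene identifier.
#' @param size Window size in nt (default 150).
#' @return Data frame with columns `gene_id`, `intron_index`
#'   (transcript-order intron number), `side`
#'   (`downstream_of_exon`/`upstream_of_exon`), `chrom`, `start`, `end`
#'   (0-based half-open genomic), `strand`.  Empty for genes with fewer
#'   than 3 exons.
#' @export
flankWindows <- function(gm, gene_id, size = 150) {
  e <- txExons(gm, gene_id)
  n <- nrow(e)
  empty <- data.frame(gene_id = character(), intron_index = integer(),
                      side = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  strand <- e$strand[1L]; chrom <- e$chrom[1L]
  rows <- list()
  for (j in seq_len(n - 1L)) {
    ## transcript intron j lies between tx exons j and j+1
    bounds <- if (strand == "+") c(e$end[j], e$start[j + 1L])
              else c(e$end[j + 1L], e$start[j])
    len <- bounds[2L] - bounds[1L]
    hasHead <- j >= 2L            # downstream of internal exon j
    hasTail <- (j + 1L) <= n - 1L # upstream of internal exon j+1
    if (!hasHead && !hasTail) next
    w <- if (hasHead && hasTail) {
      if (len >= 2L * size) size else len %/% 2L
    } else min(size, len)
    ## transcript head of the intron is genomic left on +, right on -
    headIv <- if (strand == "+") c(bounds[1L], bounds[1L] + w)
              else c(bounds[2L] - w, bounds[2L])
    tailIv <- if (strand == "+") c(bounds[2L] - w, bounds[2L])
              else c(bounds[1L], bounds[1L] + w)
    if (hasHead)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, intron_index = j, side = "downstream_of_exon",
        chrom = chrom, start = headIv[1L], end = headIv[2L],
        strand = strand, stringsAsFactors = FALSE)
    if (hasTail)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, intron_index = j, side = "upstream_of_exon",
        chrom = chrom, start = tailIv[1L], end = tailIv[2L],
        strand = strand, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Total branch length of the minimal spanning subtree of a leaf set
#'
#' Sum of the branch lengths of all edges whose bipartition separates at
#' least one chosen leaf from another; this is the length of the minimal
#' subtree connecting the leaves.  Zero or one leaf spans length 0.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param leaves Character vector of leaf labels.
#' @return Non-negative spanning branch length.
#' @export
spanningBranchLength <- function(tree, leaves) {
  leaves <- unique(leaves)
  if (length(leaves) <= 1L) return(0)
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx))
    stop("leaf label(s) not in tree: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  nTip <- length(tree$tip.label)
  ## tips below each node, by postorder accumulation over the edge matrix
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) below[[i]] <- i
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]; ch <- post$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  sel <- logical(nTip); sel[idx] <- TRUE
  total <- 0
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    tipsBelow <- below[[ch]]
    nIn <- sum(sel[tipsBelow])
    if (nIn >= 1L && nIn < length(idx)) total <- total + tree$edge.length[k]
  }
  total
}

## Character matrix [species x positions] of aligned bases over a
## reference interval; NA marks gaps and unaligned positions.
.alignedMatrix <- function(maf, chrom, start, end, species) {
  npos <- end - start
  m <- matrix(NA_character_, length(species), npos,
              dimnames = list(species, NULL))
  for (b in maf@blocks) {
    if (b$ref_chrom != chrom || b$ref_end <= start || b$ref_start >= end)
      next
    refText <- b$rows$text[b$rows$species == maf@reference][1L]
    refChars <- strsplit(refText, "")[[1L]]
    nonGap <- which(refChars != "-")
    refPos <- b$ref_start + seq_along(nonGap) - 1L   # 0-based ref positions
    keep <- refPos >= start & refPos < end
    if (!any(keep)) next
    cols <- nonGap[keep]
    outCols <- refPos[keep] - start + 1L
    for (r in seq_len(nrow(b$rows))) {
      sp <- b$rows$species[r]
      if (!sp %in% species) next
      ch <- strsplit(b$rows$text[r], "")[[1L]][cols]
      ch[ch == "-"] <- NA_character_
      m[sp, outCols] <- ch
    }
  }
  m
}

#' Conserved occurrences of a motif in one flank window
#'
#' Finds every occurrence of the motif in the reference window (on the
#' sense strand), determines which non-reference species conserve it (all
#' four aligned columns present, gap-free and spelling the identical
#' motif), and records the spanning branch length of the reference plus
#' conserving leaves.  Occurrences straddling block boundaries are
#' evaluated by stitching adjacent blocks; reference positions unaligned in
#' every species yield an empty species set (spanning length 0).
#'
#' @param window List or one-row data frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open genomic interval).
#' @param motif A 4-mer on the sense strand.
#' @param maf A [MafAlignments-class] object (reference on + strand).
#' @param tree A `phylo` species tree containing the reference leaf.
#' @param genome Named `DNAStringSet` of the reference genome.
#' @return Data frame with one row per occurrence: `position` (0-based
#'   genomic start), `motif`, `n_conserving`, `spanning_branch_length`,
#'   and a list-column `species` of conserving species.
#' @export
occurrenceBranchLength <- function(window, motif, maf, tree, genome) {
  .windowOccurrences(window, as.character(motif), maf, tree, genome)
}

## Shared engine: occurrences of several motifs in one window, one
## substring pass for all motifs.  alignedM may be precomputed; spanCache
## (an environment) memoises spanning lengths per conserving-set key.
.windowOccurrences <- function(window, motifs, maf, tree, genome,
                               alignedM = NULL, spanCache = NULL) {
  reference <- maf@reference
  others <- setdiff(tree$tip.label, reference)
  chrom <- window$chrom; start <- window$start; end <- window$end
  strand <- window$strand
  emptyOcc <- data.frame(position = integer(), motif = character(),
                         n_conserving = integer(),
                         spanning_branch_length = numeric(),
                         stringsAsFactors = FALSE)
  emptyOcc$species <- I(list())
  k <- unique(nchar(motifs))
  stopifnot(length(k) == 1L)
  npos <- end - start
  if (npos < k) return(emptyOcc)
  ## genomic-strand spelling of each sense-strand motif
  gMotifs <- if (strand == "-") revComp(motifs) else motifs
  refSeq <- genomeSeq(genome, chrom, start, end, "+")
  words <- substring(refSeq, 1:(npos - k + 1L), k:npos)
  hits <- which(words %in% gMotifs)
  if (!length(hits)) return(emptyOcc)
  if (is.null(alignedM))
    alignedM <- .alignedMatrix(maf, chrom, start, end, others)
  ## per-species aligned words (NA when any of the k columns is a gap or
  ## unaligned)
  spWords <- NULL
  if (length(others)) {
    spWords <- matrix(NA_character_, length(others), npos - k + 1L,
                      dimnames = list(others, NULL))
    for (sp in others) {
      ch <- alignedM[sp, ]
      na <- is.na(ch)
      bad <- rep(FALSE, npos - k + 1L)
      w <- rep("", npos - k + 1L)
      for (off in seq_len(k)) {
        idx <- off:(npos - k + off)
        bad <- bad | na[idx]
        w <- paste0(w, ifelse(na[idx], "", ch[idx]))
      }
      w[bad] <- NA_character_
      spWords[sp, ] <- w
    }
  }
  pos <- integer(length(hits)); nCon <- integer(length(hits))
  lens <- numeric(length(hits)); spList <- vector("list", length(hits))
  senseMotif <- character(length(hits))
  for (i in seq_along(hits)) {
    s <- hits[i]
    word <- words[s]
    conserving <- if (length(others))
      others[!is.na(spWords[, s]) & spWords[, s] == word] else character()
    key <- paste0("k:", paste(sort(conserving), collapse = ","))
    len <- if (!is.null(spanCache) && !is.null(spanCache[[key]])) {
      spanCache[[key]]
    } else {
      v <- spanningBranchLength(tree, c(reference, conserving))
      if (!is.null(spanCache)) assign(key, v, envir = spanCache)
      v
    }
    pos[i] <- start + s - 1L
    senseMotif[i] <- motifs[match(word, gMotifs)]
    nCon[i] <- length(conserving)
    lens[i] <- len
    spList[[i]] <- conserving
  }
  out <- data.frame(position = pos, motif = senseMotif,
                    n_conserving = nCon, spanning_branch_length = lens,
                    stringsAsFactors = FALSE)
  out$species <- I(spList)
  out
}

#' Per-intron conservation score
#'
#' Mean spanning branch length over all target-motif occurrences in the
#' intron's two flank windows, minus the same mean over all control-motif
#' occurrences.
#'
#' @param target_lengths,control_lengths Numeric vectors of spanning branch
#'   lengths for target and control occurrences of one intron.
#' @return `delta_intron`; `NA` when either occurrence pool is empty.
#' @export
deltaIntron <- function(target_lengths, control_lengths) {
  if (length(target_lengths) == 0L || length(control_lengths) == 0L)
    return(NA_real_)
  mean(target_lengths) - mean(control_lengths)
}

#' Gene-level conservation score
#'
#' The largest defined per-intron score of the gene.
#'
#' @param per_intron_scores Numeric vector of `delta_intron` values (may
#'   contain `NA`).
#' @return `delta_gene`; `NA` when no intron scored.
#' @export
deltaGene <- function(per_intron_scores) {
  ok <- per_intron_scores[!is.na(per_intron_scores)]
  if (length(ok) == 0L) return(NA_real_)
  max(ok)
}

#' Branch-length conservation scores for a set of genes
#'
#' Runs the full conservation analysis: flank windows around internal
#' exons, conserved-occurrence branch lengths for target and control
#' motifs, per-intron `delta_intron` and per-gene `delta_gene`.
#'
#' @param gm A [geneModels()] data frame.
#' @param genome Named `DNAStringSet` of the reference genome.
#' @param maf A [MafAlignments-class] object.
#' @param tree A `phylo` species tree (reference leaf included).
#' @param flank Flank window size in nt (default 150).
#' @param targets Target motifs (default [MBNL_TARGET_MOTIFS]).
#' @param controls Control motifs (default [controlMotifSet()]).
#' @return List with `gene_scores` (`gene_id`, `best_intron`, `delta_gene`)
#'   and `intron_scores` (`gene_id`, `intron_index`, `delta_intron`,
#'   `n_target_occ`, `n_control_occ`).
#' @export
conservationScores <- function(gm, genome, maf, tree, flank = 150,
                               targets = MBNL_TARGET_MOTIFS,
                               controls = controlMotifSet(targets)) {
  if (!maf@reference %in% tree$tip.label)
    stop("reference species '", maf@reference, "' is not a leaf of the tree")
  others <- setdiff(tree$tip.label, maf@reference)
  spanCache <- new.env(parent = emptyenv())
  intronRows <- list(); geneRows <- list()
  for (g in unique(gm$gene_id)) {
    fw <- flankWindows(gm, g, size = flank)
    if (nrow(fw) == 0L) {
      geneRows[[g]] <- data.frame(gene_id = g, best_intron = NA_integer_,
                                  delta_gene = NA_real_,
                                  stringsAsFactors = FALSE)
      next
    }
    perIntron <- numeric(0); intronIds <- integer(0)
    for (intron in unique(fw$intron_index)) {
      ws <- fw[fw$intron_index == intron, , drop = FALSE]
      tl <- numeric(0); cl <- numeric(0)
      for (r in seq_len(nrow(ws))) {
        w <- ws[r, ]
        if (w$end <= w$start) next
        am <- .alignedMatrix(maf, w$chrom, w$start, w$end, others)
        tocc <- .windowOccurrences(w, targets, maf, tree, genome,
                                   alignedM = am, spanCache = spanCache)
        cocc <- .windowOccurrences(w, controls, maf, tree, genome,
                                   alignedM = am, spanCache = spanCache)
        tl <- c(tl, tocc$spanning_branch_length)
        cl <- c(cl, cocc$spanning_branch_length)
      }
      di <- deltaIntron(tl, cl)
      perIntron <- c(perIntron, di); intronIds <- c(intronIds, intron)
      intronRows[[length(intronRows) + 1L]] <- data.frame(
        gene_id = g, intron_index = intron, delta_intron = di,
        n_target_occ = length(tl), n_control_occ = length(cl),
        stringsAsFactors = FALSE)
    }
    dg <- deltaGene(perIntron)
    best <- if (is.na(dg)) NA_integer_ else
      intronIds[which.max(ifelse(is.na(perIntron), -Inf, perIntron))]
    geneRows[[g]] <- data.frame(gene_id = g, best_intron = best,
                                delta_gene = dg, stringsAsFactors = FALSE)
  }
  list(gene_scores = do.call(rbind, c(geneRows, make.row.names = FALSE)),
       intron_scores = do.call(rbind, c(intronRows,
                                        make.row.names = FALSE)))
}
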