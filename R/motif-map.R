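## RNA-map analysis: five regions around skipped exons, 4-mer counting,
## background-matched control 4-mers, log2 enrichment matrix.

allKmers4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T")
      g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)
      cache <<- apply(g[, 4:1], 1L, paste, collapse = "")
    }
    cache
  }
})

#' A+T base count of a k-mer
#' @param kmer Character vector of DNA k-mers.
#' @return Integer count of A and T letters in each k-mer.
#' @export
atCount <- function(kmer) {
  vapply(strsplit(kmer, ""), function(x) sum(x %in% c("A", "T")),
         integer(1))
}

#' CG-dinucleotide count of a k-mer
#'
#' Number of `CG` dinucleotides among the k-1 dinucleotide slots (the
#' "CpG content" used for background matching).
#'
#' @param kmer Character vector of DNA k-mers.
#' @return Integer counts.
#' @export
cgCount <- function(kmer) {
  vapply(kmer, function(k) {
    n <- nchar(k)
    if (n < 2L) return(0L)
    sum(substring(k, 1:(n - 1L), 2:n) == "CG")
  }, integer(1), USE.NAMES = FALSE)
}

#' Background-matched control 4-mers
#'
#' All 4-mers with the same A+T base count and the same CG-dinucleotide
#' count as the query, excluding the four MBNL target motifs and the query
#' itself.
#'
#' @param kmer A single 4-mer.
#' @param targets Target motifs to exclude (default [MBNL_TARGET_MOTIFS]).
#' @return Character vector of control 4-mers.
#' @export
matchedControls <- function(kmer, targets = MBNL_TARGET_MOTIFS) {
  stopifnot(nchar(kmer) == 4L)
  all4 <- allKmers4()
  sel <- atCount(all4) == atCount(kmer) & cgCount(all4) == cgCount(kmer)
  setdiff(all4[sel], c(targets, kmer))
}

#' Union of matched controls over the MBNL target motifs
#'
#' @param targets Target motifs (default [MBNL_TARGET_MOTIFS]).
#' @return Sorted character vector of control 4-mers (de-duplicated,
#'   excluding all targets).
#' @export
controlMotifSet <- function(targets = MBNL_TARGET_MOTIFS) {
  sort(unique(unlist(lapply(targets, matchedControls, targets = targets))))
}

#' Count overlapping occurrences of a k-mer
#'
#' Overlapping matches are counted; positions containing `N` never match.
#'
#' @param sequence Character or `DNAString` sequence.
#' @param kmer The k-mer to count.
#' @return Integer occurrence count.
#' @examples
#' countKmer("GCGCGC", "GCGC")  # 2 (offsets 0 and 2)
#' @export
countKmer <- function(sequence, kmer) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (nchar(as.character(kmer)) > length(sequence)) return(0L)
  countPattern(as.character(kmer), sequence, fixed = TRUE)
}

#' Count overlapping YGCY motifs
#'
#' Y is a pyrimidine (C or T at the DNA level); overlapping matches are
#' counted and `N` in the sequence never matches.
#'
#' @param sequence Character or `DNAString` sequence.
#' @return Integer occurrence count.
#' @examples
#' countYgcy("TGCTGCT")  # 2 (offsets 0 and 3)
#' @export
countYgcy <- function(sequence) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (length(sequence) < 4L) return(0L)
  countPattern("YGCY", sequence, fixed = "subject")
}

#' Extract the five RNA-map regions around a skipped exon
#'
#' Returns sense-strand sequences of the skipped exon and four intronic
#' windows: just downstream of the upstream constitutive exon, just
#' upstream of the skipped exon, just downstream of the skipped exon, and
#' just upstream of the downstream constitutive exon.  Introns shorter than
#' `2 * window` are split evenly (floor(intron/2) to each side) so the two
#' windows of one intron never overlap.
#'
#' @param gm A [geneModels()] data frame.
#' @param gene_id Gene carrying the event.
#' @param exon_index Transcript-order index of the skipped exon (must have
#'   a flanking exon on each side).
#' @param genome Named `DNAStringSet`.
#' @param window Intronic window size in nt (default 250).
#' @param event_id Optional event identifier (defaults to
#'   `gene_id:exon_index`).
#' @return A [RegionSet-class] object.
#' @export
extractRegions <- function(gm, gene_id, exon_index, genome, window = 250,
                           event_id = NULL) {
  co <- rnaMapRegionCoords(gm, gene_id, exon_index, window)
  seqs <- DNAStringSet(setNames(
    vapply(seq_len(nrow(co)), function(i)
      genomeSeq(genome, co$chrom[i], co$start[i], co$end[i], co$strand[i]),
      character(1)),
    co$region))
  if (is.null(event_id)) event_id <- paste0(gene_id, ":", exon_index)
  new("RegionSet", eventId = event_id, regions = seqs[RNA_MAP_REGIONS],
      window = window)
}

#' Genomic coordinates of the five RNA-map regions
#'
#' The coordinate backbone of [extractRegions()]: 0-based half-open
#' genomic intervals for the five regions around a skipped exon, applying
#' the same even-split rule for short introns.
#'
#' @inheritParams extractRegions
#' @return Data frame with columns `region` (the [RNA_MAP_REGIONS]),
#'   `chrom`, `start`, `end`, `strand`.
#' @export
rnaMapRegionCoords <- function(gm, gene_id, exon_index, window = 250) {
  e <- txExons(gm, gene_id)
  if (exon_index < 2L || exon_index > nrow(e) - 1L)
    stop("event skipped: exon ", exon_index, " of gene ", gene_id,
         " lacks a flanking exon")
  strand <- e$strand[1L]; chrom <- e$chrom[1L]
  up <- e[exon_index - 1L, ]; sk <- e[exon_index, ]; dn <- e[exon_index + 1L, ]
  intronBounds <- function(a, b) {   # a 5' of b in transcript order
    if (strand == "+") c(a$end, b$start) else c(b$end, a$start)
  }
  upIntron <- intronBounds(up, sk)   # between upstream const and skipped
  dnIntron <- intronBounds(sk, dn)   # between skipped and downstream const
  splitW <- function(len) if (len >= 2 * window) window else len %/% 2L
  wUp <- splitW(upIntron[2L] - upIntron[1L])
  wDn <- splitW(dnIntron[2L] - dnIntron[1L])
  ## transcript-direction "head" of an intron is its genomic left end on +
  ## and genomic right end on -
  headIv <- function(intron, w) {
    if (strand == "+") c(intron[1L], intron[1L] + w)
    else c(intron[2L] - w, intron[2L])
  }
  tailIv <- function(intron, w) {
    if (strand == "+") c(intron[2L] - w, intron[2L])
    else c(intron[1L], intron[1L] + w)
  }
  iv <- rbind(up_const_down = headIv(upIntron, wUp),
              skip_up = tailIv(upIntron, wUp),
              exon = c(sk$start, sk$end),
              skip_down = headIv(dnIntron, wDn),
              down_const_up = tailIv(dnIntron, wDn))
  data.frame(region = rownames(iv), chrom = chrom,
             start = as.integer(iv[, 1L]), end = as.integer(iv[, 2L]),
             strand = strand, row.names = NULL, stringsAsFactors = FALSE)
}

## Pooled occurrence frequency of a set of motifs across sequences:
## total occurrences / total nucleotides, averaged per motif.
.meanPooledFreq <- function(seqs, motifs) {
  if (length(seqs) == 0L) return(NA_real_)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  totalNt <- sum(Biostrings::width(seqs))
  if (totalNt == 0) return(NA_real_)
  k <- unique(nchar(motifs))
  if (length(k) == 1L && k == 4L) {
    ## one pass over all 256 words, overlap-counted; words containing N
    ## are never counted, matching countKmer()
    counts <- colSums(oligonucleotideFrequency(seqs, width = 4L))
    perMotif <- counts[motifs]
  } else {
    perMotif <- vapply(motifs, function(m)
      sum(vapply(seq_along(seqs), function(i) countKmer(seqs[[i]], m),
                 integer(1))), numeric(1))
  }
  mean(perMotif / totalNt)
}

#' Log2 RNA-map enrichment for one region
#'
#' Within each event set, enrichment is the mean pooled frequency of the
#' target motifs divided by the mean pooled frequency of the
#' background-matched control motifs (frequencies are pooled occurrences
#' per pooled nucleotide across events).  The returned value is
#' `log2(enrichment(regulated) / enrichment(unaffected))`.
#'
#' @param regulated_regions,unaffected_regions `DNAStringSet` (or character
#'   vector) of the same region extracted from the regulated and unaffected
#'   event sets.
#' @param targets Target motifs (default [MBNL_TARGET_MOTIFS]).
#' @param controls Control motifs (default [controlMotifSet()] of the
#'   targets).
#' @return Log2 enrichment ratio; `NA` when a control frequency is zero.
#' @export
enrichmentLog2 <- function(regulated_regions, unaffected_regions,
                           targets = MBNL_TARGET_MOTIFS,
                           controls = controlMotifSet(targets)) {
  if (length(regulated_regions) == 0L || length(unaffected_regions) == 0L)
    stop("both event sets must be non-empty")
  enr <- function(seqs) {
    ft <- .meanPooledFreq(seqs, targets)
    fc <- .meanPooledFreq(seqs, controls)
    if (!is.finite(ft) || !is.finite(fc) || fc == 0) return(NA_real_)
    ft / fc
  }
  er <- enr(regulated_regions); eu <- enr(unaffected_regions)
  if (!is.finite(er) || !is.finite(eu) || eu == 0 || er == 0)
    return(NA_real_)
  log2(er / eu)
}

#' RNA-map enrichment matrix
#'
#' Builds the heatmap matrix of log2 motif enrichment: one row per
#' regulated event class, one column per RNA-map region, each cell the
#' [enrichmentLog2()] of that class against the unaffected class for that
#' region.
#'
#' @param regionSetsByClass Named list of lists of [RegionSet-class]
#'   objects; must include an `"unaffected"` element.
#' @param targets,controls Motif sets (see [enrichmentLog2()]).
#' @return Numeric matrix, classes (excluding `"unaffected"`) by the five
#'   [RNA_MAP_REGIONS].
#' @export
rnaMapMatrix <- function(regionSetsByClass,
                         targets = MBNL_TARGET_MOTIFS,
                         controls = controlMotifSet(targets)) {
  if (!"unaffected" %in% names(regionSetsByClass))
    stop("regionSetsByClass must include an 'unaffected' class")
  pull <- function(sets, region)
    DNAStringSet(vapply(sets, function(rs)
      as.character(regions(rs)[[region]]), character(1)))
  classes <- setdiff(names(regionSetsByClass), "unaffected")
  m <- matrix(NA_real_, length(classes), length(RNA_MAP_REGIONS),
              dimnames = list(classes, RNA_MAP_REGIONS))
  unaff <- regionSetsByClass[["unaffected"]]
  for (cl in classes) {
    for (rg in RNA_MAP_REGIONS) {
      m[cl, rg] <- enrichmentLog2(pull(regionSetsByClass[[cl]], rg),
                                  pull(unaff, rg), targets, controls)
    }
  }
  m
}

#' Stratify skipped-exon events for the RNA map
#'
#' Groups events as in the homolog-agreement heatmap: regulated between WT
#' and DKO, regulated by 1-2 homologs, regulated by >= 3 homologs, with
#' activated and repressed events kept separate, plus the unaffected pool.
#'
#' @param referenceCalls [compareGroups()] output for WT vs DKO.
#' @param agreement [agreementSummary()] output (or `NULL` to stratify on
#'   the reference comparison only).
#' @return Named list of character vectors of event ids; always includes
#'   `"unaffected"`.
#' @export
stratifyEvents <- function(referenceCalls, agreement = NULL) {
  act <- referenceCalls$event_id[
    referenceCalls$significant & referenceCalls$direction == "activated"]
  rep_ <- referenceCalls$event_id[
    referenceCalls$significant & referenceCalls$direction == "repressed"]
  unaff <- referenceCalls$event_id[!referenceCalls$significant]
  out <- list(activated = act, repressed = rep_, unaffected = unaff)
  if (!is.null(agreement)) {
    n <- agreement$n_homologs_regulating[
      match(referenceCalls$event_id, agreement$event_id)]
    for (cl in c("activated", "repressed")) {
      ids <- out[[cl]]
      nn <- n[match(ids, referenceCalls$event_id)]
      out[[paste0(cl, "_1_2_homologs")]] <- ids[nn >= 1 & nn <= 2]
      out[[paste0(cl, "_3plus_homologs")]] <- ids[nn >= 3]
    }
  }
  out
}
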