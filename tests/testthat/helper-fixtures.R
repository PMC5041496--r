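## Shared fixtures and independent oracles, built in code at test time.

## Deterministic random DNA string.
randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A toy five-exon gene (exon 150 nt, introns 600 nt) embedded in a random
## chromosome, on the requested strand.  Returns list(genome, gm).
toyGene <- function(strand = "+", seed = 42, exon_len = 150,
                    intron_len = 600, n_exons = 5, pad = 100) {
  set.seed(seed)
  span <- n_exons * exon_len + (n_exons - 1) * intron_len + 2 * pad
  genome <- Biostrings::DNAStringSet(stats::setNames(randomDna(span), "chrT"))
  starts <- pad + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  gm <- geneModels(data.frame(
    gene_id = "toy", transcript_id = "toy", chrom = "chrT",
    strand = strand, start = starts, end = starts + exon_len,
    stringsAsFactors = FALSE))
  list(genome = genome, gm = gm)
}

## Mirror a genome and gene models to the opposite strand: the reverse
## complement chromosome with mirrored coordinates carries the identical
## gene on the other strand.
mirrorGene <- function(genome, gm) {
  L <- length(genome[[1]])
  mirrored <- Biostrings::DNAStringSet(stats::setNames(
    revComp(as.character(genome[[1]])), names(genome)[1]))
  gm2 <- gm
  newStart <- L - gm$end
  gm2$end <- L - gm$start
  gm2$start <- newStart
  gm2$strand <- ifelse(gm$strand == "+", "-", "+")
  list(genome = mirrored, gm = geneModels(as.data.frame(gm2)))
}

## Write a MAF file from species rows given as text lines.
writeMafText <- function(lines, path = tempfile(fileext = ".maf")) {
  writeLines(c("##maf version=1", lines), path)
  path
}

## Independent spanning-length oracle: union of edges on the paths from
## the first leaf to every other chosen leaf (unique paths on a tree).
spanningOracle <- function(tree, leaves) {
  leaves <- unique(leaves)
  if (length(leaves) <= 1) return(0)
  idx <- match(leaves, tree$tip.label)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- character(0)
  for (j in idx[-1]) {
    np <- ape::nodepath(tree, idx[1], j)
    keys <- c(keys, edgeKey(np[-length(np)], np[-1]))
  }
  keys <- unique(keys)
  allKeys <- edgeKey(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[allKeys %in% keys])
}

## Brute-force BH step-up adjustment straight from the definition.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Naive overlapping k-mer position scan (N never matches).
naiveCountKmer <- function(sequence, kmer) {
  n <- nchar(sequence); k <- nchar(kmer)
  if (k > n) return(0L)
  sum(vapply(seq_len(n - k + 1L), function(i)
    substr(sequence, i, i + k - 1L) == kmer, logical(1)))
}

## Exact two-sided rank-sum p-value by enumeration of all rank
## assignments (no ties assumed).
enumRanksumP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  wObs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(ix) sum(seq_len(nx + ny)[ix])) -
    nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

## Tiny simulated study shared by several tests.
smallStudy <- function(seed = 7, alignments = FALSE, ...) {
  args <- list(...)
  defaults <- list(n_genes = 30L, n_planted = 5L, n_go_categories = 5L,
                   go_category_size = 5L)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  args$seed <- seed
  cfg <- do.call(simulationConfig, args)
  simulateStudy(cfg, alignments = alignments)
}
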