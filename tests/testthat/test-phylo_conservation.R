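test_that("flank windows cover internal exons and split short introns", {
  tg <- toyGene("+", n_exons = 4, intron_len = 600)
  fw <- flankWindows(tg$gm, "toy", size = 150)
  expect_equal(nrow(fw), 4)
  expect_true(all(fw$end - fw$start == 150))

  tg2 <- toyGene("+", n_exons = 2)
  expect_equal(nrow(flankWindows(tg2$gm, "toy")), 0)

  tg3 <- toyGene("+", n_exons = 5, intron_len = 200)
  fw3 <- flankWindows(tg3$gm, "toy", size = 150)
  ## middle introns carry windows on both ends: 100 nt each, no overlap
  both <- fw3[fw3$intron_index == 2, ]
  expect_equal(nrow(both), 2)
  expect_equal(unique(both$end - both$start), 100)
  expect_lte(min(both$end), max(both$start) + 100)
  ## windows stay inside the intron
  e <- tg3$gm
  expect_true(all(fw3$start >= min(e$start) & fw3$end <= max(e$end)))
})

test_that("flank windows are strand-symmetric", {
  tg <- toyGene("+", n_exons = 5, intron_len = 400)
  mir <- mirrorGene(tg$genome, tg$gm)
  fw <- flankWindows(tg$gm, "toy")
  fwM <- flankWindows(mir$gm, "toy")
  seqsP <- sort(vapply(seq_len(nrow(fw)), function(i)
    genomeSeq(tg$genome, fw$chrom[i], fw$start[i], fw$end[i],
              fw$strand[i]), character(1)))
  seqsM <- sort(vapply(seq_len(nrow(fwM)), function(i)
    genomeSeq(mir$genome, fwM$chrom[i], fwM$start[i], fwM$end[i],
              fwM$strand[i]), character(1)))
  expect_identical(seqsM, seqsP)
})

test_that("spanning branch length matches path sums on the toy tree", {
  tree <- ape::read.tree(text = "(R:1,(A:1,B:1):1);")
  expect_equal(spanningBranchLength(tree, c("R", "A", "B")), 4)
  expect_equal(spanningBranchLength(tree, c("R", "A")), 3)
  expect_equal(spanningBranchLength(tree, "R"), 0)
  expect_equal(spanningBranchLength(tree, character(0)), 0)
  ## two-leaf tree behaves as a single branch
  t2 <- ape::read.tree(text = "(X:0.4,Y:0.6);")
  expect_equal(spanningBranchLength(t2, c("X", "Y")), 1.0)
})

test_that("spanning branch length equals independent oracles on random trees", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    tree <- ape::rtree(n)
    k <- sample(2:n, 1)
    leaves <- sample(tree$tip.label, k)
    mine <- spanningBranchLength(tree, leaves)
    expect_equal(mine, spanningOracle(tree, leaves), tolerance = 1e-12)
    ## second oracle: prune to the leaf set and sum the edges
    pruned <- ape::keep.tip(tree, leaves)
    expect_equal(mine, sum(pruned$edge.length), tolerance = 1e-12)
  }
})

test_that("adding a conserving species never decreases the spanning length", {
  set.seed(19)
  for (i in 1:30) {
    tree <- ape::rtree(6)
    leaves <- sample(tree$tip.label, 2)
    prev <- spanningBranchLength(tree, leaves)
    for (extra in setdiff(tree$tip.label, leaves)) {
      leaves <- c(leaves, extra)
      nxt <- spanningBranchLength(tree, leaves)
      expect_gte(nxt, prev - 1e-12)
      prev <- nxt
    }
  }
})

## Toy alignment: reference window AAGCTTAAACGT with a GCTT at position 2.
toyConsFixture <- function(aText, bText) {
  genome <- Biostrings::DNAStringSet(c(c1 = "AAGCTTAAACGT"))
  tree <- ape::read.tree(text = "(R:1,(A:1,B:1):1);")
  path <- writeMafText(c(
    "a",
    "s R.c1 0 12 + 12 AAGCTTAAACGT",
    sprintf("s A.c1 0 %d + 12 %s", nchar(gsub("-", "", aText)), aText),
    sprintf("s B.c1 0 %d + 12 %s", nchar(gsub("-", "", bText)), bText)))
  list(genome = genome, tree = tree, maf = readMaf(path, "R"),
       window = list(chrom = "c1", start = 0L, end = 12L, strand = "+"))
}

test_that("conserved occurrences span the conserving subtree", {
  ## both species conserve GCTT -> full tree length 4
  fx <- toyConsFixture("AAGCTTAAACGT", "TTGCTTTTTTTT")
  occ <- occurrenceBranchLength(fx$window, "GCTT", fx$maf, fx$tree,
                                fx$genome)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$position, 2)
  expect_equal(occ$spanning_branch_length, 4)

  ## conserved in A only -> R-A path = 3
  fx2 <- toyConsFixture("TTGCTTTTTTTT", "AACCTTAAACGT")
  occ2 <- occurrenceBranchLength(fx2$window, "GCTT", fx2$maf, fx2$tree,
                                 fx2$genome)
  expect_equal(occ2$spanning_branch_length, 3)
  expect_equal(occ2$n_conserving, 1)

  ## present only in the reference -> 0
  fx3 <- toyConsFixture("AACCTTAAACGT", "AAGATTAAACGT")
  occ3 <- occurrenceBranchLength(fx3$window, "GCTT", fx3$maf, fx3$tree,
                                 fx3$genome)
  expect_equal(occ3$spanning_branch_length, 0)

  ## a gap inside the aligned motif breaks conservation
  fx4 <- toyConsFixture("AAG-TTAAACGT", "AAGCTTAAACGT")
  occ4 <- occurrenceBranchLength(fx4$window, "GCTT", fx4$maf, fx4$tree,
                                 fx4$genome)
  expect_equal(occ4$n_conserving, 1)   # only B
  expect_equal(occ4$spanning_branch_length, 3)
})

test_that("occurrences straddling block boundaries are stitched", {
  genome <- Biostrings::DNAStringSet(c(c1 = "AAAAGCTTAAAA"))
  tree <- ape::read.tree(text = "(R:1,(A:1,B:1):1);")
  path <- writeMafText(c(
    "a",
    "s R.c1 0 6 + 12 AAAAGC",
    "s A.c1 0 6 + 12 AAAAGC",
    "s B.c1 0 6 + 12 AAAAGC",
    "a",
    "s R.c1 6 6 + 12 TTAAAA",
    "s A.c1 6 6 + 12 TTAAAA",
    "s B.c1 6 6 + 12 CCAAAA"))
  maf <- readMaf(path, "R")
  win <- list(chrom = "c1", start = 0L, end = 12L, strand = "+")
  occ <- occurrenceBranchLength(win, "GCTT", maf, tree, genome)
  expect_equal(occ$position, 4)
  expect_equal(occ$n_conserving, 1)   # A carries GC|TT across both blocks
  expect_equal(occ$spanning_branch_length, 3)
})

test_that("windows unaligned in all species give empty conserving sets", {
  genome <- Biostrings::DNAStringSet(c(c1 = "AAGCTTAAACGT"))
  tree <- ape::read.tree(text = "(R:1,(A:1,B:1):1);")
  maf <- new("MafAlignments", blocks = list(), reference = "R")
  win <- list(chrom = "c1", start = 0L, end = 12L, strand = "+")
  occ <- occurrenceBranchLength(win, "GCTT", maf, tree, genome)
  expect_equal(occ$n_conserving, 0)
  expect_equal(occ$spanning_branch_length, 0)
})

test_that("minus-strand windows are scanned on the sense strand", {
  ## genomic AAGC at position 2 is sense-strand GCTT for a minus gene
  genome <- Biostrings::DNAStringSet(c(c1 = "TTAAGCTTTTTT"))
  tree <- ape::read.tree(text = "(R:1,(A:1,B:1):1);")
  path <- writeMafText(c(
    "a",
    "s R.c1 0 12 + 12 TTAAGCTTTTTT",
    "s A.c1 0 12 + 12 TTAAGCTTTTTT",
    "s B.c1 0 12 + 12 TTTTTTTTTTTT"))
  maf <- readMaf(path, "R")
  win <- list(chrom = "c1", start = 0L, end = 12L, strand = "-")
  occ <- occurrenceBranchLength(win, "GCTT", maf, tree, genome)
  ## sense GCTT = genomic AAGC at 0-based 2
  expect_true(2 %in% occ$position)
  expect_true(all(occ$motif == "GCTT"))
})

test_that("delta scores follow the mean-difference and max rules", {
  expect_equal(deltaIntron(c(4, 3), c(0, 1, 2)), 3.5 - 1)
  expect_equal(deltaIntron(c(2, 2), c(2, 2, 2)), 0)
  expect_true(is.na(deltaIntron(numeric(0), c(1, 2))))
  expect_true(is.na(deltaIntron(c(1, 2), numeric(0))))
  expect_equal(deltaGene(c(-0.2, 0.9, 0.1)), 0.9)
  expect_true(is.na(deltaGene(c(NA, NA))))
  expect_equal(deltaGene(0.4), 0.4)
  ## delta_gene never decreases when an intron is added
  set.seed(23)
  for (i in 1:20) {
    sc <- runif(sample(1:5, 1), -1, 2)
    expect_gte(deltaGene(c(sc, runif(1, -1, 2))), deltaGene(sc))
  }
})

test_that("planted conserved genes score above the background", {
  st <- smallStudy(seed = 29, alignments = TRUE)
  cons <- conservationScores(st$gene_models, st$genome, st$maf, st$tree)
  dg <- stats::setNames(cons$gene_scores$delta_gene,
                        cons$gene_scores$gene_id)
  expect_identical(cons$gene_scores$delta_gene,
                   vapply(split(cons$intron_scores$delta_intron,
                                cons$intron_scores$gene_id)[
                     cons$gene_scores$gene_id],
                     deltaGene, numeric(1), USE.NAMES = FALSE))
  planted <- st$planted_genes
  others <- setdiff(names(dg), planted)
  expect_gt(min(dg[planted]), stats::quantile(dg[others], 0.75,
                                              na.rm = TRUE))
})
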