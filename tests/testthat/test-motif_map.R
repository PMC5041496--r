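test_that("k-mer counting is overlapping and N-aware", {
  expect_equal(countKmer("GCGCGC", "GCGC"), 2)
  expect_equal(countKmer("AAAA", "GCTT"), 0)
  expect_equal(countKmer("GCNTT", "GCTT"), 0)
  expect_equal(countKmer("ACG", "GCTT"), 0)
  seq10k <- randomDna(10000, seed = 5)
  for (m in c(MBNL_TARGET_MOTIFS, "AAAA", "ATAT")) {
    expect_equal(countKmer(seq10k, m), naiveCountKmer(seq10k, m))
  }
})

test_that("YGCY counting enumerates overlapping pyrimidine contexts", {
  expect_equal(countYgcy("TGCT"), 1)
  expect_equal(countYgcy("TGCTGCT"), 2)
  expect_equal(countYgcy("AGCA"), 0)
  expect_equal(countYgcy("NGCT"), 0)
  ## equals the sum over the four concrete YGCY words for a random sequence
  s <- randomDna(5000, seed = 9)
  concrete <- c("CGCC", "CGCT", "TGCC", "TGCT")
  expect_equal(countYgcy(s), sum(vapply(concrete, naiveCountKmer,
                                        integer(1), sequence = s)))
})

test_that("matched controls share A+T and CG-dinucleotide content", {
  ## full enumeration oracle over all 256 4-mers
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b), 1, paste, collapse = "")
  at <- vapply(all4, function(k)
    sum(strsplit(k, "")[[1]] %in% c("A", "T")), integer(1))
  cg <- vapply(all4, function(k)
    sum(substring(k, 1:3, 2:4) == "CG"), integer(1))

  ctrl <- matchedControls("AAAA")
  expect_length(ctrl, 15)
  expect_setequal(ctrl, setdiff(all4[at == 4], "AAAA"))

  for (t in MBNL_TARGET_MOTIFS) {
    ctrl <- matchedControls(t)
    expect_true(length(ctrl) > 0)
    expect_false(any(MBNL_TARGET_MOTIFS %in% ctrl))
    expect_true(all(at[ctrl] == at[t] & cg[ctrl] == cg[t]))
  }

  gc <- matchedControls("GCGC")
  oracle <- setdiff(all4[at == 0 & cg == cg["GCGC"]],
                    c(MBNL_TARGET_MOTIFS, "GCGC"))
  expect_setequal(gc, oracle)
})

test_that("the (A+T, CG) classes partition the 256 4-mers", {
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b), 1, paste, collapse = "")
  key <- paste(atCount(all4), cgCount(all4))
  expect_equal(sum(table(key)), 256)
  ## each 4-mer lands in exactly one class
  expect_equal(length(all4), length(unique(all4)))
})

test_that("RNA-map regions have the documented coordinates on both strands", {
  tg <- toyGene("+")          # introns 600 nt >= 2 * 250
  rs <- extractRegions(tg$gm, "toy", 3, tg$genome, window = 250)
  w <- Biostrings::width(regions(rs))
  expect_equal(unname(w), c(250, 250, 150, 250, 250))
  ## coordinate arithmetic: regions sit at the intron ends
  co <- rnaMapRegionCoords(tg$gm, "toy", 3, 250)
  e <- tg$gm
  expect_equal(co$start[co$region == "up_const_down"], e$end[2])
  expect_equal(co$end[co$region == "skip_up"], e$start[3])
  expect_equal(co$start[co$region == "skip_down"], e$end[3])
  expect_equal(co$end[co$region == "down_const_up"], e$start[4])

  ## strand symmetry: the mirrored minus-strand gene yields identical
  ## sense-strand sequences
  mir <- mirrorGene(tg$genome, tg$gm)
  rsM <- extractRegions(mir$gm, "toy", 3, mir$genome, window = 250)
  expect_identical(as.character(regions(rsM)), as.character(regions(rs)))
})

test_that("short introns are split evenly without overlap", {
  tg <- toyGene("+", intron_len = 300)
  rs <- extractRegions(tg$gm, "toy", 3, tg$genome, window = 250)
  w <- Biostrings::width(regions(rs))
  expect_equal(unname(w[c(1, 2, 4, 5)]), c(150, 150, 150, 150))
  co <- rnaMapRegionCoords(tg$gm, "toy", 3, 250)
  sd <- co[co$region == "skip_down", ]
  du <- co[co$region == "down_const_up", ]
  expect_lte(sd$end, du$start)   # non-overlapping
})

test_that("log2 enrichment is zero for identical sets and antisymmetric", {
  set.seed(21)
  a <- Biostrings::DNAStringSet(vapply(1:30, function(i) randomDna(250),
                                       character(1)))
  b <- Biostrings::DNAStringSet(vapply(1:30, function(i) randomDna(250),
                                       character(1)))
  expect_equal(enrichmentLog2(a, a), 0)
  e_ab <- enrichmentLog2(a, b)
  expect_equal(enrichmentLog2(b, a), -e_ab)
})

test_that("doubling the target rate gives ~1 log2 unit of enrichment", {
  ## 1e6 nt pools; targets injected into the regulated pool until its
  ## occurrence count is exactly twice the spontaneous rate (count
  ## feedback compensates for occurrences created at injection junctions)
  set.seed(31)
  n <- 1000L; len <- 1000L
  unaff <- vapply(seq_len(n), function(i) randomDna(len), character(1))
  reg <- vapply(seq_len(n), function(i) randomDna(len), character(1))
  countTargets <- function(seqs)
    sum(colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), 4))[MBNL_TARGET_MOTIFS])
  baseCount <- countTargets(reg)
  slots <- seq(1, len - 3, by = 4)
  while (countTargets(reg) < 2L * baseCount) {
    need <- 2L * baseCount - countTargets(reg)
    for (j in seq_len(max(50L, need %/% 2L))) {
      i <- sample(n, 1)
      p <- sample(slots, 1)
      substr(reg[i], p, p + 3) <- sample(MBNL_TARGET_MOTIFS, 1)
    }
  }
  e <- enrichmentLog2(Biostrings::DNAStringSet(reg),
                      Biostrings::DNAStringSet(unaff))
  expect_equal(e, 1.0, tolerance = 0.05)
})

test_that("counting respects the sense-strand convention", {
  tg <- toyGene("+")
  mir <- mirrorGene(tg$genome, tg$gm)
  win <- c(tg$gm$end[3], tg$gm$end[3] + 250)
  plusSeq <- genomeSeq(tg$genome, "chrT", win[1], win[2], "+")
  L <- length(tg$genome[[1]])
  minusSeq <- genomeSeq(mir$genome, "chrT", L - win[2], L - win[1], "-")
  for (m in MBNL_TARGET_MOTIFS) {
    expect_equal(countKmer(minusSeq, m), countKmer(plusSeq, m))
  }
})

test_that("the RNA-map matrix recovers injected motif placement", {
  st <- smallStudy(seed = 13, n_genes = 60, fraction_regulated = 0.4)
  byClass <- split(st$events$event_id, st$events$class)
  sets <- lapply(byClass, function(ids) lapply(ids, function(ev) {
    row <- st$events[st$events$event_id == ev, ]
    extractRegions(st$gene_models, row$gene_id, row$exon_index,
                   st$genome, 250, event_id = ev)
  }))
  m <- rnaMapMatrix(sets)
  expect_identical(colnames(m), RNA_MAP_REGIONS)
  expect_gt(m["activated", "skip_down"], 0)
  expect_gt(m["repressed", "skip_up"], 0)
  expect_gt(m["repressed", "exon"], 0)
})
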