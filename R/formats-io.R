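## File readers/writers and the shared coordinate conventions.
## All coordinates are 0-based half-open; strand is "+" or "-"; motif-level
## work happens on the sense strand (minus-strand sequence is
## reverse-complemented at extraction time).

#' Read a genome FASTA file
#'
#' Parses a FASTA file into a named [Biostrings::DNAStringSet].  Sequences
#' are uppercased, RNA `U` is mapped to `T`, and the alphabet is restricted
#' to `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by FASTA header (first whitespace token).
#' @export
readGenomeFasta <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA format error: '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(raw))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("FASTA format error: duplicate header(s): ",
         paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA format error: illegal characters in record(s): ",
         paste(nm[bad], collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA format error: empty sequence in record(s): ",
         paste(nm[empty], collapse = ", "))
  out <- DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write a genome FASTA file
#'
#' @param x A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences (may contain `N` and `-`).
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Extract genomic sequence for a 0-based half-open interval
#'
#' @param genome Named `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus-strand requests return the reverse
#'   complement (sense-strand sequence).
#' @return Character(1) sequence.
#' @export
genomeSeq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  L <- length(genome[[chrom]])
  if (start < 0 || end > L || end < start)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, L))
  s <- as.character(subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") s <- revComp(s)
  s
}

## ---------------------------------------------------------------------------
## Gene models: plain exon table in the package-wide 0-based convention.

#' Construct a gene-model exon table
#'
#' Gene models are stored as a data frame of exons with 0-based half-open
#' genomic coordinates, one row per exon, sorted by start within gene.
#'
#' @param df Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @return The validated data frame with class `"geneModels"` prepended.
#' @export
geneModels <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("gene model table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$end <= df$start))
    stop("each exon must satisfy end > start")
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  for (g in unique(df$gene_id)) {
    e <- df[df$gene_id == g, ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
  }
  rownames(df) <- NULL
  class(df) <- c("geneModels", class(df))
  df
}

#' Read gene models from BED12
#'
#' Each BED12 line becomes one gene/transcript; block coordinates become
#' exons (BED is natively 0-based half-open).
#'
#' @param path Path to a BED12 file.
#' @return A [geneModels()] data frame.
#' @export
readGeneModelsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no records in BED file '", path, "'")
  rows <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- if ("blocks" %in% colnames(mcols(g)) &&
                  length(mcols(g)$blocks[[1L]]) > 0L) {
      b <- mcols(g)$blocks[[1L]]  # 1-based, relative to feature start
      data.frame(start = start(g) - 1L + start(b) - 1L,
                 end = start(g) - 1L + end(b))
    } else {
      data.frame(start = start(g) - 1L, end = end(g))
    }
    data.frame(gene_id = mcols(g)$name, transcript_id = mcols(g)$name,
               chrom = as.character(seqnames(g)),
               strand = as.character(strand(g)),
               start = blocks$start, end = blocks$end,
               stringsAsFactors = FALSE)
  })
  geneModels(do.call(rbind, rows))
}

#' Write gene models to BED12
#'
#' @param gm A [geneModels()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsBed <- function(gm, path) {
  lines <- vapply(unique(gm$gene_id), function(g) {
    e <- gm[gm$gene_id == g, ]
    e <- e[order(e$start), ]
    chromStart <- min(e$start); chromEnd <- max(e$end)
    sizes <- paste0(paste(e$end - e$start, collapse = ","), ",")
    starts <- paste0(paste(e$start - chromStart, collapse = ","), ",")
    paste(e$chrom[1L], chromStart, chromEnd, g, 0, e$strand[1L],
          chromStart, chromEnd, "0,0,0", nrow(e), sizes, starts,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Exon features are grouped by their `Parent` (or `gene_id`) attribute;
#' GFF3's 1-based closed coordinates are converted to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A [geneModels()] data frame.
#' @export
readGeneModelsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[tolower(as.character(mcols(gr)$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in GFF3 file '", path, "'")
  mc <- mcols(gr)
  parent <- if ("Parent" %in% colnames(mc)) {
    vapply(mc$Parent, function(p) as.character(p)[1L], character(1))
  } else if ("gene_id" %in% colnames(mc)) {
    as.character(mc$gene_id)
  } else stop("GFF3 exons carry neither Parent nor gene_id")
  gene <- if ("gene_id" %in% colnames(mc) && !all(is.na(mc$gene_id)))
    as.character(mc$gene_id) else parent
  geneModels(data.frame(
    gene_id = gene, transcript_id = parent,
    chrom = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    start = start(gr) - 1L, end = end(gr),
    stringsAsFactors = FALSE))
}

#' Exons of one gene in transcript order
#'
#' @param gm A [geneModels()] data frame.
#' @param gene_id Gene identifier.
#' @return Data frame of the gene's exons ordered 5' to 3' along the
#'   transcript (reverse genomic order on the minus strand).
#' @export
txExons <- function(gm, gene_id) {
  e <- gm[gm$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown gene ", gene_id)
  e <- e[order(e$start), ]
  if (e$strand[1L] == "-") e <- e[rev(seq_len(nrow(e))), ]
  rownames(e) <- NULL
  e
}

#' Spliced (mature) transcript sequence of a gene
#'
#' Concatenates the exon sequences in transcript order on the sense strand.
#'
#' @param gm A [geneModels()] data frame.
#' @param gene_id Gene identifier.
#' @param genome Named `DNAStringSet`.
#' @return Character(1) spliced sequence.
#' @export
spliceTranscript <- function(gm, gene_id, genome) {
  e <- txExons(gm, gene_id)
  parts <- vapply(seq_len(nrow(e)), function(i)
    genomeSeq(genome, e$chrom[i], e$start[i], e$end[i], e$strand[i]),
    character(1))
  paste(parts, collapse = "")
}

## ---------------------------------------------------------------------------
## MAF 1.0

#' Read MAF 1.0 multiple-alignment blocks
#'
#' Blocks are normalised so the reference species' row lies on the +
#' strand (minus-strand reference blocks are reverse-complemented with
#' coordinates converted) and sorted by reference start.  Blocks that lack
#' the reference row are skipped with a warning.
#'
#' @param path Path to a MAF file.
#' @param reference Reference species name (the part of `src` before the
#'   first dot).
#' @return A [MafAlignments-class] object.
#' @export
readMaf <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  isA <- grepl("^a( |$)", lines)
  isS <- grepl("^s\\s", lines)
  if (any(isS) && !any(isA))
    stop("MAF format error: 's' line before 'a' line")
  groupId <- cumsum(isA)
  if (any(isS & groupId == 0L))
    stop("MAF format error: 's' line before 'a' line")
  sLines <- lines[isS]
  sGroup <- groupId[isS]
  fields <- strsplit(trimws(sLines), "\\s+")
  if (any(lengths(fields) < 7L))
    stop("MAF format error: short 's' line")
  f <- function(i) vapply(fields, `[[`, character(1), i)
  src <- f(2L)
  dot <- regexpr(".", src, fixed = TRUE)
  rows <- data.frame(
    species = ifelse(dot > 0L, substr(src, 1L, dot - 1L), src),
    chrom = ifelse(dot > 0L, substr(src, dot + 1L, nchar(src)), src),
    start = as.integer(f(3L)), size = as.integer(f(4L)),
    strand = f(5L), src_size = as.integer(f(6L)),
    text = toupper(f(7L)), stringsAsFactors = FALSE)
  blocks <- list()
  for (g in unique(sGroup)) {
    cur <- rows[sGroup == g, , drop = FALSE]
    if (nrow(cur) == 0L) next
    if (length(unique(nchar(cur$text))) > 1L)
      stop("MAF format error: ragged columns in block ", g)
    if (!reference %in% cur$species) {
      warning("MAF block lacking reference species '", reference,
              "' skipped")
      next
    }
    ref <- cur[cur$species == reference, ][1L, ]
    if (ref$strand == "-") {
      cur$text <- revComp(cur$text)
      cur$start <- cur$src_size - (cur$start + cur$size)
      cur$strand <- ifelse(cur$strand == "+", "-", "+")
      ref <- cur[cur$species == reference, ][1L, ]
    }
    blocks[[length(blocks) + 1L]] <- list(
      rows = cur, ref_chrom = ref$chrom,
      ref_start = ref$start, ref_end = ref$start + ref$size)
  }
  if (length(blocks))
    blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "ref_start"))]
  new("MafAlignments", blocks = blocks, reference = reference)
}

#' Write MAF 1.0 multiple-alignment blocks
#'
#' @param maf A [MafAlignments-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(maf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in maf@blocks) {
    writeLines("a score=0.0", con)
    r <- b$rows
    writeLines(sprintf("s %s.%s %d %d %s %d %s",
                       r$species, r$chrom, r$start, r$size, r$strand,
                       r$src_size, r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Newick species trees

#' Read a Newick species tree with mandatory branch lengths
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
readSpeciesTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file '", path, "'")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("Newick tree must carry branch lengths on every edge")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Write a species tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpeciesTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Tabular inputs

#' Read a junction count table
#'
#' Tab-separated with header: `event_id`, `sample_id`, `inclusion_reads`,
#' `exclusion_reads`, `event_type`.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
readCountTable <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "sample_id", "inclusion_reads", "exclusion_reads",
            "event_type")
  miss <- setdiff(need, colnames(ct))
  if (length(miss))
    stop("count table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ct[c("event_id", "sample_id")]))
    stop("duplicate (event_id, sample_id) rows in count table")
  if (any(ct$inclusion_reads < 0) || any(ct$exclusion_reads < 0))
    stop("read counts must be non-negative")
  if (!all(ct$event_type %in% EVENT_TYPES))
    stop("event_type must be one of: ", paste(EVENT_TYPES, collapse = ", "))
  ct
}

#' Write a junction count table
#' @param ct Count table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, group)
#' @param path Path to the TSV file.
#' @return Data frame with columns `sample_id`, `group`.
#' @export
readSampleSheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ss)))
    stop("sample sheet needs columns sample_id and group")
  ss
}

#' Read a gene-to-GO mapping
#'
#' Tab-separated `gene_id<TAB>go_id` with optional third column `go_name`;
#' a header row is detected by the literal column names.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `go_id`, `go_name`.
#' @export
readGoMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("gene_id", first)
  gm <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader)
    colnames(gm) <- c("gene_id", "go_id", "go_name")[seq_len(ncol(gm))]
  if (!all(c("gene_id", "go_id") %in% colnames(gm)))
    stop("GO map needs columns gene_id and go_id")
  if (!"go_name" %in% colnames(gm)) gm$go_name <- gm$go_id
  if (nrow(gm) == 0L) stop("empty GO map")
  gm
}

#' Category membership lists from a GO map
#'
#' @param goMap Data frame from [readGoMap()].
#' @return Named list: `go_id` -> character vector of member gene ids.
#' @export
goMembership <- function(goMap) {
  split(goMap$gene_id, goMap$go_id)
}
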