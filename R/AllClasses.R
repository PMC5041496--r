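#' SpliceCounts: junction read counts per event and sample
#'
#' A \linkS4class{SummarizedExperiment} with two assays, `inclusion` and
#' `exclusion`, holding non-negative junction read counts; `rowData` carries
#' `event_type` (one of [EVENT_TYPES]) and the junction weights
#' `n_inc_junctions` / `n_exc_junctions`; `colData` carries the sample
#' `group` (e.g. WT, DKO, GFP, Hs, Ci, Dm, Ce, Ta).
#'
#' @slot . inherits all slots from SummarizedExperiment.
#' @export
setClass("SpliceCounts", contains = "SummarizedExperiment")

setValidity("SpliceCounts", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("inclusion", "exclusion") %in% an))
    msg <- c(msg, "assays must include 'inclusion' and 'exclusion'")
  else {
    inc <- assay(object, "inclusion")
    exc <- assay(object, "exclusion")
    if (any(inc < 0, na.rm = TRUE) || any(exc < 0, na.rm = TRUE))
      msg <- c(msg, "junction counts must be non-negative")
  }
  rd <- rowData(object)
  if (!all(c("event_type", "n_inc_junctions", "n_exc_junctions") %in%
           colnames(rd)))
    msg <- c(msg, paste("rowData must carry event_type, n_inc_junctions,",
                        "n_exc_junctions"))
  else {
    if (!all(rd$event_type %in% EVENT_TYPES))
      msg <- c(msg, paste("event_type must be one of:",
                          paste(EVENT_TYPES, collapse = ", ")))
    if (any(rd$n_inc_junctions < 1) || any(rd$n_exc_junctions < 1))
      msg <- c(msg, "junction weights must be >= 1")
  }
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must carry a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct a SpliceCounts object
#'
#' Assembles the event-by-sample inclusion/exclusion count matrices from a
#' long-format count table and a sample sheet.
#'
#' @param countTable Data frame with columns `event_id`, `sample_id`,
#'   `inclusion_reads`, `exclusion_reads`, `event_type` (see
#'   [readCountTable()]).  Missing event/sample combinations become zeros.
#' @param sampleSheet Data frame with columns `sample_id`, `group`.
#' @param junctionWeights Data frame mapping `event_type` to
#'   `n_inc_junctions` / `n_exc_junctions`; defaults to [JUNCTION_WEIGHTS].
#' @return A [SpliceCounts-class] object.
#' @examples
#' ct <- data.frame(event_id = "ev1", sample_id = c("s1", "s2"),
#'                  inclusion_reads = c(20L, 4L), exclusion_reads = c(10L, 18L),
#'                  event_type = "SE")
#' ss <- data.frame(sample_id = c("s1", "s2"), group = c("WT", "DKO"))
#' sc <- SpliceCounts(ct, ss)
#' @export
SpliceCounts <- function(countTable, sampleSheet,
                         junctionWeights = JUNCTION_WEIGHTS) {
  stopifnot(is.data.frame(countTable), is.data.frame(sampleSheet))
  need <- c("event_id", "sample_id", "inclusion_reads", "exclusion_reads",
            "event_type")
  miss <- setdiff(need, colnames(countTable))
  if (length(miss))
    stop("countTable is missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group") %in% colnames(sampleSheet)))
    stop("sampleSheet needs columns sample_id and group")
  events <- unique(countTable$event_id)
  samples <- sampleSheet$sample_id
  unknown <- setdiff(countTable$sample_id, samples)
  if (length(unknown))
    stop("samples absent from sampleSheet: ", paste(unknown, collapse = ", "))
  mk <- function(col) {
    m <- matrix(0L, length(events), length(samples),
                dimnames = list(events, samples))
    m[cbind(match(countTable$event_id, events),
            match(countTable$sample_id, samples))] <- as.integer(countTable[[col]])
    m
  }
  et <- countTable$event_type[match(events, countTable$event_id)]
  jw <- junctionWeights[match(et, junctionWeights$event_type), ]
  rd <- DataFrame(event_type = et,
                  n_inc_junctions = jw$n_inc_junctions,
                  n_exc_junctions = jw$n_exc_junctions,
                  row.names = events)
  cd <- DataFrame(group = sampleSheet$group, row.names = samples)
  se <- SummarizedExperiment(
    assays = list(inclusion = mk("inclusion_reads"),
                  exclusion = mk("exclusion_reads")),
    rowData = rd, colData = cd)
  new("SpliceCounts", se)
}

#' MafAlignments: multiple-alignment blocks anchored on a reference
#'
#' A set of MAF 1.0 alignment blocks, each normalised so the reference row
#' is on the + strand, sorted by reference start coordinate.
#'
#' @slot blocks list; each element is a list with elements `rows` (a data
#'   frame with columns `species`, `chrom`, `start`, `size`, `strand`,
#'   `src_size`, `text`), `ref_start`, `ref_end` (0-based half-open on the
#'   reference) and `ref_chrom`.
#' @slot reference character(1), the reference species name.
#' @export
setClass("MafAlignments",
         representation(blocks = "list", reference = "character"))

setValidity("MafAlignments", function(object) {
  msg <- character()
  if (length(object@reference) != 1L)
    msg <- c(msg, "reference must be a single species name")
  for (i in seq_along(object@blocks)) {
    b <- object@blocks[[i]]
    if (!all(c("rows", "ref_start", "ref_end", "ref_chrom") %in% names(b))) {
      msg <- c(msg, sprintf("block %d malformed", i)); next
    }
    w <- nchar(b$rows$text)
    if (length(unique(w)) > 1L)
      msg <- c(msg, sprintf("block %d has ragged columns", i))
    if (!object@reference %in% b$rows$species)
      msg <- c(msg, sprintf("block %d lacks the reference row", i))
    else {
      r <- b$rows[b$rows$species == object@reference, ][1L, ]
      ungapped <- nchar(gsub("-", "", r$text))
      if (ungapped != b$ref_end - b$ref_start)
        msg <- c(msg, sprintf(
          "block %d: ungapped reference length %d != ref interval %d",
          i, ungapped, b$ref_end - b$ref_start))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MafAlignments-class number of alignment blocks
#' @param x A `MafAlignments` object.
#' @export
setMethod("length", "MafAlignments", function(x) length(x@blocks))

setMethod("show", "MafAlignments", function(object) {
  sp <- unique(unlist(lapply(object@blocks, function(b) b$rows$species)))
  cat("MafAlignments with", length(object@blocks), "block(s),",
      length(sp), "species; reference:", object@reference, "\n")
})

#' RegionSet: the five RNA-map windows around one skipped exon
#'
#' Sense-strand sequences for the skipped exon and the four flanking
#' intronic windows used in the RNA-map analysis (see [RNA_MAP_REGIONS]).
#'
#' @slot eventId character(1) event identifier.
#' @slot regions [Biostrings::DNAStringSet] named by [RNA_MAP_REGIONS];
#'   intronic regions are at most `window` nucleotides.
#' @slot window numeric(1), the intronic window size used at extraction.
#' @export
setClass("RegionSet",
         representation(eventId = "character", regions = "DNAStringSet",
                        window = "numeric"))

setValidity("RegionSet", function(object) {
  msg <- character()
  if (!identical(names(object@regions), RNA_MAP_REGIONS))
    msg <- c(msg, paste("regions must be named, in order:",
                        paste(RNA_MAP_REGIONS, collapse = ", ")))
  else {
    intr <- setdiff(RNA_MAP_REGIONS, "exon")
    if (any(Biostrings::width(object@regions[intr]) > object@window))
      msg <- c(msg, "intronic regions must not exceed the window size")
  }
  bad <- grepl("[^ACGTN]", as.character(object@regions))
  if (any(bad))
    msg <- c(msg, "sequences restricted to the {A,C,G,T,N} alphabet")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet for event", object@eventId, "(window",
      object@window, "nt)\n")
  w <- Biostrings::width(object@regions)
  cat(paste(sprintf("  %-14s %4d nt", names(object@regions), w),
            collapse = "\n"), "\n")
})

#' @describeIn RegionSet-class the five region sequences
#' @param x A `RegionSet` object.
#' @export
regions <- function(x) {
  stopifnot(is(x, "RegionSet"))
  x@regions
}

#' @describeIn RegionSet-class the event identifier
#' @export
eventId <- function(x) {
  stopifnot(is(x, "RegionSet"))
  x@eventId
}
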