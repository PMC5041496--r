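## Rank-sum GO enrichment of delta-gene, BH correction, directional floor,
## cross-species intersection.

#' Rank-sum enrichment of a gene category
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of the `delta_gene`
#' distribution inside a GO category against all genes outside it.  The
#' exact distribution is used when `n_in * n_out <= 400` and there are no
#' ties; otherwise the normal approximation with tie correction applies.
#'
#' @param delta_gene_by_gene Named numeric vector of `delta_gene` scores
#'   (names are gene ids; `NA` scores are dropped).
#' @param category_members Character vector of member gene ids.
#' @return List with `p_raw`, `mean_in`, `mean_out`, `n_in`, `n_out`;
#'   `NULL` when either side is empty after dropping undefined scores.
#' @export
ranksumEnrichment <- function(delta_gene_by_gene, category_members) {
  x <- delta_gene_by_gene[!is.na(delta_gene_by_gene)]
  inSide <- x[names(x) %in% category_members]
  outSide <- x[!names(x) %in% category_members]
  if (length(inSide) == 0L || length(outSide) == 0L) return(NULL)
  exact <- length(inSide) * length(outSide) <= 400
  p <- suppressWarnings(
    wilcox.test(inSide, outSide, alternative = "two.sided",
                exact = exact, correct = FALSE)$p.value)
  list(p_raw = p, mean_in = mean(inSide), mean_out = mean(outSide),
       n_in = length(inSide), n_out = length(outSide))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Directional floor on adjusted p-values
#'
#' Sets the adjusted p-value to 1 (and flags `floored = TRUE`) for
#' categories whose mean score inside the category is strictly lower than
#' outside; applied after BH correction.
#'
#' @param results Data frame with columns `mean_in`, `mean_out`,
#'   `p_adjusted`.
#' @return The data frame with `p_adjusted` floored and a `floored`
#'   column.
#' @export
directionalFloor <- function(results) {
  stopifnot(all(c("mean_in", "mean_out", "p_adjusted") %in%
                colnames(results)))
  floored <- !is.na(results$mean_in) & !is.na(results$mean_out) &
    results$mean_in < results$mean_out
  results$p_adjusted[floored] <- 1
  results$floored <- floored
  results
}

#' GO-category enrichment of delta-gene conservation scores
#'
#' Runs [ranksumEnrichment()] per category, BH-corrects the raw p-values,
#' then applies the [directionalFloor()].  Genes with undefined
#' `delta_gene` are excluded from both sides of every test; categories with
#' fewer than `minMembers` scored member genes are reported untested.
#'
#' @param delta_gene_by_gene Named numeric vector of gene scores.
#' @param goMap Data frame from [readGoMap()] (columns `gene_id`, `go_id`,
#'   optional `go_name`).
#' @param minMembers Minimum scored member genes per tested category
#'   (default 5).
#' @return Data frame with one row per category: `go_id`, `go_name`,
#'   `n_in`, `n_out`, `mean_in`, `mean_out`, `p_raw`, `p_adjusted`,
#'   `floored`, `tested`.
#' @export
goEnrichment <- function(delta_gene_by_gene, goMap, minMembers = 5) {
  members <- goMembership(goMap)
  nameOf <- if ("go_name" %in% colnames(goMap))
    setNames(goMap$go_name, goMap$go_id) else NULL
  rows <- lapply(names(members), function(cat) {
    scored <- sum(!is.na(delta_gene_by_gene[
      names(delta_gene_by_gene) %in% members[[cat]]]))
    res <- if (scored >= minMembers)
      ranksumEnrichment(delta_gene_by_gene, members[[cat]]) else NULL
    if (is.null(res)) {
      data.frame(go_id = cat,
                 go_name = if (is.null(nameOf)) cat else
                   unname(nameOf[cat]),
                 n_in = scored, n_out = NA_integer_, mean_in = NA_real_,
                 mean_out = NA_real_, p_raw = NA_real_, tested = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(go_id = cat,
                 go_name = if (is.null(nameOf)) cat else
                   unname(nameOf[cat]),
                 n_in = res$n_in, n_out = res$n_out,
                 mean_in = res$mean_in, mean_out = res$mean_out,
                 p_raw = res$p_raw, tested = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  out$p_adjusted[out$tested] <- bhAdjust(out$p_raw[out$tested])
  out <- directionalFloor(out)
  out
}

#' Categories enriched across species
#'
#' Retains categories with BH-adjusted p below `alpha` in at least
#' `min_species` of the per-species result sets, and returns the
#' `-log10(p_adjusted)` matrix for heatmap display.
#'
#' @param per_species_results Named list of [goEnrichment()] data frames,
#'   one per species.
#' @param alpha Significance cutoff on `p_adjusted` (default 0.01).
#' @param min_species Minimum number of species (default 4, inclusive).
#' @return List with `categories` (character vector of retained go_ids) and
#'   `log10p` (matrix, categories x species, `-log10(p_adjusted)`).
#' @export
crossSpeciesIntersection <- function(per_species_results, alpha = 0.01,
                                     min_species = 4) {
  if (length(per_species_results) < min_species)
    stop("need at least ", min_species, " per-species result sets")
  allCats <- sort(unique(unlist(lapply(per_species_results,
                                       function(r) r$go_id))))
  pMat <- sapply(per_species_results, function(r)
    r$p_adjusted[match(allCats, r$go_id)])
  if (is.null(dim(pMat))) pMat <- matrix(pMat, nrow = length(allCats))
  rownames(pMat) <- allCats
  colnames(pMat) <- names(per_species_results)
  nSig <- rowSums(!is.na(pMat) & pMat < alpha)
  keep <- allCats[nSig >= min_species]
  list(categories = keep,
       log10p = -log10(pMat[keep, , drop = FALSE]))
}
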