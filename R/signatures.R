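# Per-cell gene-signature scores and subset proportions.

#' Score a gene signature per cell with expression-matched controls
#'
#' For each cell, the score is the mean log-normalized expression of the
#' gene-set genes minus the mean expression of control genes matched on
#' average expression: all genes are ranked by their mean expression across
#' cells (ties broken by gene name so the result is invariant to column
#' order) and cut into `n_bins` equal-frequency bins; each gene-set gene
#' draws `n_ctrl_per_gene` control genes from its own bin (excluding
#' gene-set genes, sampled with replacement when the bin is small, widening
#' to neighbouring bins only if a bin holds no eligible gene). Under
#' exchangeability of gene-set and control labels the expected score is 0.
#' Scores are reproducible for a fixed seed.
#'
#' @param expr numeric cells-by-genes matrix of log-normalized expression
#'   with cell ids as rownames and gene symbols as colnames.
#' @param gene_set character vector of gene symbols (case-sensitive).
#' @param name signature name recorded in the output.
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl_per_gene control genes per gene-set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return data.frame: `cell_id`, `signature_name`, `score`.
#' @export
score_signature <- function(expr, gene_set, name = "signature",
                            n_bins = 25, n_ctrl_per_gene = 100, seed = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  genes <- colnames(expr)
  if (length(genes) < max(2, n_bins)) {
    stop("expression matrix must contain at least max(2, n_bins) genes")
  }
  set_genes <- sort(unique(gene_set))
  present <- intersect(set_genes, genes)
  if (length(present) == 0) {
    stop("scoring error for signature '", name,
         "': no gene-set genes present in the expression matrix")
  }
  if (length(present) < 0.5 * length(set_genes)) {
    warning("signature '", name, "': only ", length(present), " of ",
            length(set_genes), " genes present in the matrix")
  }
  gene_means <- colMeans(expr)
  # order-invariant binning: rank by (mean, name), equal-frequency bins
  ord <- order(gene_means, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) / (length(genes) / n_bins))
  names(bin) <- genes
  eligible <- setdiff(genes, present)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      b <- bin[[g]]
      cand <- eligible[bin[eligible] == b]
      width <- 0
      while (length(cand) == 0 && width < n_bins) {
        width <- width + 1
        cand <- eligible[abs(bin[eligible] - b) <= width]
      }
      if (length(cand) == 0) stop("scoring error for signature '", name,
                                  "': no eligible control genes")
      sample(sort(cand), n_ctrl_per_gene, replace = TRUE)
    }), use.names = FALSE)
  })
  score <- rowMeans(expr[, present, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  data.frame(cell_id = rownames(expr),
             signature_name = name,
             score = unname(score),
             stringsAsFactors = FALSE)
}

#' Score several gene signatures
#'
#' @param expr cells-by-genes matrix (see [score_signature()]).
#' @param gene_sets named list of gene symbol vectors (e.g. from
#'   [read_gene_sets()]).
#' @param ... passed to [score_signature()].
#' @return long data.frame of per-cell scores for all signatures.
#' @export
score_signatures <- function(expr, gene_sets, ...) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  out <- lapply(names(gene_sets), function(nm) {
    score_signature(expr, gene_sets[[nm]], name = nm, ...)
  })
  do.call(rbind, out)
}

#' Per-donor subset proportions
#'
#' `proportion = |numerator n denominator| / |denominator|` within each group
#' defined by `per`. The numerator filter must nest inside the denominator
#' filter; groups with an empty denominator are omitted with a reason in the
#' `"omitted"` attribute.
#'
#' @param cells data.frame of cells.
#' @param numerator,denominator logical vectors parallel to `cells` rows.
#' @param per character vector of grouping columns (e.g.
#'   `c("donor_id", "tissue")`).
#' @return data.frame: grouping columns, `n_numerator`, `n_denominator`,
#'   `proportion`.
#' @export
subset_proportions <- function(cells, numerator, denominator,
                               per = c("donor_id", "tissue")) {
  stopifnot(length(numerator) == nrow(cells),
            length(denominator) == nrow(cells),
            all(per %in% names(cells)))
  if (any(numerator & !denominator)) {
    stop("numerator filter must nest inside the denominator filter")
  }
  key <- group_key(cells, per)
  keys <- sort(unique(key))
  omitted <- character(0)
  rows <- lapply(keys, function(k) {
    idx <- key == k
    den <- sum(denominator & idx)
    if (den == 0) {
      omitted <<- c(omitted, k)
      return(NULL)
    }
    cbind(cells[which(idx)[1], per, drop = FALSE],
          data.frame(n_numerator = sum(numerator & idx),
                     n_denominator = den,
                     proportion = sum(numerator & idx) / den,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <-
    if (length(omitted)) paste0(omitted, ": empty denominator") else character(0)
  out
}
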