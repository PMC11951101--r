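# Clonotype sharing between B-cell subsets and tissues within donors — the
# computational readout behind memory-to-plasma-cell differentiation claims.

#' Pairwise clonotype-set similarity
#'
#' Similarity between two clonotype identity sets from the same donor.
#' The default metric is the overlap coefficient
#' `|A n B| / min(|A|, |B|)`, which is symmetric, bounded in `[0, 1]`, equals
#' 1 when the smaller set is contained in the larger, and is robust to the
#' large compartment-size asymmetries between memory B cells and plasma
#' cells. Jaccard (`|A n B| / |A u B|`) is available for sensitivity
#' analysis. Similarity is 0 (flagged) when either set is empty.
#'
#' @param clonotypes_a,clonotypes_b character vectors of clonotype ids.
#' @param metric `"overlap"` (default) or `"jaccard"`.
#' @param donor_a,donor_b optional donor ids; differing donors are an error
#'   (sharing is only meaningful within a donor).
#' @return list: `n_a`, `n_b`, `n_shared`, `similarity`, `empty_input`.
#' @export
pairwise_similarity <- function(clonotypes_a, clonotypes_b,
                                metric = c("overlap", "jaccard"),
                                donor_a = NULL, donor_b = NULL) {
  metric <- match.arg(metric)
  if (!is.null(donor_a) && !is.null(donor_b) && !identical(donor_a, donor_b)) {
    stop("cross-donor similarity is undefined: '", donor_a, "' vs '",
         donor_b, "'")
  }
  a <- unique(clonotypes_a[!is.na(clonotypes_a)])
  b <- unique(clonotypes_b[!is.na(clonotypes_b)])
  shared <- length(intersect(a, b))
  empty <- length(a) == 0 || length(b) == 0
  sim <- if (empty) 0 else if (metric == "overlap") {
    shared / min(length(a), length(b))
  } else {
    shared / length(union(a, b))
  }
  list(n_a = length(a), n_b = length(b), n_shared = shared,
       similarity = sim, empty_input = empty)
}

.compartment_sets <- function(cells, compartment_cols) {
  key <- group_key(cells, compartment_cols)
  split(cells$clonotype_id, key)
}

#' Per-donor and group-mean clonotype-similarity matrices
#'
#' For every donor, computes the pairwise similarity between all compartments
#' (e.g. cell types) over that donor's clonotype sets; entries where either
#' compartment has fewer than `min_clonotypes` clonotypes are missing, not
#' zero, so sparse compartments do not drag group means toward zero. The
#' group-level matrix is the mean of the per-donor matrices over donors with
#' a non-missing entry (donor = unit of replication, never pooled
#' clonotypes). Diagonals are defined as 1.
#'
#' @param cells data.frame with `donor_id`, `clonotype_id` and the
#'   compartment columns.
#' @param compartment_cols columns defining compartments (default
#'   `"cell_type"`).
#' @param min_clonotypes minimum clonotypes per compartment (default 10).
#' @param metric passed to [pairwise_similarity()].
#' @return list of class `similarity_matrices`: `per_donor` (named list of
#'   matrices), `mean` (matrix), `n_donors` (matrix of contributing donor
#'   counts).
#' @export
similarity_matrix <- function(cells, compartment_cols = "cell_type",
                              min_clonotypes = 10,
                              metric = c("overlap", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(all(c("donor_id", "clonotype_id") %in% names(cells)),
            all(compartment_cols %in% names(cells)))
  cells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  comps <- sort(unique(group_key(cells, compartment_cols)))
  donors <- sort(unique(cells$donor_id))
  per_donor <- lapply(donors, function(d) {
    sub <- cells[cells$donor_id == d, , drop = FALSE]
    sets <- .compartment_sets(sub, compartment_cols)
    sets <- lapply(sets, function(s) unique(s))
    m <- matrix(NA_real_, length(comps), length(comps),
                dimnames = list(comps, comps))
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (i == j) { m[i, j] <- 1; next }
        a <- sets[[comps[i]]] %||% character(0)
        b <- sets[[comps[j]]] %||% character(0)
        if (length(a) < min_clonotypes || length(b) < min_clonotypes) next
        m[i, j] <- pairwise_similarity(a, b, metric)$similarity
      }
    }
    m
  })
  names(per_donor) <- donors
  stack <- simplify2array(per_donor)
  mean_m <- apply(stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  n_m <- apply(stack, c(1, 2), function(v) sum(!is.na(v)))
  if (all(is.na(mean_m[upper.tri(mean_m)]))) {
    stop("no donor passes the minimum-clonotype requirement for any ",
         "compartment pair")
  }
  structure(list(per_donor = per_donor, mean = mean_m, n_donors = n_m,
                 metric = metric, min_clonotypes = min_clonotypes),
            class = "similarity_matrices")
}

#' @export
print.similarity_matrices <- function(x, ...) {
  cat("Clonotype similarity (", x$metric, " coefficient, min ",
      x$min_clonotypes, " clonotypes), mean over ",
      length(x$per_donor), " donor(s):\n", sep = "")
  print(round(x$mean, 3))
  invisible(x)
}

#' Per-donor similarity between two (cell type, tissue) compartments
#'
#' Long-format per-donor similarity entries between, e.g., colonic MBCs and
#' blood PCs. Donors where either compartment falls below `min_clonotypes`
#' yield `NA` with the reason recorded.
#'
#' @param cells data.frame with `donor_id`, `clonotype_id`, `cell_type`,
#'   `tissue` and any extra columns named in `carry` to carry through
#'   (first value per donor, e.g. `disease_group`).
#' @param cell_type_pair length-2 character: cell types of compartments a, b.
#' @param tissue_pair length-2 character: tissues of compartments a, b.
#' @param min_clonotypes minimum clonotypes per compartment (default 10).
#' @param metric passed to [pairwise_similarity()].
#' @param carry extra per-donor columns to carry into the result.
#' @return data.frame: `donor_id`, carried columns, `subset_a`, `subset_b`,
#'   `n_clonotypes_a`, `n_clonotypes_b`, `n_shared`, `similarity`, `reason`.
#' @export
cross_tissue_similarity <- function(cells, cell_type_pair, tissue_pair,
                                    min_clonotypes = 10,
                                    metric = c("overlap", "jaccard"),
                                    carry = "disease_group") {
  metric <- match.arg(metric)
  stopifnot(length(cell_type_pair) == 2, length(tissue_pair) == 2)
  carry <- intersect(carry, names(cells))
  donors <- sort(unique(cells$donor_id))
  rows <- lapply(donors, function(d) {
    sub <- cells[cells$donor_id == d & !is.na(cells$clonotype_id), ,
                 drop = FALSE]
    a <- unique(sub$clonotype_id[sub$cell_type == cell_type_pair[1] &
                                   sub$tissue == tissue_pair[1]])
    b <- unique(sub$clonotype_id[sub$cell_type == cell_type_pair[2] &
                                   sub$tissue == tissue_pair[2]])
    reason <- NA_character_
    sim <- shared <- NA_real_
    if (length(a) < min_clonotypes || length(b) < min_clonotypes) {
      reason <- sprintf("below minimum clonotypes (a=%d, b=%d, need >= %d)",
                        length(a), length(b), min_clonotypes)
    } else {
      ps <- pairwise_similarity(a, b, metric)
      sim <- ps$similarity
      shared <- ps$n_shared
    }
    base <- data.frame(donor_id = d, stringsAsFactors = FALSE)
    for (cc in carry) base[[cc]] <- sub[[cc]][1] %||% NA_character_
    cbind(base, data.frame(
      subset_a = paste(cell_type_pair[1], tissue_pair[1], sep = ":"),
      subset_b = paste(cell_type_pair[2], tissue_pair[2], sep = ":"),
      n_clonotypes_a = length(a), n_clonotypes_b = length(b),
      n_shared = shared, similarity = sim, reason = reason,
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare similarity entries between groups
#'
#' Delegates to [compare_groups()] (two-tailed t by default; the paired
#' variant matches inflamed vs non-inflamed regions within donors via
#' `pair_col`).
#'
#' @param entries data.frame of per-donor similarity entries (e.g. from
#'   [cross_tissue_similarity()]).
#' @param group_col grouping column (e.g. `disease_group`).
#' @param value_col value column (default `"similarity"`).
#' @param test passed to [compare_groups()].
#' @param pair_col pairing column for `test = "paired_t"`.
#' @return a `group_comparison` object.
#' @export
compare_similarity_groups <- function(entries, group_col,
                                      value_col = "similarity",
                                      test = "t_two_tailed",
                                      pair_col = NULL) {
  keep <- !is.na(entries[[value_col]])
  entries <- entries[keep, , drop = FALSE]
  groups <- unique(entries[[group_col]])
  if (length(groups) < 2 || any(table(entries[[group_col]]) < 2)) {
    stop("insufficient data: need >= 2 donors in each of >= 2 groups")
  }
  compare_groups(entries[[value_col]], entries[[group_col]], test = test,
                 pair_ids = if (!is.null(pair_col)) entries[[pair_col]])
}

#' Empirical permutation null for compartment similarity
#'
#' Permutes clone labels among a donor's cells (within donor, across the two
#' compartments) to obtain the similarity distribution expected from
#' singleton collisions alone, against which an observed similarity can be
#' tested.
#'
#' @param cells one donor's cells: data.frame with `clonotype_id` and
#'   `cell_type`.
#' @param cell_type_pair length-2 character vector of compartments.
#' @param n_perm number of permutations (default 200).
#' @param metric passed to [pairwise_similarity()].
#' @param seed RNG seed.
#' @return numeric vector of `n_perm` null similarities.
#' @export
similarity_permutation_null <- function(cells, cell_type_pair, n_perm = 200,
                                        metric = "overlap", seed = 1) {
  sub <- cells[cells$cell_type %in% cell_type_pair &
                 !is.na(cells$clonotype_id), , drop = FALSE]
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(sub$cell_type)
      pairwise_similarity(sub$clonotype_id[lab == cell_type_pair[1]],
                          sub$clonotype_id[lab == cell_type_pair[2]],
                          metric)$similarity
    }, numeric(1))
  })
}
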