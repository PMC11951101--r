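# Donor-scoped heavy-chain clonotyping, clonal expansion, Shannon-entropy
# diversity (with depth-matched rarefaction) and IgHV-usage tables.

#' Assign donor-scoped heavy-chain clonotypes
#'
#' Cells are grouped into clonotypes by exact identity of
#' (donor, allele-stripped V gene, allele-stripped J gene, junction amino-acid
#' sequence). Identical rearrangements in different donors are distinct
#' clonotypes: clonal descent is only meaningful within a donor. Clonotype
#' ids are deterministic ordinals within the sorted key order (no hashing), so
#' permuting the input rows yields the identical partition and identical ids.
#'
#' @param cells data.frame with one heavy chain per cell: columns `cell_id`,
#'   `donor_id`, `v_call`, `j_call`, `junction_aa` (plus `junction` when
#'   `junction_nt_identity` is used).
#' @param junction_nt_identity optional sensitivity-analysis threshold in
#'   (0, 1]: instead of exact amino-acid identity, junctions of equal length
#'   whose nucleotide identity is at least this fraction are merged
#'   (single linkage within each donor/V/J/length group). `NULL` (default)
#'   keeps the exact-match rule.
#' @return list of class `clonotype_assignment`:
#'   `cells` (input rows that were clonotyped, plus `clonotype_id`),
#'   `clonotypes` (one row per clonotype: `clonotype_id`, `donor_id`,
#'   `v_gene`, `j_gene`, `junction_aa`, `size`),
#'   `excluded` (cells lacking a junction, with reason).
#' @export
assign_clonotypes <- function(cells, junction_nt_identity = NULL) {
  stopifnot(all(c("cell_id", "donor_id", "v_call", "j_call", "junction_aa")
                %in% names(cells)))
  no_junction <- is.na(cells$junction_aa) | cells$junction_aa == ""
  excluded <- data.frame(cell_id = cells$cell_id[no_junction],
                         reason = rep("missing junction_aa",
                                      sum(no_junction)),
                         stringsAsFactors = FALSE)
  cells <- cells[!no_junction, , drop = FALSE]
  cells$v_gene <- strip_allele(cells$v_call)
  cells$j_gene <- strip_allele(cells$j_call)
  if (is.null(junction_nt_identity)) {
    key <- paste(cells$donor_id, cells$v_gene, cells$j_gene,
                 cells$junction_aa, sep = "|")
  } else {
    stopifnot(junction_nt_identity > 0, junction_nt_identity <= 1,
              "junction" %in% names(cells))
    key <- .junction_identity_key(cells, junction_nt_identity)
  }
  keys <- sort(unique(key))
  donor_of <- sub("\\|.*$", "", keys)
  ordinal <- stats::ave(seq_along(keys), donor_of, FUN = seq_along)
  ids <- setNames(sprintf("%s.CT%05d", donor_of, ordinal), keys)
  cells$clonotype_id <- unname(ids[key])
  sizes <- table(cells$clonotype_id)
  first <- cells[!duplicated(cells$clonotype_id), , drop = FALSE]
  first <- first[order(first$clonotype_id), , drop = FALSE]
  clonotypes <- data.frame(clonotype_id = first$clonotype_id,
                           donor_id = first$donor_id,
                           v_gene = first$v_gene,
                           j_gene = first$j_gene,
                           junction_aa = first$junction_aa,
                           size = as.integer(sizes[first$clonotype_id]),
                           stringsAsFactors = FALSE)
  rownames(cells) <- rownames(clonotypes) <- NULL
  structure(list(cells = cells, clonotypes = clonotypes, excluded = excluded),
            class = "clonotype_assignment")
}

# Single-linkage merge of equal-length junctions with nucleotide identity
# >= threshold, within each donor/V/J/length group. Deterministic: clusters
# are seeded in sorted junction order.
.junction_identity_key <- function(cells, threshold) {
  grp <- paste(cells$donor_id, cells$v_gene, cells$j_gene,
               nchar(cells$junction), sep = "|")
  key <- character(nrow(cells))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    juncs <- sort(unique(cells$junction[idx]))
    n <- length(juncs)
    comp <- seq_len(n)
    if (n > 1) {
      mats <- lapply(strsplit(juncs, ""), identity)
      len <- length(mats[[1]])
      find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ident <- sum(mats[[i]] == mats[[j]]) / len
          if (ident >= threshold) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
      comp <- vapply(seq_len(n), find, integer(1))
    }
    cluster_of <- setNames(paste0(g, "|jc", comp), juncs)
    key[idx] <- unname(cluster_of[cells$junction[idx]])
  }
  key
}

#' @export
print.clonotype_assignment <- function(x, ...) {
  cat("Clonotype assignment:", nrow(x$cells), "cells in",
      nrow(x$clonotypes), "clonotypes across",
      length(unique(x$clonotypes$donor_id)), "donor(s);",
      nrow(x$excluded), "cell(s) excluded\n")
  invisible(x)
}

#' Fraction of cells in expanded clonotypes
#'
#' The expanded fraction of a compartment is the proportion of its cells
#' whose clonotype has two or more members *within that compartment*
#' (compartment-restricted sizes).
#'
#' @param clone_ids per-cell clonotype labels of the compartment's cells.
#' @param reference_ids per-cell clone labels used to compute clone sizes;
#'   defaults to `clone_ids` (compartment-restricted sizes). Pass the
#'   donor-wide labels to score expansion against donor-wide clone sizes.
#' @return real in `[0, 1]`; `NA` for an empty compartment.
#' @export
expanded_fraction <- function(clone_ids, reference_ids = clone_ids) {
  clone_ids <- clone_ids[!is.na(clone_ids)]
  reference_ids <- reference_ids[!is.na(reference_ids)]
  if (length(clone_ids) == 0) return(NA_real_)
  sizes <- table(reference_ids)
  expanded <- names(sizes)[sizes >= 2]
  mean(clone_ids %in% expanded)
}

#' Shannon entropy of a clone-size distribution
#'
#' `H = -sum(p_i * log(p_i))` with `p_i = size_i / sum(sizes)`, natural
#' logarithm, unnormalized. `H = 0` for a single clone and `H = log(k)` for
#' `k` equally sized clones.
#'
#' @param clone_sizes vector of positive clone sizes.
#' @return non-negative real.
#' @export
shannon_entropy <- function(clone_sizes) {
  if (length(clone_sizes) == 0) stop("clone_sizes must be nonempty")
  if (any(clone_sizes <= 0)) stop("clone sizes must be positive")
  p <- clone_sizes / sum(clone_sizes)
  -sum(p * log(p))
}

#' Rarefied Shannon entropy
#'
#' Shannon entropy depends on the number of sampled cells, so comparing
#' compartments of unequal size conflates diversity with depth. Rarefaction
#' subsamples `depth` cells without replacement `n_resamples` times and
#' reports the mean and SD of the induced clone-size-distribution entropies.
#'
#' @param clone_ids per-cell clonotype labels.
#' @param depth number of cells per resample (`<=` number of cells).
#' @param n_resamples number of resamples (default 100).
#' @param seed RNG seed; results are bit-reproducible for a fixed seed.
#' @return list with `mean`, `sd`, `depth`, `n_resamples`.
#' @export
rarefied_entropy <- function(clone_ids, depth, n_resamples = 100, seed = 1) {
  clone_ids <- clone_ids[!is.na(clone_ids)]
  n <- length(clone_ids)
  if (depth > n) stop("depth (", depth, ") exceeds number of cells (", n, ")")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  ent <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      shannon_entropy(as.numeric(table(sample(clone_ids, depth))))
    }, numeric(1))
  })
  list(mean = mean(ent), sd = if (n_resamples > 1) sd(ent) else 0,
       depth = depth, n_resamples = n_resamples)
}

#' Per-group V-gene usage frequencies
#'
#' Usage frequencies of allele-stripped heavy-chain V genes within each group;
#' frequencies sum to 1 per group. Allele variants (`IGHV3-23*01`,
#' `IGHV3-23*04`) are pooled under the gene.
#'
#' @param cells data.frame with a `v_call` column and the grouping columns.
#' @param grouping character vector of grouping column names.
#' @return data.frame: grouping columns, `v_gene`, `frequency`, `n_cells`.
#' @export
vgene_usage <- function(cells, grouping) {
  stopifnot("v_call" %in% names(cells), all(grouping %in% names(cells)))
  cells <- cells[!is.na(cells$v_call) & cells$v_call != "", , drop = FALSE]
  cells$v_gene <- strip_allele(cells$v_call)
  key <- group_key(cells, grouping)
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sub <- cells[key == k, , drop = FALSE]
    tab <- table(sub$v_gene)
    cbind(sub[rep(1, length(tab)), grouping, drop = FALSE],
          data.frame(v_gene = names(tab),
                     frequency = as.numeric(tab) / nrow(sub),
                     n_cells = nrow(sub),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clonal statistics per compartment
#'
#' Convenience summary combining cell counts, clonotype counts, expanded
#' fraction and (optionally rarefied) Shannon entropy for each compartment
#' defined by the grouping columns.
#'
#' @param cells data.frame with `clonotype_id` plus grouping columns.
#' @param grouping character vector of compartment-defining columns.
#' @param rarefy_depth `NULL` for plain entropy, `"auto"` for the smallest
#'   compartment size, or an integer depth.
#' @param n_resamples,seed passed to [rarefied_entropy()].
#' @param expansion_scope `"compartment"` (default) scores expansion against
#'   compartment-restricted clone sizes; `"donor_wide"` against sizes over
#'   the whole input table.
#' @return data.frame: grouping columns, `n_cells`, `n_clonotypes`,
#'   `expanded_fraction`, `shannon_entropy`, `entropy_sd`, `entropy_depth`.
#' @export
clonal_stats <- function(cells, grouping, rarefy_depth = NULL,
                         n_resamples = 100, seed = 1,
                         expansion_scope = c("compartment", "donor_wide")) {
  expansion_scope <- match.arg(expansion_scope)
  stopifnot("clonotype_id" %in% names(cells), all(grouping %in% names(cells)))
  cells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  key <- group_key(cells, grouping)
  keys <- sort(unique(key))
  depth <- rarefy_depth
  if (identical(rarefy_depth, "auto")) depth <- min(table(key))
  rows <- lapply(keys, function(k) {
    sub <- cells[key == k, , drop = FALSE]
    sizes <- as.numeric(table(sub$clonotype_id))
    if (is.null(depth) || depth > nrow(sub)) {
      h <- shannon_entropy(sizes); hsd <- NA_real_; d <- NA_integer_
    } else {
      r <- rarefied_entropy(sub$clonotype_id, depth, n_resamples, seed)
      h <- r$mean; hsd <- r$sd; d <- as.integer(depth)
    }
    ref <- if (expansion_scope == "compartment") sub$clonotype_id else
      cells$clonotype_id
    cbind(sub[1, grouping, drop = FALSE],
          data.frame(n_cells = nrow(sub), n_clonotypes = length(sizes),
                     expanded_fraction = expanded_fraction(sub$clonotype_id,
                                                           ref),
                     shannon_entropy = h, entropy_sd = hsd, entropy_depth = d,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
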