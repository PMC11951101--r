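# Somatic hypermutation quantification against germline V alignments,
# naive-calibrated mutation threshold, isotype calls and in-silico memory
# B-cell identification.

.acgt <- utf8ToInt("ACGT")

#' Count somatic mutations against germline
#'
#' Compares each chain's gapped V-region alignment with its germline
#' alignment position by position. A position contributes to
#' `comparable_length` only when both symbols are unambiguous bases
#' (`A/C/G/T`); positions carrying `N`, `.` or `-` in either sequence are
#' excluded from both the numerator and the denominator, so insertions and
#' deletions are not counted as mutations. `n_mutations` is the number of
#' comparable positions where the two bases differ and
#' `mutation_rate = n_mutations / comparable_length`.
#'
#' @param chains data.frame with columns `sequence_id`, `sequence_alignment`
#'   and `germline_alignment` (equal lengths per row).
#' @return data.frame with one row per chain: `sequence_id`, `n_mutations`,
#'   `comparable_length`, `mutation_rate`.
#' @examples
#' count_mutations(data.frame(sequence_id = "s1",
#'                            sequence_alignment = "ATGAATGC",
#'                            germline_alignment = "ATGCATGC"))
#' @export
count_mutations <- function(chains) {
  stopifnot(is.data.frame(chains),
            all(c("sequence_id", "sequence_alignment",
                  "germline_alignment") %in% names(chains)))
  obs <- toupper(chains$sequence_alignment)
  germ <- toupper(chains$germline_alignment)
  if (any(nchar(obs) != nchar(germ))) {
    bad <- chains$sequence_id[nchar(obs) != nchar(germ)]
    stop("alignment length mismatch for sequence_id: ",
         paste(bad, collapse = ", "))
  }
  n <- length(obs)
  n_mut <- integer(n)
  comp <- integer(n)
  for (i in seq_len(n)) {
    oi <- utf8ToInt(obs[i])
    gi <- utf8ToInt(germ[i])
    ok <- oi %in% .acgt & gi %in% .acgt
    comp[i] <- sum(ok)
    n_mut[i] <- sum(oi[ok] != gi[ok])
  }
  if (any(comp == 0)) {
    bad <- chains$sequence_id[comp == 0]
    stop("degenerate alignment (no comparable positions) for sequence_id: ",
         paste(bad, collapse = ", "))
  }
  data.frame(sequence_id = chains$sequence_id,
             n_mutations = n_mut,
             comparable_length = comp,
             mutation_rate = n_mut / comp,
             stringsAsFactors = FALSE)
}

#' Calibrate the antigen-driven mutation threshold on sorted naive B cells
#'
#' Flow-sorted naive B cells (IgD+CD27-) carry germline-configured receptors,
#' so their apparent mutation counts estimate the technical noise floor
#' (sequencing error, allele mis-assignment). The threshold is the
#' nearest-rank `quantile` of the naive mutation-count distribution
#' (rank `ceiling(quantile * n)` of the sorted counts); downstream a chain is
#' called "mutated" iff its count strictly exceeds `threshold_count`, which
#' bounds the naive false-positive fraction by `1 - quantile` plus sampling
#' error.
#'
#' @param naive_counts integer vector of per-chain mutation counts from sorted
#'   naive B cells.
#' @param quantile calibration quantile in (0, 1]; default 0.99.
#' @param min_n minimum number of calibration chains (default 50).
#' @param chain_scope `"heavy_only"` (default) or `"heavy_and_light"`;
#'   recorded for provenance.
#' @return object of class `naive_threshold` with fields `threshold_count`,
#'   `quantile`, `n_naive_chains`, `chain_scope`.
#' @export
calibrate_naive_threshold <- function(naive_counts, quantile = 0.99,
                                      min_n = 50,
                                      chain_scope = c("heavy_only",
                                                      "heavy_and_light")) {
  chain_scope <- match.arg(chain_scope)
  if (!(quantile > 0 && quantile <= 1)) stop("quantile must be in (0, 1]")
  naive_counts <- naive_counts[!is.na(naive_counts)]
  n <- length(naive_counts)
  if (n < min_n) {
    stop("calibration error: only ", n, " naive chains (need >= ", min_n,
         "); supply more naive cells or set a fallback threshold constant")
  }
  sorted <- sort(naive_counts)
  rank <- ceiling(quantile * n)
  structure(list(threshold_count = as.integer(sorted[rank]),
                 quantile = quantile,
                 n_naive_chains = n,
                 chain_scope = chain_scope),
            class = "naive_threshold")
}

#' @export
print.naive_threshold <- function(x, ...) {
  cat("Naive-calibrated mutation threshold\n")
  cat(sprintf("  threshold_count: %d (call mutated iff count > threshold)\n",
              x$threshold_count))
  cat(sprintf("  quantile: %.3f (nearest-rank) on %d naive %s chains\n",
              x$quantile, x$n_naive_chains,
              if (x$chain_scope == "heavy_only") "heavy" else "heavy+light"))
  invisible(x)
}

.isotype_map <- c(IGHG1 = "IgG1", IGHG2 = "IgG2", IGHG3 = "IgG3",
                  IGHG4 = "IgG4", IGHA1 = "IgA1", IGHA2 = "IgA2",
                  IGHM = "IgM", IGHD = "IgD", IGHE = "IgE")
.class_map <- c(IgG1 = "IgG", IgG2 = "IgG", IgG3 = "IgG", IgG4 = "IgG",
                IgA1 = "IgA", IgA2 = "IgA", IgM = "IgM", IgD = "IgD",
                IgE = "IgE")

#' Call the immunoglobulin isotype from the constant-region gene
#'
#' The `c_call` is case-folded and prefix-matched against the heavy-chain
#' constant genes `IGHM, IGHD, IGHG1-4, IGHA1-2, IGHE` (subtypes matched
#' first; a bare class-level call such as `IGHG` yields isotype `unknown` but
#' resolves the class). Empty or unmatched calls yield
#' `unknown`/`unknown`/not-switched: unknown is a value, not an error. A chain
#' is class-switched iff its class is IgG, IgA or IgE.
#'
#' @param c_call character vector of constant-region gene calls (may be empty
#'   strings or NA).
#' @return data.frame with columns `isotype`, `isotype_class`,
#'   `class_switched`.
#' @export
call_isotype <- function(c_call) {
  cc <- toupper(ifelse(is.na(c_call), "", c_call))
  isotype <- rep("unknown", length(cc))
  for (gene in names(.isotype_map)) {
    hit <- isotype == "unknown" & startsWith(cc, gene)
    isotype[hit] <- .isotype_map[[gene]]
  }
  iso_class <- ifelse(isotype %in% names(.class_map),
                      .class_map[isotype], "unknown")
  # class-level fallback for calls without a subtype digit (e.g. "IGHG")
  bare <- which(isotype == "unknown")
  iso_class[bare[startsWith(cc[bare], "IGHG")]] <- "IgG"
  iso_class[bare[startsWith(cc[bare], "IGHA")]] <- "IgA"
  data.frame(isotype = isotype,
             isotype_class = iso_class,
             class_switched = iso_class %in% c("IgG", "IgA", "IgE"),
             stringsAsFactors = FALSE)
}

#' Identify memory B cells in silico
#'
#' Within the naive/memory compartment, a cell is called MBC iff its
#' heavy-chain mutation count strictly exceeds the naive-calibrated threshold
#' and/or its isotype is class-switched; otherwise it is `naive_like`.
#' Cells already labelled GCBC or PC upstream pass through unchanged. Cells
#' without an evaluable heavy chain are returned as `NA` and listed in the
#' `"unclassifiable"` attribute.
#'
#' @param cells data.frame with columns `cell_id`, `compartment` (values
#'   `naive_memory`, `GCBC`, `PC`), `n_mutations` and `class_switched`
#'   (heavy-chain based; `NA` when no heavy chain survived QC).
#' @param threshold a [calibrate_naive_threshold()] object.
#' @return character vector parallel to `cells` rows with values `MBC`,
#'   `naive_like`, `GCBC`, `PC` or `NA`; attribute `"unclassifiable"` holds
#'   the ids of cells with no heavy-chain evidence.
#' @export
classify_mbc <- function(cells, threshold) {
  stopifnot(inherits(threshold, "naive_threshold"),
            all(c("cell_id", "compartment", "n_mutations",
                  "class_switched") %in% names(cells)))
  out <- rep(NA_character_, nrow(cells))
  pass <- cells$compartment %in% c("GCBC", "PC")
  out[pass] <- cells$compartment[pass]
  nm <- cells$compartment == "naive_memory"
  evaluable <- nm & !is.na(cells$n_mutations)
  mutated <- cells$n_mutations > threshold$threshold_count
  switched <- cells$class_switched %in% TRUE
  out[evaluable] <- ifelse(mutated[evaluable] | switched[evaluable],
                           "MBC", "naive_like")
  unclass_ids <- cells$cell_id[nm & is.na(cells$n_mutations)]
  attr(out, "unclassifiable") <- unclass_ids
  out
}

#' Summarize mutation rates by metadata groups
#'
#' @param cells data.frame with one row per cell carrying `mutation_rate` and
#'   the grouping columns.
#' @param grouping character vector of column names to group by.
#' @param min_n groups with fewer cells are flagged (`small_group = TRUE`),
#'   not dropped.
#' @return data.frame: grouping columns, `mean_rate`, `median_rate`, `n`,
#'   `small_group`.
#' @export
shm_summary <- function(cells, grouping, min_n = 10) {
  missing <- setdiff(grouping, names(cells))
  if (length(missing) > 0) {
    stop("unknown grouping key(s): ", paste(missing, collapse = ", "))
  }
  cells <- cells[!is.na(cells$mutation_rate), , drop = FALSE]
  key <- group_key(cells, grouping)
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sub <- cells[key == k, , drop = FALSE]
    cbind(sub[1, grouping, drop = FALSE],
          data.frame(mean_rate = mean(sub$mutation_rate),
                     median_rate = median(sub$mutation_rate),
                     n = nrow(sub),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$small_group <- out$n < min_n
  out
}

#' Per-donor mutation increment from memory B cells to plasma cells
#'
#' For each donor and terminal-ileum region, returns the difference between
#' the mean heavy-chain mutation count of plasma cells and that of memory
#' B cells. The increment tracks the SHM acquired after MBC reactivation:
#' a smaller increment in inflamed regions indicates impaired post-memory
#' hypermutation. Donor/region cells with fewer than `min_cells` MBCs or PCs
#' yield `NA` with the reason recorded.
#'
#' @param cells data.frame with columns `donor_id`, `cell_type`,
#'   `n_mutations` and the column named by `region_col`.
#' @param region_col metadata column distinguishing regions (default
#'   `"inflammation"`).
#' @param min_cells minimum MBCs and PCs per donor/region (default 5).
#' @return data.frame: `donor_id`, region, `increment`, `n_mbc`, `n_pc`,
#'   `reason` (`NA` when valid).
#' @export
mbc_to_pc_increment <- function(cells, region_col = "inflammation",
                                min_cells = 5) {
  stopifnot(all(c("donor_id", "cell_type", "n_mutations", region_col)
                %in% names(cells)))
  cells <- cells[cells$cell_type %in% c("MBC", "PC") &
                   !is.na(cells$n_mutations), , drop = FALSE]
  key <- paste(cells$donor_id, cells[[region_col]], sep = "|")
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sub <- cells[key == k, , drop = FALSE]
    mbc <- sub$n_mutations[sub$cell_type == "MBC"]
    pc <- sub$n_mutations[sub$cell_type == "PC"]
    reason <- NA_character_
    inc <- NA_real_
    if (length(mbc) < min_cells || length(pc) < min_cells) {
      reason <- sprintf("insufficient cells (MBC=%d, PC=%d, need >= %d)",
                        length(mbc), length(pc), min_cells)
    } else {
      inc <- mean(pc) - mean(mbc)
    }
    data.frame(donor_id = sub$donor_id[1],
               region = sub[[region_col]][1],
               increment = inc, n_mbc = length(mbc), n_pc = length(pc),
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "region"] <- region_col
  rownames(out) <- NULL
  out
}

#' Per-group isotype frequencies
#'
#' Frequencies of heavy-chain isotypes (or isotype classes) within grouping
#' cells. Cells with unknown isotype are excluded from the denominator.
#'
#' @param cells data.frame with an `isotype` (and `isotype_class`) column plus
#'   the grouping columns.
#' @param grouping character vector of grouping column names.
#' @param level `"isotype"` (IgG1, IgA2, ...) or `"class"` (IgG, IgA, ...).
#' @return data.frame: grouping columns, `isotype`, `frequency`, `n_cells`
#'   (group denominator). Frequencies sum to 1 per group.
#' @export
isotype_frequencies <- function(cells, grouping,
                                level = c("isotype", "class")) {
  level <- match.arg(level)
  col <- if (level == "isotype") "isotype" else "isotype_class"
  stopifnot(col %in% names(cells), all(grouping %in% names(cells)))
  cells <- cells[!is.na(cells[[col]]) & cells[[col]] != "unknown", ,
                 drop = FALSE]
  key <- group_key(cells, grouping)
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sub <- cells[key == k, , drop = FALSE]
    tab <- table(sub[[col]])
    cbind(sub[rep(1, length(tab)), grouping, drop = FALSE],
          data.frame(isotype = names(tab),
                     frequency = as.numeric(tab) / nrow(sub),
                     n_cells = nrow(sub),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
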