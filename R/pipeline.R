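# End-to-end repertoire analysis: chain QC, SHM profiling, threshold
# calibration, in-silico MBC identification, clonotyping and the cohort-level
# summaries.

#' Build the per-cell analysis table
#'
#' Selects one heavy chain per cell (when a cell has several IGH rows the one
#' with the highest `consensus_count` is kept, falling back to the
#' lexicographically smallest `sequence_id`; the choice is reported in the
#' `"multi_heavy"` attribute), computes its mutation profile and isotype
#' call, and joins the cell metadata.
#'
#' @param airr validated chain table (see [read_airr()]).
#' @param metadata per-cell metadata with `cell_id`.
#' @return data.frame with one row per metadata cell: metadata columns plus
#'   `sequence_id`, `v_call`, `j_call`, `junction_aa`, `n_mutations`,
#'   `comparable_length`, `mutation_rate`, `isotype`, `isotype_class`,
#'   `class_switched` (NA where no heavy chain was found).
#' @export
build_cell_table <- function(airr, metadata) {
  stopifnot("cell_id" %in% names(airr), "cell_id" %in% names(metadata))
  heavy <- airr[is.na(airr$locus) | airr$locus %in% c("", "IGH"), ,
                drop = FALSE]
  cc <- if ("consensus_count" %in% names(heavy)) {
    suppressWarnings(as.numeric(heavy$consensus_count))
  } else rep(NA_real_, nrow(heavy))
  cc[is.na(cc)] <- -Inf
  ord <- order(heavy$cell_id, -cc, heavy$sequence_id)
  heavy <- heavy[ord, , drop = FALSE]
  dup <- duplicated(heavy$cell_id)
  multi <- unique(heavy$cell_id[dup])
  heavy <- heavy[!dup, , drop = FALSE]
  prof <- count_mutations(heavy)
  iso <- call_isotype(heavy$c_call %||% rep("", nrow(heavy)))
  heavy_tab <- cbind(
    heavy[, intersect(c("cell_id", "sequence_id", "v_call", "j_call",
                        "junction_aa"), names(heavy)), drop = FALSE],
    prof[, c("n_mutations", "comparable_length", "mutation_rate")], iso)
  out <- merge(metadata, heavy_tab, by = "cell_id", all.x = TRUE,
               sort = FALSE)
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "multi_heavy") <- multi
  out
}

#' Run the full repertoire analysis
#'
#' The standard pipeline over a chain table and cell metadata:
#' heavy-chain selection and SHM profiling ([build_cell_table()]), mutation
#' threshold calibration on the sorted naive cells
#' ([calibrate_naive_threshold()]), in-silico MBC identification
#' ([classify_mbc()]), donor-scoped clonotyping ([assign_clonotypes()]) and
#' the cohort summaries: SHM by disease group and cell type, isotype
#' frequencies, clonal statistics, MBC-PC similarity and (when donor scores
#' are given) the resident-like-MBC versus disease-score association.
#'
#' @param airr chain table (validated AIRR rows).
#' @param metadata per-cell metadata: `cell_id`, `donor_id`,
#'   `disease_group`, `tissue`, `inflammation`, `sorted_gate`, `compartment`
#'   (`naive_memory`/`GCBC`/`PC`), optional `cluster_label`.
#' @param donors optional donor table with `donor_id`, `disease_group` and
#'   `disease_score`.
#' @param quantile naive-threshold calibration quantile (default 0.99).
#' @param min_calibration_n minimum naive chains for calibration.
#' @param min_clonotypes minimum clonotypes per compartment for similarity.
#' @param metric similarity metric, `"overlap"` or `"jaccard"`.
#' @return object of class `bcr_analysis`; see the fields documented in the
#'   vignette. Use `summary()` for the headline cohort contrasts.
#' @export
analyze_repertoire <- function(airr, metadata, donors = NULL,
                               quantile = 0.99, min_calibration_n = 50,
                               min_clonotypes = 10,
                               metric = c("overlap", "jaccard")) {
  metric <- match.arg(metric)
  cells <- build_cell_table(airr, metadata)
  naive <- cells[cells$sorted_gate == "naive" & !is.na(cells$n_mutations), ]
  threshold <- calibrate_naive_threshold(naive$n_mutations,
                                         quantile = quantile,
                                         min_n = min_calibration_n)
  ag <- cells[cells$sorted_gate != "naive", , drop = FALSE]
  ag$cell_type <- classify_mbc(ag, threshold)
  ag$cell_type[ag$cell_type == "naive_like"] <- "NBC"

  with_junction <- ag[!is.na(ag$junction_aa) & ag$junction_aa != "" &
                        !is.na(ag$v_call), , drop = FALSE]
  clon <- assign_clonotypes(with_junction)
  ag <- merge(ag, clon$cells[, c("cell_id", "clonotype_id")],
              by = "cell_id", all.x = TRUE, sort = FALSE)
  ag <- ag[order(ag$cell_id), , drop = FALSE]
  rownames(ag) <- NULL

  shm_by_group <- shm_summary(
    ag[ag$cell_type %in% c("MBC", "GCBC", "PC"), ],
    grouping = c("disease_group", "cell_type"))
  iso_freq <- isotype_frequencies(
    ag[ag$cell_type %in% c("MBC", "GCBC", "PC"), ],
    grouping = c("donor_id", "disease_group", "tissue", "inflammation",
                 "cell_type"))
  expansion <- clonal_stats(
    ag[!is.na(ag$clonotype_id) & ag$cell_type %in% c("MBC", "GCBC", "PC"), ],
    grouping = c("donor_id", "disease_group", "tissue", "cell_type"))
  usage <- vgene_usage(ag[ag$cell_type %in% c("MBC", "GCBC", "PC"), ],
                       grouping = c("disease_group", "cell_type"))
  mbc_pc <- cross_tissue_similarity(
    ag, cell_type_pair = c("MBC", "PC"), tissue_pair = c("TI", "TI"),
    min_clonotypes = min_clonotypes, metric = metric)

  association <- NULL
  if (!is.null(donors) && "disease_score" %in% names(donors)) {
    ti_mbc <- ag$cell_type == "MBC" & ag$tissue == "TI"
    resident <- ti_mbc & ag$cluster_label == "resident_like"
    if (any(resident, na.rm = TRUE)) {
      props <- subset_proportions(ag, resident, ti_mbc, per = "donor_id")
      m <- merge(props, donors[, c("donor_id", "disease_score")],
                 by = "donor_id")
      m <- m[!is.na(m$disease_score), , drop = FALSE]
      if (nrow(m) >= 3 && sd(m$proportion) > 0) {
        association <- correlate_with_disease(m$proportion, m$disease_score)
        association$data <- m
      }
    }
  }

  structure(list(cells = ag,
                 threshold = threshold,
                 clonotypes = clon$clonotypes,
                 shm_by_group = shm_by_group,
                 isotype_frequencies = iso_freq,
                 expansion = expansion,
                 vgene_usage = usage,
                 mbc_pc_similarity = mbc_pc,
                 association = association),
            class = "bcr_analysis")
}

#' @export
print.bcr_analysis <- function(x, ...) {
  cat("BCR repertoire analysis\n")
  cat("  cells analysed:", nrow(x$cells), "in",
      length(unique(x$cells$donor_id)), "donors;",
      nrow(x$clonotypes), "clonotypes\n")
  cat("  mutation threshold:", x$threshold$threshold_count,
      sprintf("(quantile %.2f on %d naive chains)\n",
              x$threshold$quantile, x$threshold$n_naive_chains))
  tab <- table(x$cells$cell_type)
  cat("  cell types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Headline disease contrasts of a repertoire analysis
#'
#' Computes the cohort-level effect summaries: the CD vs non-IBD SHM
#' contrast in antigen-experienced cells, paired isotype shifts between
#' inflamed and non-inflamed TI regions (IgA and IgG1 in PCs, IgM in MBCs),
#' the MBC-PC clonotype-similarity contrast between disease groups, and the
#' resident-like-MBC proportion vs disease-score association.
#'
#' @param object a `bcr_analysis` object.
#' @param ... unused.
#' @return object of class `summary.bcr_analysis`: a list of the contrast
#'   results, each carrying its estimate(s) and p value.
#' @export
summary.bcr_analysis <- function(object, ...) {
  cells <- object$cells
  ag <- cells[cells$cell_type %in% c("MBC", "GCBC", "PC") &
                !is.na(cells$mutation_rate), , drop = FALSE]
  shm <- compare_groups(ag$mutation_rate, ag$disease_group,
                        test = "t_two_tailed")

  iso <- object$isotype_frequencies
  paired_iso <- function(cell_type, isotype) {
    sub <- iso[iso$cell_type == cell_type & iso$tissue == "TI" &
                 iso$disease_group == "CD" &
                 iso$inflammation %in% c("inflamed", "non_inflamed"), ,
               drop = FALSE]
    # donors with both regions; absent isotype rows mean frequency 0
    donors <- intersect(sub$donor_id[sub$inflammation == "inflamed"],
                        sub$donor_id[sub$inflammation == "non_inflamed"])
    if (length(donors) < 2) return(NULL)
    grid <- expand.grid(donor_id = donors,
                        inflammation = c("inflamed", "non_inflamed"),
                        stringsAsFactors = FALSE)
    sub <- sub[sub$isotype == isotype, , drop = FALSE]
    m <- merge(grid, sub[, c("donor_id", "inflammation", "frequency")],
               by = c("donor_id", "inflammation"), all.x = TRUE)
    m$frequency[is.na(m$frequency)] <- 0
    compare_groups(m$frequency, m$inflammation, test = "paired_t",
                   pair_ids = m$donor_id)
  }
  iga_pc <- paired_iso("PC", "IgA1")
  # pool IgA1+IgA2 into an IgA-class paired contrast
  iso_class <- isotype_frequencies(
    cells[cells$cell_type == "PC", ],
    grouping = c("donor_id", "disease_group", "tissue", "inflammation",
                 "cell_type"), level = "class")
  paired_class <- function(frame, cell_type, klass) {
    sub <- frame[frame$cell_type == cell_type & frame$tissue == "TI" &
                   frame$disease_group == "CD" &
                   frame$inflammation %in% c("inflamed", "non_inflamed"), ,
                 drop = FALSE]
    donors <- intersect(sub$donor_id[sub$inflammation == "inflamed"],
                        sub$donor_id[sub$inflammation == "non_inflamed"])
    if (length(donors) < 2) return(NULL)
    grid <- expand.grid(donor_id = donors,
                        inflammation = c("inflamed", "non_inflamed"),
                        stringsAsFactors = FALSE)
    sub <- sub[sub$isotype == klass, , drop = FALSE]
    m <- merge(grid, sub[, c("donor_id", "inflammation", "frequency")],
               by = c("donor_id", "inflammation"), all.x = TRUE)
    m$frequency[is.na(m$frequency)] <- 0
    compare_groups(m$frequency, m$inflammation, test = "paired_t",
                   pair_ids = m$donor_id)
  }
  iga_class_pc <- paired_class(iso_class, "PC", "IgA")
  igg1_pc <- paired_iso("PC", "IgG1")
  igm_mbc <- paired_iso("MBC", "IgM")

  sim <- object$mbc_pc_similarity
  sim_cmp <- if (length(unique(sim$disease_group[!is.na(sim$similarity)]))
                 >= 2) {
    compare_similarity_groups(sim, "disease_group")
  }

  structure(list(shm_cd_vs_nonibd = shm,
                 iga_pc_inflamed_vs_non = iga_class_pc %||% iga_pc,
                 igg1_pc_inflamed_vs_non = igg1_pc,
                 igm_mbc_inflamed_vs_non = igm_mbc,
                 mbc_pc_similarity_cd_vs_nonibd = sim_cmp,
                 resident_mbc_vs_disease_score = object$association),
            class = "summary.bcr_analysis")
}

#' @export
print.summary.bcr_analysis <- function(x, ...) {
  show <- function(label, cmp) {
    if (is.null(cmp)) {
      cat(sprintf("  %-42s (not estimable)\n", label))
    } else if (inherits(cmp, "association_result")) {
      cat(sprintf("  %-42s r = %+.3f, p = %.3g (n = %d)\n", label,
                  cmp$pearson_r, cmp$p_value, cmp$n))
    } else {
      d <- diff(rev(cmp$estimate))
      cat(sprintf("  %-42s %s=%.4g vs %s=%.4g, p = %.3g\n", label,
                  names(cmp$estimate)[1], cmp$estimate[1],
                  names(cmp$estimate)[2], cmp$estimate[2], cmp$p_value))
    }
  }
  cat("Cohort-level disease contrasts\n")
  show("SHM rate, CD vs nonIBD:", x$shm_cd_vs_nonibd)
  show("IgA PC freq, inflamed vs non-inflamed TI:", x$iga_pc_inflamed_vs_non)
  show("IgG1 PC freq, inflamed vs non-inflamed TI:",
       x$igg1_pc_inflamed_vs_non)
  show("IgM MBC freq, inflamed vs non-inflamed TI:",
       x$igm_mbc_inflamed_vs_non)
  show("MBC-PC similarity, CD vs nonIBD:", x$mbc_pc_similarity_cd_vs_nonibd)
  show("resident-like MBC prop vs disease score:",
       x$resident_mbc_vs_disease_score)
  invisible(x)
}
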