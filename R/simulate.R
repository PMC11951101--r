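# Fully seeded synthetic study generator: germline reference, single-cell
# AIRR repertoires with clonal structure / SHM / class switching, cell and
# donor metadata, a small expression matrix with matching gene sets, and
# ground truth for parameter-recovery tests.

.ighv_names <- c(
  "IGHV1-2", "IGHV1-8", "IGHV1-18", "IGHV1-24", "IGHV1-46", "IGHV1-69",
  "IGHV2-5", "IGHV2-26", "IGHV2-70", "IGHV3-7", "IGHV3-9", "IGHV3-11",
  "IGHV3-15", "IGHV3-21", "IGHV3-23", "IGHV3-30", "IGHV3-33", "IGHV3-48",
  "IGHV3-49", "IGHV3-53", "IGHV3-74", "IGHV4-4", "IGHV4-31", "IGHV4-34",
  "IGHV4-39", "IGHV4-59", "IGHV4-61", "IGHV5-51", "IGHV6-1", "IGHV7-4-1")

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.c_gene_of <- c(IgM = "IGHM", IgD = "IGHD", IgG1 = "IGHG1", IgG2 = "IGHG2",
                IgG3 = "IGHG3", IgG4 = "IGHG4", IgA1 = "IGHA1",
                IgA2 = "IGHA2", IgE = "IGHE")
.iso_cols <- c("IgM", "IgD", "IgG1", "IgG2", "IgG3", "IgA1", "IgA2")

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.build_germline_seqs <- function(n_v, n_j, v_length, j_length) {
  v_names <- if (n_v <= length(.ighv_names)) .ighv_names[seq_len(n_v)] else
    c(.ighv_names, sprintf("IGHV9-%d", seq_len(n_v - length(.ighv_names))))
  list(v = setNames(.random_dna(n_v, v_length), paste0(v_names, "*01")),
       j = setNames(.random_dna(n_j, j_length),
                    sprintf("IGHJ%d*01", seq_len(n_j))))
}

#' Generate a synthetic germline V/J segment reference
#'
#' Random unambiguous-base segments with IMGT-style names
#' (`IGHV{family}-{gene}*01`, `IGHJ{n}*01`); a synthetic stand-in for a
#' curated germline database, deterministic per seed.
#'
#' @param n_v,n_j numbers of V and J segments.
#' @param v_length,j_length segment lengths in nucleotides.
#' @param seed RNG seed.
#' @return list with named character vectors `v` and `j`.
#' @export
build_germline <- function(n_v = 30, n_j = 6, v_length = 300, j_length = 48,
                           seed = 1) {
  stopifnot(n_v >= 1, n_j >= 1)
  with_seed(seed, .build_germline_seqs(n_v, n_j, v_length, j_length))
}

.default_shm_lambda <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
cell_type disease_group region       lambda
NBC       any           any          0.3
MBC       nonIBD        any          6
MBC       CD            any          4
GCBC      nonIBD        any          8
GCBC      CD            any          6
PC        nonIBD        any          12
PC        CD            non_inflamed 10
PC        CD            inflamed     6
")
}

.default_isotype_probs <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
cell_type disease_group region   IgM  IgD  IgG1 IgG2 IgG3 IgA1 IgA2
NBC       any           any      0.60 0.40 0.00 0.00 0.00 0.00 0.00
MBC       any           any      0.25 0.05 0.15 0.05 0.05 0.30 0.15
MBC       CD            inflamed 0.45 0.05 0.15 0.05 0.05 0.17 0.08
GCBC      any           any      0.20 0.00 0.20 0.05 0.05 0.35 0.15
PC        any           any      0.05 0.00 0.15 0.05 0.05 0.45 0.25
PC        CD            inflamed 0.05 0.00 0.40 0.07 0.05 0.28 0.15
")
  df
}

# most-specific-first wildcard lookup in a strata table
.stratum_row <- function(table, cell_type, disease_group, region) {
  cand <- rbind(c(cell_type, disease_group, region),
                c(cell_type, disease_group, "any"),
                c(cell_type, "any", region),
                c(cell_type, "any", "any"),
                c("any", disease_group, region),
                c("any", disease_group, "any"),
                c("any", "any", region),
                c("any", "any", "any"))
  for (i in seq_len(nrow(cand))) {
    hit <- table$cell_type == cand[i, 1] &
      table$disease_group == cand[i, 2] & table$region == cand[i, 3]
    if (any(hit)) return(table[which(hit)[1], , drop = FALSE])
  }
  stop("no stratum for (", cell_type, ", ", disease_group, ", ", region, ")")
}

#' Configure a synthetic cohort
#'
#' Assembles and validates the generator's parameters. Defaults describe a
#' neutral multi-donor, multi-tissue design with no disease effects; see
#' [default_cd_scenario()] for the canonical Crohn's-disease scenario with
#' designed effect directions.
#'
#' @param n_donors named integer vector, donors per disease group.
#' @param cells_per_sample antigen-experienced cells per donor and sample.
#' @param cell_type_probs named list (per tissue) of probability vectors over
#'   `NBC, MBC, GCBC, PC`; each sums to 1.
#' @param resident_mbc_beta named list of Beta(a, b) shape pairs per disease
#'   group for the per-donor resident-like MBC propensity in the terminal
#'   ileum.
#' @param clone_geom_prob named vector of geometric success probabilities per
#'   cell type (mean clone size `1/p`).
#' @param shm_lambda strata table (`cell_type`, `disease_group`, `region`,
#'   `lambda`) with `"any"` wildcards; Poisson mean mutation counts.
#' @param naive_lambda Poisson mean for sorted naive calibration cells.
#' @param isotype_probs strata table of isotype probability vectors
#'   (`IgM ... IgA2` columns, rows sum to 1, `"any"` wildcards).
#' @param mbc_pc_sharing named vector per disease group: fraction of plasma
#'   cells assigned to clones that also contain memory B cells of the same
#'   donor.
#' @param vgene_boost list (`gene`, `factor`, `cell_type`, `disease_group`)
#'   multiplying one V gene's sampling weight in the named stratum, or NULL.
#' @param disease_score list: `intercept`, `slope` (on the resident-like MBC
#'   proportion), and either `sd` (noise SD, score units) or `target_rho`
#'   (calibrates the noise SD to the realized cross-donor proportion spread
#'   so the model correlation equals `target_rho`).
#' @param expression list: `n_genes`, `n_cells` (cells carried into the
#'   matrix), `set_size` (genes per emitted signature), `ifn_shift`
#'   (log-units added to IFN-set genes in inflamed-region cells), `base_sd`.
#' @param germline list: `n_v`, `n_j`, `v_length`.
#' @param naive_cells_per_donor,n_naive_donors sorted naive blood cells used
#'   for threshold calibration.
#' @param emit_light_chains also emit one IGK chain per cell.
#' @param light_lambda_factor light-chain Poisson mean as a multiple of the
#'   stratum's heavy-chain mean.
#' @param junction_length_aa junction (CDR3) length in amino acids.
#' @param seed RNG seed; every draw in [simulate_cohort()] derives from it.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = c(CD = 8, nonIBD = 7),
                          cells_per_sample = 150,
                          cell_type_probs = list(
                            blood = c(NBC = 0.10, MBC = 0.45, GCBC = 0.00,
                                      PC = 0.45),
                            colon = c(NBC = 0.10, MBC = 0.40, GCBC = 0.15,
                                      PC = 0.35),
                            TI = c(NBC = 0.10, MBC = 0.40, GCBC = 0.15,
                                   PC = 0.35)),
                          resident_mbc_beta = list(CD = c(5, 5),
                                                   nonIBD = c(3, 7)),
                          clone_geom_prob = c(NBC = 0.95, MBC = 0.60,
                                              GCBC = 0.50, PC = 0.55),
                          shm_lambda = .default_shm_lambda(),
                          naive_lambda = 0.3,
                          isotype_probs = .default_isotype_probs(),
                          mbc_pc_sharing = c(CD = 0, nonIBD = 0),
                          vgene_boost = NULL,
                          disease_score = list(intercept = 5, slope = 30,
                                               sd = 3, target_rho = NULL),
                          expression = list(n_genes = 300, n_cells = 1000,
                                            set_size = 20, ifn_shift = 1,
                                            base_sd = 0.4),
                          germline = list(n_v = 30, n_j = 6, v_length = 300),
                          naive_cells_per_donor = 60,
                          n_naive_donors = 5,
                          emit_light_chains = FALSE,
                          light_lambda_factor = 0.6,
                          junction_length_aa = 13,
                          seed = 1) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' @param cfg a [cohort_config()] list.
#' @return `cfg` invisibly; errors describe the violated constraint.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  for (tis in names(cfg$cell_type_probs)) {
    p <- cfg$cell_type_probs[[tis]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("cell_type_probs[['", tis, "']] must be a probability vector")
    }
  }
  iso <- cfg$isotype_probs
  sums <- rowSums(iso[, .iso_cols, drop = FALSE])
  if (any(abs(sums - 1) > 1e-6) || any(iso[, .iso_cols] < 0)) {
    stop("isotype_probs rows must be probability vectors over ",
         paste(.iso_cols, collapse = ", "))
  }
  if (any(cfg$shm_lambda$lambda < 0)) stop("shm_lambda must be >= 0")
  if (any(cfg$mbc_pc_sharing < 0 | cfg$mbc_pc_sharing > 1)) {
    stop("mbc_pc_sharing must lie in [0, 1]")
  }
  if (any(cfg$clone_geom_prob <= 0 | cfg$clone_geom_prob > 1)) {
    stop("clone_geom_prob must lie in (0, 1]")
  }
  for (g in names(cfg$n_donors)) {
    if (cfg$mbc_pc_sharing[[g]] > 0) {
      # every tissue with PCs must also produce MBC clones somewhere
      has_mbc <- any(vapply(cfg$cell_type_probs,
                            function(p) p[["MBC"]] > 0, logical(1)))
      if (!has_mbc) {
        stop("infeasible composition: mbc_pc_sharing > 0 for ", g,
             " but no tissue produces MBCs")
      }
    }
  }
  invisible(cfg)
}

#' Canonical Crohn's-disease cohort scenario
#'
#' The regression-test scenario: 8 CD and 7 non-IBD donors, four sample
#' types (blood, colon, non-inflamed TI for everyone; inflamed TI for CD
#' donors), with five designed disease-effect directions: lower SHM in CD
#' antigen-experienced cells, an IgA-to-IgG1 switch-probability shift in
#' inflamed-TI plasma cells, an IgM increase in inflamed-TI memory B cells,
#' higher MBC-PC clonotype sharing in CD, and a positive correlation between
#' the resident-like MBC proportion and the donor disease score.
#'
#' @param seed RNG seed.
#' @param null_effects if TRUE, all CD-specific effects are removed (CD
#'   strata copy the non-IBD parameters and the disease score is noise only);
#'   used for global-null calibration checks.
#' @return a [cohort_config()] object.
#' @export
default_cd_scenario <- function(seed = 1, null_effects = FALSE) {
  if (!null_effects) {
    return(cohort_config(
      mbc_pc_sharing = c(CD = 0.30, nonIBD = 0.05),
      vgene_boost = list(gene = "IGHV3-23", factor = 3, cell_type = "MBC",
                         disease_group = "CD"),
      disease_score = list(intercept = 5, slope = 30, sd = NULL,
                           target_rho = 0.95),
      seed = seed))
  }
  lam <- .default_shm_lambda()
  lam <- lam[lam$disease_group != "CD", , drop = FALSE]
  lam$disease_group[lam$disease_group == "nonIBD"] <- "any"
  iso <- .default_isotype_probs()
  iso <- iso[iso$disease_group == "any", , drop = FALSE]
  cohort_config(
    shm_lambda = lam,
    isotype_probs = iso,
    mbc_pc_sharing = c(CD = 0.05, nonIBD = 0.05),
    resident_mbc_beta = list(CD = c(3, 7), nonIBD = c(3, 7)),
    disease_score = list(intercept = 5, slope = 0, sd = 3, target_rho = NULL),
    seed = seed)
}

# geometric clone-size law (support 1, 2, ...); trimmed to cover n_cells
# exactly, so clone sizes partition the compartment's cells.
draw_clone_sizes <- function(n_cells, prob) {
  if (n_cells == 0) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, rgeom(max(16L, ceiling(n_cells * prob)), prob) + 1L)
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_cells)
  sizes[sizes > 0]
}

.mutate_sequence <- function(germ_chars, k) {
  if (k == 0) return(paste(germ_chars, collapse = ""))
  len <- length(germ_chars)
  k <- min(k, len)
  pos <- sample.int(len, k)
  for (p in pos) {
    germ_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), germ_chars[p]), 1)
  }
  paste(germ_chars, collapse = "")
}

.random_junction <- function(len_aa) {
  paste(c("C", sample(.aa_alphabet, len_aa - 2, replace = TRUE), "W"),
        collapse = "")
}

#' Simulate a synthetic multi-tissue BCR cohort
#'
#' Realizes the design in a [cohort_config()]: per donor, antigen-experienced
#' cells are drawn per sample and cell type, grouped into donor-scoped clones
#' under a geometric clone-size law (clones may span tissues), each clone
#' receives a germline V/J and an exact junction, each cell draws a Poisson
#' mutation count for its (cell type, disease, region) stratum and that many
#' unique-position substitutions over the V segment, and an isotype from the
#' stratum's switch vector. A fraction of plasma cells is re-assigned to
#' clones containing memory B cells of the same donor (the MBC-PC sharing
#' dial). Sorted naive blood cells are emitted for threshold calibration;
#' donor disease scores follow a linear model in the realized resident-like
#' MBC proportion; a small expression matrix realizes the configured
#' IFN-signature shift in inflamed-region cells. Identical config and seed
#' reproduce every output exactly.
#'
#' @param cfg a [cohort_config()] object.
#' @return list of class `bcr_cohort`: `airr` (chain table), `metadata`
#'   (cell table), `donors`, `germline` (list `v`, `j`), `expression`
#'   (cells x genes matrix), `gene_sets`, `truth` (per-cell and per-donor
#'   ground truth plus the realized config).
#' @export
simulate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  with_seed(cfg$seed, .simulate_cohort_impl(cfg))
}

.simulate_cohort_impl <- function(cfg) {
  germ <- .build_germline_seqs(cfg$germline$n_v, cfg$germline$n_j,
                               cfg$germline$v_length, 48)
  v_genes <- strip_allele(names(germ$v))
  v_chars <- lapply(germ$v, function(s) strsplit(s, "")[[1]])
  donors <- data.frame(
    donor_id = c(sprintf("CD%02d", seq_len(cfg$n_donors[["CD"]])),
                 sprintf("N%02d", seq_len(cfg$n_donors[["nonIBD"]]))),
    disease_group = rep(c("CD", "nonIBD"), cfg$n_donors[c("CD", "nonIBD")]),
    stringsAsFactors = FALSE)

  chain_rows <- list()
  cell_rows <- list()
  truth_rows <- list()
  resident_prop <- setNames(rep(NA_real_, nrow(donors)), donors$donor_id)

  for (d in seq_len(nrow(donors))) {
    donor <- donors$donor_id[d]
    disease <- donors$disease_group[d]
    samples <- data.frame(
      code = c("BL", "CO", "TIN"),
      tissue = c("blood", "colon", "TI"),
      inflammation = c("not_applicable", "non_inflamed", "non_inflamed"),
      stringsAsFactors = FALSE)
    if (disease == "CD") {
      samples <- rbind(samples, data.frame(
        code = "TII", tissue = "TI", inflammation = "inflamed"))
    }
    # per-sample cell-type counts
    counts <- lapply(seq_len(nrow(samples)), function(si) {
      p <- cfg$cell_type_probs[[samples$tissue[si]]]
      drop(rmultinom(1, cfg$cells_per_sample, p))
    })
    counts <- do.call(rbind, counts) # samples x cell types
    cell_types <- colnames(counts)

    # donor-wide clone universe per cell type
    donor_cells <- list()
    clone_meta <- list() # clone_id -> v_call, j_call, junction
    for (ct in cell_types) {
      n_ct <- sum(counts[, ct])
      if (n_ct == 0) next
      sizes <- draw_clone_sizes(n_ct, cfg$clone_geom_prob[[ct]])
      clone_ids <- sprintf("%s_%s_cl%04d", donor, ct, seq_along(sizes))
      w <- rep(1, length(v_genes))
      vb <- cfg$vgene_boost
      if (!is.null(vb) && identical(vb$cell_type, ct) &&
          identical(vb$disease_group, disease)) {
        w[v_genes == vb$gene] <- vb$factor
      }
      v_idx <- sample.int(length(v_genes), length(sizes), replace = TRUE,
                          prob = w / sum(w))
      j_idx <- sample.int(length(germ$j), length(sizes), replace = TRUE)
      for (ci in seq_along(sizes)) {
        clone_meta[[clone_ids[ci]]] <- list(
          v_call = names(germ$v)[v_idx[ci]],
          j_call = names(germ$j)[j_idx[ci]],
          junction_aa = .random_junction(cfg$junction_length_aa),
          v_index = v_idx[ci])
      }
      membership <- sample(rep(clone_ids, sizes))
      # spread over samples in row order
      sample_of <- rep(seq_len(nrow(samples)), counts[, ct])
      donor_cells[[ct]] <- data.frame(
        clone_id = membership, cell_type = ct,
        sample_index = sample_of, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, donor_cells)
    rownames(cells) <- NULL

    # MBC <-> PC clonotype sharing
    s <- cfg$mbc_pc_sharing[[disease]]
    if (s > 0) {
      mbc_clones <- unique(cells$clone_id[cells$cell_type == "MBC"])
      pc_idx <- which(cells$cell_type == "PC")
      if (length(pc_idx) > 0) {
        if (length(mbc_clones) == 0) {
          stop("infeasible composition: sharing fraction ", s, " for donor ",
               donor, " but no MBC clones exist")
        }
        n_share <- round(s * length(pc_idx))
        take <- sample(pc_idx, n_share)
        cells$clone_id[take] <- sample(mbc_clones, n_share, replace = TRUE)
      }
    }

    # resident-like MBC cluster labels
    shp <- cfg$resident_mbc_beta[[disease]]
    propensity <- rbeta(1, shp[1], shp[2])
    tissue_mult <- c(blood = 0.02 / max(propensity, 1e-6), colon = 0.5,
                     TI = 1.0)
    cells$cluster_label <- NA_character_
    is_mbc <- cells$cell_type == "MBC"
    tis <- samples$tissue[cells$sample_index]
    pr <- pmin(1, propensity * tissue_mult[tis])
    lab <- ifelse(rbinom(nrow(cells), 1, pr) == 1, "resident_like",
                  "circulating")
    cells$cluster_label[is_mbc] <- lab[is_mbc]
    ti_mbc <- is_mbc & tis == "TI"
    resident_prop[donor] <- if (any(ti_mbc)) {
      mean(cells$cluster_label[ti_mbc] == "resident_like")
    } else NA_real_

    # per-cell chains
    cells$cell_id <- sprintf("%s_%s_%04d", donor,
                             samples$code[cells$sample_index],
                             stats::ave(seq_len(nrow(cells)),
                                        cells$sample_index, FUN = seq_along))
    region <- ifelse(samples$inflammation[cells$sample_index] == "inflamed",
                     "inflamed", "non_inflamed")
    lambda <- vapply(seq_len(nrow(cells)), function(i) {
      .stratum_row(cfg$shm_lambda, cells$cell_type[i], disease,
                   region[i])$lambda
    }, numeric(1))
    k <- rpois(nrow(cells), lambda)
    iso_key <- paste(cells$cell_type, region)
    isotype <- character(nrow(cells))
    for (kk in unique(iso_key)) {
      idx <- which(iso_key == kk)
      row <- .stratum_row(cfg$isotype_probs, cells$cell_type[idx[1]],
                          disease, region[idx[1]])
      p <- as.numeric(row[, .iso_cols])
      isotype[idx] <- sample(.iso_cols, length(idx), replace = TRUE, prob = p)
    }
    seqs <- character(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      vi <- clone_meta[[cells$clone_id[i]]]$v_index
      seqs[i] <- .mutate_sequence(v_chars[[vi]], k[i])
    }
    cm <- clone_meta[cells$clone_id]
    heavy <- data.frame(
      sequence_id = paste0(cells$cell_id, "_IGH"),
      cell_id = cells$cell_id,
      locus = "IGH",
      v_call = vapply(cm, `[[`, character(1), "v_call"),
      j_call = vapply(cm, `[[`, character(1), "j_call"),
      c_call = paste0(.c_gene_of[isotype], "*01"),
      junction_aa = vapply(cm, `[[`, character(1), "junction_aa"),
      junction = .random_dna(nrow(cells), 3 * cfg$junction_length_aa),
      sequence_alignment = seqs,
      germline_alignment = unname(germ$v[vapply(cm, `[[`, numeric(1),
                                                "v_index")]),
      stringsAsFactors = FALSE)
    chain_rows[[donor]] <- heavy
    if (cfg$emit_light_chains) {
      kl <- rpois(nrow(cells), cfg$light_lambda_factor * lambda)
      lseqs <- vapply(seq_len(nrow(cells)), function(i) {
        vi <- clone_meta[[cells$clone_id[i]]]$v_index
        .mutate_sequence(v_chars[[vi]], kl[i])
      }, character(1))
      light <- heavy
      light$sequence_id <- paste0(cells$cell_id, "_IGK")
      light$locus <- "IGK"
      light$v_call <- sub("^IGHV", "IGKV", light$v_call)
      light$j_call <- sub("^IGHJ", "IGKJ", light$j_call)
      light$c_call <- "IGKC"
      light$sequence_alignment <- lseqs
      chain_rows[[paste0(donor, "_light")]] <- light
    }

    cell_rows[[donor]] <- data.frame(
      cell_id = cells$cell_id,
      donor_id = donor,
      disease_group = disease,
      tissue = samples$tissue[cells$sample_index],
      inflammation = samples$inflammation[cells$sample_index],
      sorted_gate = "antigen_experienced",
      compartment = ifelse(cells$cell_type %in% c("GCBC", "PC"),
                           cells$cell_type, "naive_memory"),
      cluster_label = ifelse(is.na(cells$cluster_label), "",
                             cells$cluster_label),
      stringsAsFactors = FALSE)
    truth_rows[[donor]] <- data.frame(
      cell_id = cells$cell_id,
      clone_id = cells$clone_id,
      cell_type = cells$cell_type,
      cluster_label = ifelse(is.na(cells$cluster_label), "",
                             cells$cluster_label),
      n_mutations_true = k,
      lambda = lambda,
      stringsAsFactors = FALSE)
  }

  # sorted naive calibration cells (blood, IgD+CD27- gate)
  naive_donors <- donors$donor_id[seq_len(min(cfg$n_naive_donors,
                                              nrow(donors)))]
  for (donor in naive_donors) {
    disease <- donors$disease_group[donors$donor_id == donor]
    n <- cfg$naive_cells_per_donor
    cell_id <- sprintf("%s_NV_%04d", donor, seq_len(n))
    k <- rpois(n, cfg$naive_lambda)
    v_idx <- sample.int(length(v_genes), n, replace = TRUE)
    j_idx <- sample.int(length(germ$j), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      .mutate_sequence(v_chars[[v_idx[i]]], k[i])
    }, character(1))
    isotype <- sample(c("IgM", "IgD"), n, replace = TRUE, prob = c(0.6, 0.4))
    chain_rows[[paste0(donor, "_naive")]] <- data.frame(
      sequence_id = paste0(cell_id, "_IGH"),
      cell_id = cell_id, locus = "IGH",
      v_call = names(germ$v)[v_idx],
      j_call = names(germ$j)[j_idx],
      c_call = paste0(.c_gene_of[isotype], "*01"),
      junction_aa = vapply(seq_len(n), function(i)
        .random_junction(cfg$junction_length_aa), character(1)),
      junction = .random_dna(n, 3 * cfg$junction_length_aa),
      sequence_alignment = seqs,
      germline_alignment = unname(germ$v[v_idx]),
      stringsAsFactors = FALSE)
    cell_rows[[paste0(donor, "_naive")]] <- data.frame(
      cell_id = cell_id, donor_id = donor, disease_group = disease,
      tissue = "blood", inflammation = "not_applicable",
      sorted_gate = "naive", compartment = "naive_memory",
      cluster_label = "", stringsAsFactors = FALSE)
    truth_rows[[paste0(donor, "_naive")]] <- data.frame(
      cell_id = cell_id, clone_id = NA_character_, cell_type = "NBC",
      cluster_label = "", n_mutations_true = k,
      lambda = cfg$naive_lambda, stringsAsFactors = FALSE)
  }

  airr <- do.call(rbind, chain_rows)
  metadata <- do.call(rbind, cell_rows)
  truth_cells <- do.call(rbind, truth_rows)
  rownames(airr) <- rownames(metadata) <- rownames(truth_cells) <- NULL

  # donor disease scores (CD donors only)
  cd <- donors$disease_group == "CD"
  prop <- resident_prop[donors$donor_id[cd]]
  ds <- cfg$disease_score
  noise_sd <- ds$sd
  if (!is.null(ds$target_rho)) {
    rho <- ds$target_rho
    noise_sd <- if (rho >= 1) 0 else if (rho <= 0 || ds$slope == 0) {
      ds$sd %||% 3
    } else ds$slope * sd(prop, na.rm = TRUE) * sqrt(1 / rho^2 - 1)
  }
  score <- ds$intercept + ds$slope * prop +
    rnorm(length(prop), 0, noise_sd)
  donors$disease_score <- NA_real_
  donors$disease_score[cd] <- pmax(0, score)

  # expression matrix + matching gene sets
  ex <- cfg$expression
  genes <- sprintf("GENE%04d", seq_len(ex$n_genes))
  set_names <- c("IFN_I", "IFN_II", "S_PHASE", "G2M", "LZ", "DZ")
  shuffled <- sample(genes)
  gene_sets <- setNames(lapply(seq_along(set_names), function(i) {
    shuffled[seq_len(ex$set_size) + (i - 1) * ex$set_size]
  }), set_names)
  n_expr <- min(ex$n_cells, nrow(metadata))
  expr_cells <- sort(sample(metadata$cell_id, n_expr))
  mu <- rnorm(ex$n_genes, 1, 0.5)
  expr <- matrix(rnorm(n_expr * ex$n_genes, 0, ex$base_sd),
                 nrow = n_expr, ncol = ex$n_genes,
                 dimnames = list(expr_cells, genes))
  expr <- sweep(expr, 2, mu, `+`)
  inflamed_cells <- metadata$cell_id[metadata$inflammation == "inflamed"]
  hot <- rownames(expr) %in% inflamed_cells
  ifn <- c(gene_sets$IFN_I, gene_sets$IFN_II)
  expr[hot, ifn] <- expr[hot, ifn] + ex$ifn_shift

  structure(list(airr = airr,
                 metadata = metadata,
                 donors = donors,
                 germline = germ,
                 expression = expr,
                 gene_sets = gene_sets,
                 truth = list(cells = truth_cells,
                              donors = cbind(donors,
                                             resident_prop =
                                               unname(resident_prop)),
                              config = cfg)),
            class = "bcr_cohort")
}

#' @export
print.bcr_cohort <- function(x, ...) {
  cat("Synthetic BCR cohort:", nrow(x$metadata), "cells,",
      nrow(x$airr), "chains,", nrow(x$donors), "donors (",
      sum(x$donors$disease_group == "CD"), "CD /",
      sum(x$donors$disease_group == "nonIBD"), "nonIBD )\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `airr.tsv`, `metadata.tsv`, `donors.tsv`, `germline.fasta`,
#' `expr.tsv`, `signatures.gmt`, `truth_cells.tsv` under `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bcr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_airr(cohort$airr, file.path(dir, "airr.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$donors, file.path(dir, "donors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write_germline_fasta(c(cohort$germline$v, cohort$germline$j),
                       file.path(dir, "germline.fasta"))
  expr <- data.frame(cell_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sets(cohort$gene_sets, file.path(dir, "signatures.gmt"))
  utils::write.table(cohort$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Donor-level association sub-generator
#'
#' Draws per-donor resident-like MBC proportions (Beta distributed) and
#' disease scores whose model correlation with the proportions equals `rho`
#' (noise variance calibrated against the Beta's theoretical spread;
#' `rho = 0` gives the association null). Used for correlation-calibration
#' studies where simulating full repertoires per replicate is unnecessary.
#'
#' @param n_donors number of donors.
#' @param rho designed Pearson correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @param beta_shape Beta(a, b) shape pair for proportions.
#' @param score_mean,score_sd location/scale of the disease score.
#' @return data.frame: `donor_id`, `proportion`, `disease_score`.
#' @export
simulate_donor_association <- function(n_donors, rho, seed = 1,
                                       beta_shape = c(5, 5),
                                       score_mean = 12, score_sd = 5) {
  stopifnot(rho >= 0, rho < 1)
  with_seed(seed, {
    a <- beta_shape[1]; b <- beta_shape[2]
    p <- rbeta(n_donors, a, b)
    mu <- a / (a + b)
    sdp <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    z <- rnorm(n_donors)
    s <- score_mean + score_sd * (rho * (p - mu) / sdp +
                                    sqrt(1 - rho^2) * z)
    data.frame(donor_id = sprintf("D%03d", seq_len(n_donors)),
               proportion = p, disease_score = s,
               stringsAsFactors = FALSE)
  })
}
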