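make_clono_cells <- function() {
  data.frame(
    cell_id = sprintf("c%d", 1:6),
    donor_id = c("d1", "d1", "d2", "d1", "d1", "d1"),
    v_call = c("IGHV3-23*01", "IGHV3-23*04", "IGHV3-23*01", "IGHV1-2*01",
               "IGHV3-23*01", "IGHV3-23*01"),
    j_call = "IGHJ4*01",
    junction_aa = c("CARDYW", "CARDYW", "CARDYW", "CARDYW", "CARDYF", ""),
    stringsAsFactors = FALSE)
}

test_that("clonotypes group by donor, gene-level V/J and exact junction", {
  res <- assign_clonotypes(make_clono_cells())
  # c1 and c2 share a clonotype (allele variants pool under IGHV3-23)
  ids <- setNames(res$cells$clonotype_id, res$cells$cell_id)
  expect_identical(ids[["c1"]], ids[["c2"]])
  # same rearrangement in another donor is a different clonotype
  expect_false(ids[["c3"]] == ids[["c1"]])
  # one junction residue apart: distinct clonotypes under exact match
  expect_false(ids[["c5"]] == ids[["c1"]])
  # missing junction excluded with a reason
  expect_equal(res$excluded$cell_id, "c6")
  expect_false("c6" %in% res$cells$cell_id)
})

test_that("clonotype sizes partition each donor's cells and ids are order-invariant", {
  set.seed(21)
  cells <- simulate_cohort(small_scenario(seed = 4))$airr
  meta <- simulate_cohort(small_scenario(seed = 4))$metadata
  tab <- build_cell_table(cells, meta)
  tab <- tab[!is.na(tab$junction_aa) & tab$junction_aa != "", ]
  res <- assign_clonotypes(tab)
  for (d in unique(res$clonotypes$donor_id)) {
    expect_equal(sum(res$clonotypes$size[res$clonotypes$donor_id == d]),
                 sum(res$cells$donor_id == d))
  }
  perm <- assign_clonotypes(tab[sample(nrow(tab)), ])
  a <- res$cells[order(res$cells$cell_id), c("cell_id", "clonotype_id")]
  b <- perm$cells[order(perm$cells$cell_id), c("cell_id", "clonotype_id")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("expanded fraction counts cells in clones of two or more", {
  sizes <- c(3, 2, 1, 1, 1)
  ids <- rep(sprintf("cl%d", seq_along(sizes)), sizes)
  expect_equal(expanded_fraction(ids), 5 / 8)
  expect_equal(expanded_fraction(sprintf("cl%d", 1:4)), 0)
  expect_equal(expanded_fraction(rep("cl1", 9)), 1)
  expect_true(is.na(expanded_fraction(character(0))))
  # appending a singleton never increases the expanded-cell count
  expect_lte(expanded_fraction(c(ids, "new_singleton")) * 9,
             expanded_fraction(ids) * 8 + 1e-12)
})

test_that("Shannon entropy matches closed forms and brute-force recomputation", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(4), 0)
  expect_equal(shannon_entropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(1, 0)), "positive")
  expect_error(shannon_entropy(numeric(0)), "nonempty")
  set.seed(9)
  for (i in 1:50) {
    sizes <- sample(1:40, sample(1:15, 1), replace = TRUE)
    h <- shannon_entropy(sizes)
    expect_equal(h, entropy_oracle(sizes), tolerance = 1e-12)
    expect_gte(h, 0)
    expect_lte(h, log(length(sizes)) + 1e-12)
    # merging two clones never increases entropy
    if (length(sizes) >= 2) {
      merged <- c(sizes[1] + sizes[2], sizes[-(1:2)])
      expect_lte(shannon_entropy(merged), h + 1e-12)
    }
  }
})

test_that("rarefied entropy degenerates correctly and matches a high-rep oracle", {
  ids <- rep(sprintf("cl%d", 1:10), times = 1:10)
  full <- rarefied_entropy(ids, depth = length(ids), n_resamples = 5,
                           seed = 2)
  expect_equal(full$mean, shannon_entropy(1:10))
  expect_equal(full$sd, 0)

  expect_equal(rarefied_entropy(rep("cl1", 30), depth = 10)$mean, 0)
  expect_error(rarefied_entropy(ids, depth = 1000), "depth")

  # uniform 50 clones (3 cells each), depth 25: mean strictly below log(50)
  # and within the Monte-Carlo band of an independent high-rep simulation
  uni <- rep(sprintf("cl%d", 1:50), each = 3)
  got <- rarefied_entropy(uni, depth = 25, n_resamples = 200, seed = 3)
  expect_lt(got$mean, log(50))
  set.seed(99)
  oracle <- replicate(10000, {
    tab <- table(sample(uni, 25))
    entropy_oracle(as.numeric(tab))
  })
  tol <- 4 * sd(oracle) * sqrt(1 / 200 + 1 / 10000)
  expect_lt(abs(got$mean - mean(oracle)), tol)
})

test_that("rarefied entropy is bit-reproducible for a fixed seed", {
  ids <- rep(sprintf("cl%d", 1:20), times = rpois(20, 3) + 1)
  a <- rarefied_entropy(ids, depth = 15, n_resamples = 50, seed = 123)
  b <- rarefied_entropy(ids, depth = 15, n_resamples = 50, seed = 123)
  expect_identical(a, b)
})

test_that("V-gene usage pools alleles and sums to one per group", {
  cells <- data.frame(
    grp = "all",
    v_call = c("IGHV3-23*01", "IGHV3-23*04", "IGHV1-2*02", "IGHV4-34*01"),
    stringsAsFactors = FALSE)
  u <- vgene_usage(cells, "grp")
  expect_equal(u$frequency[u$v_gene == "IGHV3-23"], 0.5)
  expect_equal(sum(u$frequency), 1)
  expect_false(any(grepl("\\*", u$v_gene)))
})

test_that("usage boost of IGHV3-23 in CD MBCs is recovered from the generator", {
  cfg <- cohort_config(
    n_donors = c(CD = 2, nonIBD = 2),
    cells_per_sample = 170,
    cell_type_probs = list(
      blood = c(NBC = 0, MBC = 1, GCBC = 0, PC = 0),
      colon = c(NBC = 0, MBC = 1, GCBC = 0, PC = 0),
      TI = c(NBC = 0, MBC = 1, GCBC = 0, PC = 0)),
    naive_cells_per_donor = 50, n_naive_donors = 1,
    vgene_boost = list(gene = "IGHV3-23", factor = 3, cell_type = "MBC",
                       disease_group = "CD"),
    seed = 31)
  coh <- simulate_cohort(cfg)
  tab <- build_cell_table(coh$airr, coh$metadata)
  tab <- tab[tab$sorted_gate == "antigen_experienced", ]
  u <- vgene_usage(tab, "disease_group")
  f_cd <- u$frequency[u$disease_group == "CD" & u$v_gene == "IGHV3-23"]
  f_n <- u$frequency[u$disease_group == "nonIBD" & u$v_gene == "IGHV3-23"]
  # design: weight 3 vs 1 over 30 genes -> 3/32 vs 1/30 at the clone level
  n_cd <- unique(u$n_cells[u$disease_group == "CD"])
  se <- sqrt(0.094 * (1 - 0.094) / n_cd) * 3  # clone clustering inflates this
  expect_gt(f_cd, f_n)
  expect_lt(abs(f_cd - 3 / 32), 3 * se)
})

test_that("clonal stats combine counts, expansion and entropy per compartment", {
  ids <- c(rep("a", 3), rep("b", 2), "c")
  cells <- data.frame(grp = rep(c("g1", "g2"), c(6, 2)),
                      clonotype_id = c(ids, "x", "y"),
                      stringsAsFactors = FALSE)
  st <- clonal_stats(cells, "grp")
  g1 <- st[st$grp == "g1", ]
  expect_equal(g1$n_cells, 6)
  expect_equal(g1$n_clonotypes, 3)
  expect_equal(g1$expanded_fraction, 5 / 6)
  expect_equal(g1$shannon_entropy, entropy_oracle(c(3, 2, 1)))
  st2 <- clonal_stats(cells, "grp", rarefy_depth = "auto", seed = 5)
  expect_equal(unique(st2$entropy_depth), 2L)
})

test_that("junction nucleotide-identity clustering merges near-identical clones", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:4),
    donor_id = "d1",
    v_call = "IGHV3-23*01",
    j_call = "IGHJ4*01",
    junction_aa = c("CARDYW", "CARDYW", "CARDFW", "CARDYW"),
    junction = c("TGTGCTAGAGATTAC",   # reference
                 "TGTGCTAGAGATTAC",   # identical
                 "TGTGCTAGAGATTAT",   # 1 nt apart (14/15 = 0.933)
                 "AGAACTTGTCCGGAT"),  # far away
    stringsAsFactors = FALSE)
  strict <- assign_clonotypes(cells)
  ids_s <- setNames(strict$cells$clonotype_id, strict$cells$cell_id)
  expect_false(ids_s[["c3"]] == ids_s[["c1"]])   # exact-aa rule splits

  relaxed <- assign_clonotypes(cells, junction_nt_identity = 0.9)
  ids_r <- setNames(relaxed$cells$clonotype_id, relaxed$cells$cell_id)
  expect_identical(ids_r[["c1"]], ids_r[["c2"]])
  expect_identical(ids_r[["c1"]], ids_r[["c3"]])
  expect_false(ids_r[["c4"]] == ids_r[["c1"]])
  for (d in unique(relaxed$clonotypes$donor_id)) {
    expect_equal(sum(relaxed$clonotypes$size), nrow(relaxed$cells))
  }
})

test_that("donor-wide expansion scope counts cross-compartment clone mates", {
  # the clone spans two compartments with one cell in each: a singleton
  # under compartment-restricted sizes, expanded donor-wide
  cells <- data.frame(
    grp = c("A", "B", "B"),
    clonotype_id = c("cl1", "cl1", "cl2"),
    stringsAsFactors = FALSE)
  comp <- clonal_stats(cells, "grp")
  expect_equal(comp$expanded_fraction[comp$grp == "A"], 0)
  wide <- clonal_stats(cells, "grp", expansion_scope = "donor_wide")
  expect_equal(wide$expanded_fraction[wide$grp == "A"], 1)
  expect_equal(wide$expanded_fraction[wide$grp == "B"], 0.5)
})
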