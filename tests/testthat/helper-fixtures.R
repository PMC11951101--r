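# Shared fixtures: all inputs are generated in code.

# Down-scaled cohort used by most integration tests.
small_scenario <- function(seed = 1, ...) {
  cohort_config(
    n_donors = c(CD = 2, nonIBD = 2),
    cells_per_sample = 60,
    naive_cells_per_donor = 40,
    n_naive_donors = 2,
    expression = list(n_genes = 120, n_cells = 200, set_size = 10,
                      ifn_shift = 1, base_sd = 0.4),
    seed = seed,
    ...)
}

# Minimal valid chain table.
make_airr <- function(n = 3, germ = "ATGCATGCATGC") {
  m <- max(n, 1)
  df <- data.frame(
    sequence_id = sprintf("seq%02d", seq_len(m)),
    cell_id = sprintf("cell%02d", seq_len(m)),
    locus = "IGH",
    v_call = "IGHV3-23*01",
    j_call = "IGHJ4*01",
    c_call = "IGHG1*01",
    junction_aa = "CARDYW",
    junction = "TGTGCTAGA",
    sequence_alignment = germ,
    germline_alignment = germ,
    stringsAsFactors = FALSE)
  df[seq_len(n), , drop = FALSE]
}

# Independent per-position mutation comparator (different implementation
# from the package's counter: works on split characters).
brute_force_mutations <- function(obs, germ) {
  o <- strsplit(toupper(obs), "")[[1]]
  g <- strsplit(toupper(germ), "")[[1]]
  bases <- c("A", "C", "G", "T")
  n_mut <- 0L; comp <- 0L
  for (i in seq_along(o)) {
    if (o[i] %in% bases && g[i] %in% bases) {
      comp <- comp + 1L
      if (o[i] != g[i]) n_mut <- n_mut + 1L
    }
  }
  c(n_mutations = n_mut, comparable_length = comp)
}

# Random alignment pair over the full alphabet incl. N and gap symbols.
random_alignment_pair <- function(len = 60) {
  alpha <- c("A", "C", "G", "T", "N", ".", "-")
  probs <- c(0.2, 0.2, 0.2, 0.2, 0.08, 0.06, 0.06)
  list(obs = paste(sample(alpha, len, TRUE, probs), collapse = ""),
       germ = paste(sample(alpha, len, TRUE, probs), collapse = ""))
}

# Independent Shannon entropy (direct formula, no shared code).
entropy_oracle <- function(sizes) {
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}
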