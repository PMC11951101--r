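`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip the allele suffix from a V/J/C gene call
#'
#' Immunogenetics callers report alleles as `GENE*allele` (e.g. `IGHV3-23*01`)
#' and may list several comma-separated candidate calls. Gene-level grouping
#' (clonotyping, V-gene usage) uses the first call with the `*allele` suffix
#' removed; the raw call is always preserved in the input table.
#'
#' @param call character vector of gene calls.
#' @return character vector of allele-stripped gene names.
#' @examples
#' strip_allele(c("IGHV3-23*01", "IGHV1-2*02,IGHV1-2*04"))
#' @export
strip_allele <- function(call) {
  first <- sub("[, ].*$", "", call)
  sub("\\*.*$", "", first)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps seeded operations (signature
# scoring, rarefaction, simulation) from perturbing user code.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if
      (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Interaction key for grouping columns; deterministic, no factor surprises.
group_key <- function(df, cols) {
  stopifnot(all(cols %in% names(df)))
  do.call(paste, c(unname(df[cols]), sep = "|"))
}
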