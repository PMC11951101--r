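# GMT gene sets, germline FASTA, cell metadata and expression matrices.

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are collapsed; gene symbols are matched case-sensitively
#' throughout the package (no alias resolution).
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (one per gene set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT format error at line ", i,
           ": expected name, description and at least one gene")
    }
    nms[i] <- fields[1]
    out[[i]] <- unique(fields[-(1:2)])
  }
  setNames(out, nms)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output file path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a germline segment reference from FASTA
#'
#' @param path path to a FASTA file of germline V/J segments (IMGT-style
#'   record names, e.g. `IGHV3-23*01`).
#' @return named character vector of uppercase nucleotide sequences.
#' @export
read_germline_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write a germline segment reference to FASTA
#'
#' @param segments named character vector of nucleotide sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(segments, path) {
  stopifnot(!is.null(names(segments)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(segments), path)
  invisible(path)
}

#' Read per-cell metadata
#'
#' @param path tab-separated table with a `cell_id` column.
#' @return data.frame of character columns.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                          na.strings = NULL, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"cell_id" %in% names(df)) {
    stop("metadata format error: missing mandatory column cell_id")
  }
  df
}

#' Read a log-normalized cells-by-genes expression matrix
#'
#' Two on-disk layouts are supported: a dense labelled TSV (rows = cells,
#' columns = genes, first column holding cell ids) and a MatrixMarket triplet
#' (`.mtx`, rows = genes, columns = cells, 10x convention) accompanied by
#' one-symbol-per-line gene and cell label files.
#'
#' @param path path to the `.tsv`/`.txt` or `.mtx` file.
#' @param cells optional character vector of cell ids to restrict to. Cells
#'   absent from the matrix are reported in the `"missing_cells"` attribute;
#'   an empty intersection is an error.
#' @param genes_path,cells_path label files, required for MTX input.
#' @return dense numeric matrix, cells in rows, genes in columns.
#' @export
read_expression <- function(path, cells = NULL, genes_path = NULL,
                            cells_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("MTX input requires genes_path and cells_path label files")
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path, warn = FALSE)
    cell_ids <- readLines(cells_path, warn = FALSE)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      stop("MTX dimensions do not match label files (genes x cells expected)")
    }
    dimnames(m) <- list(gene_ids, cell_ids)
    m <- t(m)
  } else {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                            row.names = 1, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  missing_cells <- character(0)
  if (!is.null(cells)) {
    keep <- intersect(cells, rownames(m))
    missing_cells <- setdiff(cells, rownames(m))
    if (length(keep) == 0) {
      stop("empty intersection between requested cells and expression matrix")
    }
    if (length(missing_cells) > 0) {
      warning(length(missing_cells),
              " requested cell(s) absent from expression matrix")
    }
    m <- m[keep, , drop = FALSE]
  }
  attr(m, "missing_cells") <- missing_cells
  m
}
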