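# AIRR Rearrangement TSV input/output.
#
# One row per immunoglobulin chain, AIRR-community column names. The missing
# value dialect is the empty string (never "NA"): AIRR TSV is exchanged with
# non-R tools that do not understand R's NA token.

.airr_required <- c(
  "sequence_id", "v_call", "j_call", "junction_aa",
  "sequence_alignment", "germline_alignment"
)

# Canonical column order on write; extra columns follow alphabetically.
.airr_order <- c(
  "sequence_id", "cell_id", "locus", "v_call", "j_call", "c_call",
  "junction", "junction_aa", "sequence_alignment", "germline_alignment",
  "consensus_count"
)

.alignment_alphabet <- "^[ACGTNacgtn.\\-]*$"

#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated rearrangement table (one row per chain) and validates
#' each row against the chain-record invariants: equal-length
#' `sequence_alignment` / `germline_alignment`, alignment alphabet restricted
#' to `A C G T N . -`, and a non-empty `v_call`. Rows with an alignment-length
#' mismatch abort with an error naming the offending `sequence_id`; rows
#' violating the other invariants are removed and reported in the
#' `"rejected"` attribute (a data frame of `sequence_id` and `reason`), never
#' silently dropped.
#'
#' @param path path to a tab-separated AIRR Rearrangement file.
#' @return `data.frame` of validated chain records (all columns character
#'   except `consensus_count`, which is converted to numeric when present),
#'   with attribute `"rejected"` describing removed rows.
#' @seealso [write_airr()]
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) stop("AIRR file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", na.strings = NULL,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.airr_required, names(df))
  if (length(missing) > 0) {
    stop("AIRR format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if ("consensus_count" %in% names(df)) {
    df$consensus_count <- suppressWarnings(as.numeric(df$consensus_count))
  }
  validate_airr(df)
}

#' Validate chain records
#'
#' Applies the chain-record invariants to an in-memory rearrangement table.
#' See [read_airr()] for the rules and the error/rejection contract.
#'
#' @param df data.frame with at least the mandatory AIRR columns.
#' @return validated data.frame with attribute `"rejected"`.
#' @export
validate_airr <- function(df) {
  missing <- setdiff(.airr_required, names(df))
  if (length(missing) > 0) {
    stop("AIRR format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  len_mismatch <- nchar(df$sequence_alignment) != nchar(df$germline_alignment)
  if (any(len_mismatch)) {
    stop("AIRR validation error: sequence_alignment and germline_alignment ",
         "lengths differ for sequence_id: ",
         paste(df$sequence_id[len_mismatch], collapse = ", "))
  }
  bad_alpha <- !grepl(.alignment_alphabet, df$sequence_alignment) |
    !grepl(.alignment_alphabet, df$germline_alignment)
  bad_vcall <- is.na(df$v_call) | df$v_call == ""
  reasons <- character(nrow(df))
  reasons[bad_vcall] <- "empty v_call"
  reasons[bad_alpha] <- "alignment contains symbols outside {A,C,G,T,N,.,-}"
  drop <- bad_alpha | bad_vcall
  rejected <- data.frame(sequence_id = df$sequence_id[drop],
                         reason = reasons[drop],
                         stringsAsFactors = FALSE)
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " chain record(s) rejected during AIRR validation;",
            " see attr(, 'rejected')")
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write an AIRR Rearrangement TSV
#'
#' Writes chain records as a tab-separated table with AIRR column names in a
#' deterministic order (canonical AIRR columns first, any extras
#' alphabetically). Missing values are written as empty fields, never `"NA"`.
#'
#' @param records data.frame of chain records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_airr()]
#' @export
write_airr <- function(records, path) {
  stopifnot(is.data.frame(records))
  known <- intersect(.airr_order, names(records))
  extra <- sort(setdiff(names(records), .airr_order))
  records <- records[, c(known, extra), drop = FALSE]
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing AIRR file '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
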