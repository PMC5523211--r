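#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd rbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

# Character sets. Everything outside the four unambiguous bases is treated as
# missing for all downstream computation: gaps and '?'/'N' mark unsequenced
# positions, and IUPAC ambiguity codes are too weak to support a distance or a
# fixation claim.
BASES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("-", "N", "?", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
ALLOWED_CHARS <- c(BASES, MISSING_CHARS)

is_missing_char <- function(x) x %in% MISSING_CHARS

#' Read an aligned FASTA file
#'
#' Reads a (sequential or line-wrapped) FASTA file holding a multiple sequence
#' alignment and validates it: all rows must have equal length, headers must be
#' unique, and characters must be DNA bases, gaps, `N`/`?`, or IUPAC ambiguity
#' codes. Input is case-folded to upper case and `U` is mapped to `T`, so
#' RNA-style records from public databases are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A character matrix (rows = sequences, columns = alignment sites)
#'   with row names set to the FASTA ids (first whitespace-delimited token of
#'   each header).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC-T"), f)
#' read_fasta_alignment(f)
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">")) {
    stop("not a FASTA file (no '>' header at top): ", path)
  }
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids)) stop("FASTA record with no sequence lines")
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[[1L]])[[1L]]
    stop("alignment rows differ in length: '", ids[[bad]], "' has ",
         lens[[bad]], " sites, '", ids[[1L]], "' has ", lens[[1L]])
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- which(!(mat %in% ALLOWED_CHARS))
  if (length(bad)) {
    i <- ((bad[[1L]] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[[1L]] - 1L) %/% nrow(mat)) + 1L
    stop("illegal character '", mat[[bad[[1L]]]], "' in record '", ids[[i]],
         "' at site ", j)
  }
  if (any(rowSums(matrix(!(mat %in% MISSING_CHARS), nrow = nrow(mat))) == 0L)) {
    stop("alignment row(s) with no determined base")
  }
  mat
}

#' Write an alignment to FASTA
#'
#' @param mat Character matrix with row names, as returned by
#'   [read_fasta_alignment()], or a `labeled_alignment`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(mat, path, width = 70) {
  if (inherits(mat, "labeled_alignment")) mat <- mat$matrix
  out <- character(0)
  for (i in seq_len(nrow(mat))) {
    s <- paste(mat[i, ], collapse = "")
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    out <- c(out, paste0(">", rownames(mat)[[i]]), chunks)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a tab-separated table with a header row. Required columns are
#' `seq_id`, `species` and `role` (`ingroup` or `outgroup`); optional columns
#' `accession`, `sex` and `locality` are carried along, any other column is
#' ignored with a message.
#'
#' @param path Path to a TSV file.
#' @return A data frame of specimen records, one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("seq_id", "species", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata is missing required column(s): ",
                         paste(miss, collapse = ", "))
  optional <- c("accession", "sex", "locality")
  extra <- setdiff(names(df), c(req, optional))
  if (length(extra)) {
    message("ignoring metadata column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  df$seq_id <- as.character(df$seq_id)
  df$species <- as.character(df$species)
  df$role <- as.character(df$role)
  if (anyDuplicated(df$seq_id)) {
    stop("duplicate seq_id(s) in metadata: ",
         paste(unique(df$seq_id[duplicated(df$seq_id)]), collapse = ", "))
  }
  if (any(!nzchar(df$species) | is.na(df$species))) {
    stop("empty species label for seq_id(s): ",
         paste(df$seq_id[!nzchar(df$species) | is.na(df$species)],
               collapse = ", "))
  }
  bad_role <- setdiff(unique(df$role), c("ingroup", "outgroup"))
  if (length(bad_role)) {
    stop("invalid role value(s): ", paste(bad_role, collapse = ", "),
         " (allowed: ingroup, outgroup)")
  }
  if ("sex" %in% names(df)) {
    bad_sex <- setdiff(unique(df$sex[!is.na(df$sex) & nzchar(df$sex)]),
                       c("male", "female", "unknown"))
    if (length(bad_sex)) {
      stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
           " (allowed: male, female, unknown)")
    }
  }
  df[] <- lapply(df, as.character)
  df
}

#' Write a specimen metadata table
#' @param records Data frame of specimen records.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bind an alignment to its specimen metadata
#'
#' Joins an alignment matrix to the specimen records by sequence id, producing
#' the labeled alignment every downstream analysis consumes. In `strict` mode
#' the two id sets must match exactly; in `lenient` mode the intersection is
#' kept and dropped ids are reported in a warning. The output row order follows
#' the metadata order.
#'
#' @param mat Character matrix from [read_fasta_alignment()].
#' @param records Data frame from [read_metadata()].
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return An object of class `labeled_alignment`: a list with elements
#'   `matrix` (character matrix, rows named by seq_id) and `records`
#'   (data frame, same order as the matrix rows).
#' @export
bind_alignment <- function(mat, records, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  fasta_ids <- rownames(mat)
  meta_ids <- records$seq_id
  only_fasta <- setdiff(fasta_ids, meta_ids)
  only_meta <- setdiff(meta_ids, fasta_ids)
  if (mode == "strict" && (length(only_fasta) || length(only_meta))) {
    stop("id mismatch between alignment and metadata; only in FASTA: [",
         paste(only_fasta, collapse = ", "), "]; only in metadata: [",
         paste(only_meta, collapse = ", "), "]")
  }
  keep <- intersect(meta_ids, fasta_ids)
  if (mode == "lenient" && (length(only_fasta) || length(only_meta))) {
    warning("dropped unmatched id(s): ",
            paste(c(only_fasta, only_meta), collapse = ", "))
  }
  if (length(keep) == 0L) stop("no ids shared between alignment and metadata")
  records <- records[match(keep, records$seq_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(matrix = mat[keep, , drop = FALSE], records = records),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labeled alignment: ", nrow(x$matrix), " sequences x ",
      ncol(x$matrix), " sites\n", sep = "")
  tab <- table(x$records$species)
  cat(length(tab), " species (", sum(x$records$role == "ingroup"),
      " ingroup, ", sum(x$records$role == "outgroup"),
      " outgroup sequences)\n", sep = "")
  invisible(x)
}

# integer encoding used by the distance/diagnostic engines:
# A,C,G,T -> 1..4, everything missing -> NA
encode_alignment <- function(aln) {
  mat <- if (inherits(aln, "labeled_alignment")) aln$matrix else aln
  code <- match(mat, BASES)
  matrix(code, nrow = nrow(mat), dimnames = dimnames(mat))
}
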