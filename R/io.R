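#' @importFrom utils read.delim write.table combn head
NULL

COUNT_COLUMNS <- c("individual_id", "primer_combo", "dna_type", "replicate",
                   "variant_id", "sequence", "read_count")
PRIMER_COMBOS <- c("PC1", "PC2", "PC3")
DNA_TYPES <- c("gDNA", "cDNA")

group_key <- function(tab) {
  paste(tab$individual_id, tab$primer_combo, tab$dna_type, tab$replicate,
        sep = "\r")
}

#' Validate an amplicon count table
#'
#' Checks the long-form read-count table invariants: column set, enum
#' values, non-negative integer counts, the bijection between `variant_id`
#' and `sequence`, no duplicated (group, variant) rows, and positive totals
#' for every sequenced group.
#'
#' @param tab A data frame with columns `individual_id`, `primer_combo`,
#'   `dna_type`, `replicate`, `variant_id`, `sequence`, `read_count`.
#' @param lines Optional integer vector mapping rows to source-file line
#'   numbers (used to phrase parse errors when reading from disk).
#' @return The validated table, classed `amplicon_counts`, invisibly
#'   usable as a plain data frame.
#' @export
as_amplicon_counts <- function(tab, lines = NULL) {
  missing_cols <- setdiff(COUNT_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stop("count table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- as.data.frame(tab)[, COUNT_COLUMNS]
  if (is.null(lines)) lines <- seq_len(nrow(tab))
  where <- function(i) paste0("line ", lines[i][1])

  bad <- which(!tab$primer_combo %in% PRIMER_COMBOS)
  if (length(bad) > 0)
    stop("invalid primer_combo at ", where(bad), call. = FALSE)
  bad <- which(!tab$dna_type %in% DNA_TYPES)
  if (length(bad) > 0)
    stop("invalid dna_type at ", where(bad), call. = FALSE)

  rep_num <- suppressWarnings(as.integer(tab$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1)
  if (length(bad) > 0)
    stop("replicate must be an integer >= 1 at ", where(bad), call. = FALSE)
  tab$replicate <- rep_num

  counts <- suppressWarnings(as.numeric(tab$read_count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad) > 0)
    stop("read_count must be a non-negative integer at ", where(bad),
         call. = FALSE)
  tab$read_count <- as.integer(counts)

  tab$sequence <- toupper(tab$sequence)
  bad <- which(!grepl("^[ACGT]+$", tab$sequence))
  if (length(bad) > 0)
    stop("sequence must be a non-empty A/C/G/T string at ", where(bad),
         call. = FALSE)
  bad <- which(is.na(tab$variant_id) | !nzchar(tab$variant_id))
  if (length(bad) > 0)
    stop("empty variant_id at ", where(bad), call. = FALSE)

  map <- unique(tab[, c("variant_id", "sequence")])
  if (anyDuplicated(map$variant_id))
    stop("integrity error: variant_id mapped to more than one sequence: ",
         paste(unique(map$variant_id[duplicated(map$variant_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(map$sequence))
    stop("integrity error: the same sequence carries more than one variant_id",
         call. = FALSE)

  dup <- duplicated(paste(group_key(tab), tab$variant_id, sep = "\r"))
  if (any(dup))
    stop("duplicate (group, variant) row at ", where(which(dup)), call. = FALSE)

  totals <- tapply(tab$read_count, group_key(tab), sum)
  if (any(totals <= 0))
    stop("group with zero total read count: ",
         gsub("\r", "/", names(totals)[totals <= 0][1]), call. = FALSE)

  rownames(tab) <- NULL
  class(tab) <- c("amplicon_counts", "data.frame")
  tab
}

#' Read an amplicon count table from TSV
#'
#' @param path Path to a tab-separated file with a header row naming the
#'   seven count-table fields.
#' @return A validated `amplicon_counts` data frame.
#' @seealso [write_count_table()], [as_amplicon_counts()]
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  as_amplicon_counts(tab, lines = seq_len(nrow(tab)) + 1L)
}

#' Write an amplicon count table to TSV
#'
#' @param tab An `amplicon_counts` table (or a data frame with the same
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(tab, path) {
  tab <- as_amplicon_counts(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named vector of uppercase sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (names are record ids).  Lowercase bases
#'   are uppercased; duplicate or empty ids are an error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must have a non-empty id", call. = FALSE)
  if (anyDuplicated(names(records)))
    stop("duplicate record id(s)", call. = FALSE)
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Number of records spanned by a GenBank accession range
#'
#' Accession ranges such as `MN686116-MN686203` are inclusive; the span is
#' the difference of the numeric suffixes plus one.
#'
#' @param first,last Accession strings sharing an alphabetic prefix.
#' @return Integer count of accessions in the inclusive range.
#' @export
#' @examples
#' genbank_span("MN686116", "MN686203")  # 88
genbank_span <- function(first, last) {
  parse1 <- function(x) {
    m <- regmatches(x, regexec("^([A-Za-z_]+)(\\d+)$", x))[[1]]
    if (length(m) != 3) stop("not an accession: ", x, call. = FALSE)
    list(prefix = m[2], num = as.numeric(m[3]))
  }
  a <- parse1(first); b <- parse1(last)
  if (a$prefix != b$prefix)
    stop("accessions have different prefixes", call. = FALSE)
  if (b$num < a$num) stop("range is reversed", call. = FALSE)
  as.integer(b$num - a$num + 1)
}
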