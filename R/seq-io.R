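#' Construct a taxonomically labeled sequence database
#'
#' @param sequences named character vector of protein sequences, or an
#'   `AAStringSet`.
#' @param domain character vector of domain-of-life labels (recycled if
#'   length 1), one of Eukaryota, Bacteria, Archaea, Virus, Unknown.
#' @param category character vector of category labels (e.g. focal,
#'   familyA, familyB, background), recycled if length 1.
#' @param sourceIds optional named list of merged source ids.
#' @return a [TaxSeqDB-class].
#' @export
taxSeqDB <- function(sequences, domain, category, sourceIds = NULL) {
  if (!methods::is(sequences, "AAStringSet")) {
    checkResidues(unname(sequences), "database sequence")
    sequences <- Biostrings::AAStringSet(sequences)
  }
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  n <- length(sequences)
  domain <- rep_len(domain, n)
  category <- rep_len(category, n)
  if (is.null(sourceIds))
    sourceIds <- stats::setNames(as.list(ids), ids)
  tx <- data.frame(id = ids, domain_of_life = domain, category = category,
                   stringsAsFactors = FALSE)
  new("TaxSeqDB", sequences = sequences, taxonomy = tx,
      sourceIds = sourceIds)
}

#' @describeIn taxSeqDB ids of all records.
#' @param db a [TaxSeqDB-class].
#' @export
seqIds <- function(db) names(db@sequences)

#' @describeIn taxSeqDB sequences as a named character vector.
#' @export
dbSequences <- function(db) {
  stats::setNames(as.character(db@sequences), names(db@sequences))
}

#' @describeIn taxSeqDB the taxonomy table (id, domain_of_life, category).
#' @export
taxonomyTable <- function(db) db@taxonomy

#' Read a sequence database from FASTA plus a taxonomy TSV
#'
#' The taxonomy file must have columns `id`, `domain_of_life` and
#' `category` and cover every FASTA record.
#'
#' @param fastaPath protein FASTA file.
#' @param taxonomyPath tab-separated taxonomy table.
#' @return a [TaxSeqDB-class].
#' @export
readTaxSeqDB <- function(fastaPath, taxonomyPath) {
  if (!file.exists(fastaPath)) stop("FASTA file not found: ", fastaPath)
  if (!file.exists(taxonomyPath))
    stop("taxonomy file not found: ", taxonomyPath)
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tx <- utils::read.delim(taxonomyPath, stringsAsFactors = FALSE)
  m <- match(names(seqs), tx$id)
  if (anyNA(m)) stop("taxonomy table does not cover all FASTA records")
  taxSeqDB(seqs, tx$domain_of_life[m], tx$category[m])
}

#' Write a sequence database as FASTA plus a taxonomy TSV
#'
#' @param db a [TaxSeqDB-class].
#' @param fastaPath,taxonomyPath output paths.
#' @return invisibly, the two paths.
#' @export
writeTaxSeqDB <- function(db, fastaPath, taxonomyPath) {
  Biostrings::writeXStringSet(db@sequences, fastaPath, width = 60L)
  utils::write.table(db@taxonomy, taxonomyPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(fastaPath, taxonomyPath))
}

#' Read / write aligned FASTA (A2M, `-` for gaps)
#'
#' @param path file path.
#' @return a [SeqAlignment-class].
#' @export
readAlignmentFasta <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  rows <- toupper(stats::setNames(as.character(ss), names(ss)))
  rows <- gsub("\\.", "-", rows)
  new("SeqAlignment", rows = rows)
}

#' @rdname readAlignmentFasta
#' @param alignment a [SeqAlignment-class].
#' @export
writeAlignmentFasta <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(alignment@rows), path, width = 60L)
  invisible(path)
}

#' Read a Stockholm-format alignment
#'
#' Minimal single-block reader for seed alignments: `#=` annotation lines
#' are ignored, `.` gaps become `-`, and sequences split across blocks are
#' concatenated.
#'
#' @param path Stockholm file.
#' @return a [SeqAlignment-class].
#' @export
readStockholm <- function(path) {
  if (!file.exists(path)) stop("Stockholm file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "#") || startsWith(ln, "//") || !nzchar(trimws(ln)))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) next
    rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
  }
  if (!length(rows)) stop("no sequence lines found in ", path)
  seqs <- toupper(gsub("\\.", "-", unlist(rows)))
  new("SeqAlignment", rows = seqs)
}

#' Write nucleotide sequences as FASTA
#' @param sequences named character vector of nucleotide sequences.
#' @param path output path.
#' @export
writeNucleotideFasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 60L)
  invisible(path)
}
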