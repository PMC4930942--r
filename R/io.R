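# Readers and writers: TSV matrices and sheets, promoter FASTA, JSON truth.
# Table dialect: tab-delimited, header row, '.' decimal, no quoting.

#' Read an expression matrix and its sample sheet
#'
#' The matrix TSV has a `gene_id` first column and one numeric column per
#' sample; the sheet TSV has columns sample_id, genotype, condition,
#' replicate. Sample ids must match between the two files; duplicate gene or
#' sample ids and non-finite values are rejected.
#'
#' @param matrix_path,sample_sheet_path Paths to the two TSV files.
#' @return List with `expr` and `samples` tibbles.
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  expr <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "gene_id") {
    abort("expression matrix must have 'gene_id' as its first column")
  }
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE,
                             progress = FALSE)
  need <- c("sample_id", "genotype", "condition", "replicate")
  if (!all(need %in% names(samples))) {
    abort(paste0("sample sheet must have columns: ", paste(need, collapse = ", ")))
  }
  non_num <- setdiff(names(expr), "gene_id")[
    !vapply(expr[setdiff(names(expr), "gene_id")], is.numeric, TRUE)]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric expression columns: ", paste(non_num, collapse = ", ")))
  }
  samples$replicate <- as.integer(samples$replicate)
  validate_expression(expr, samples)
  list(expr = expr, samples = as_tibble(samples))
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param expr,samples Expression tibble and sample sheet.
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(expr, samples, matrix_path, sample_sheet_path) {
  validate_expression(expr, samples)
  readr::write_tsv(expr, matrix_path, progress = FALSE)
  readr::write_tsv(samples, sample_sheet_path, progress = FALSE)
  invisible(matrix_path)
}

#' Read promoter sequences from FASTA
#'
#' Record id = first whitespace-delimited token of the header; sequences are
#' uppercased. Duplicate ids, empty sequences, U (RNA) and letters outside
#' the IUPAC nucleotide alphabet are rejected.
#'
#' @param path FASTA file path.
#' @return Tibble: gene_id, sequence.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) abort("empty sequence in FASTA")
  if (any(grepl("U", seqs, fixed = TRUE))) abort("RNA letter U in FASTA")
  bad <- grepl(paste0("[^", paste(names(IUPAC_MAP), collapse = ""), "]"), seqs)
  if (any(bad)) {
    abort(paste0("non-nucleotide letters in sequence for: ", ids[bad][1]))
  }
  tibble(gene_id = unname(ids), sequence = unname(seqs))
}

#' Write promoter sequences as FASTA
#'
#' @param promoters Tibble with `gene_id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, the path.
#' @export
write_promoter_fasta <- function(promoters, path, width = 60) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- promoters$gene_id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a diurnal time-course matrix
#'
#' TSV with `gene_id` first and one `ZT<t>` column per timepoint.
#'
#' @param path TSV path.
#' @return Tibble of profiles.
#' @export
read_time_course <- function(path) {
  tc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tc)[1] != "gene_id") abort("time course must have 'gene_id' first")
  profile_timepoints(tc) # validates ZT columns
  tc
}

#' Write a diurnal time-course matrix as TSV
#'
#' @param profiles Tibble of profiles (gene_id + ZT columns).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_time_course <- function(profiles, path) {
  readr::write_tsv(profiles, path, progress = FALSE)
  invisible(path)
}

#' Write planted truth as JSON
#'
#' @param truth Truth tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
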