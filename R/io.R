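#' Read a FASTQ file into a read table
#'
#' Plain 4-line-record FASTQ. Read names of the form
#' `cell:UMI:index` (as written by [gen_reads()]) are parsed into
#' `cell_id` and `umi` columns; other names leave those columns NA.
#'
#' @param path FASTQ file path.
#' @return `fastq_reads` data.frame with `read_id`, `cell_id`, `umi`,
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record starting at line ",
         4 * (length(lines) %/% 4) + 1)
  n <- length(lines) %/% 4
  if (n == 0) {
    out <- data.frame(read_id = character(), cell_id = character(),
                      umi = character(), sequence = character(),
                      quality = character())
    class(out) <- c("fastq_reads", "data.frame")
    return(out)
  }
  hdr <- lines[seq(1, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  if (any(substr(hdr, 1, 1) != "@"))
    stop("malformed header at line ",
         (which(substr(hdr, 1, 1) != "@")[1] - 1) * 4 + 1)
  if (any(substr(plus, 1, 1) != "+"))
    stop("malformed separator at line ",
         (which(substr(plus, 1, 1) != "+")[1] - 1) * 4 + 3)
  ids <- sub("^@", "", hdr)
  parts <- strsplit(ids, ":", fixed = TRUE)
  cell <- vapply(parts, function(p) if (length(p) >= 3) p[1] else NA_character_, "")
  umi <- vapply(parts, function(p) if (length(p) >= 3) p[2] else NA_character_, "")
  out <- data.frame(read_id = ids, cell_id = cell, umi = umi,
                    sequence = lines[seq(2, by = 4, length.out = n)],
                    quality = lines[seq(4, by = 4, length.out = n)],
                    stringsAsFactors = FALSE)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Write a read table as FASTQ
#'
#' @param reads `fastq_reads` data.frame (a `quality` column is used if
#'   present, else a constant Phred+33 quality is written).
#' @param path output path.
#' @param quality_char constant quality character when no quality column.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  qual <- reads$quality
  if (is.null(qual))
    qual <- vapply(nchar(reads$sequence), function(L)
      strrep(quality_char, L), "")
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix with gene and cell labels
#'
#' Matrix Market coordinate format (`.mtx`, with sibling
#' `<path>.genes.txt` / `<path>.cells.txt` one-column label files) or a
#' dense tab-delimited table with gene rownames and cell column names.
#'
#' @param path `.mtx` or delimited file path.
#' @return sparse `dgCMatrix` (genes x cells) with dimnames.
#' @export
read_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes.txt"))
    cells <- readLines(paste0(path, ".cells.txt"))
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("label/dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but labels are ", length(genes), " genes x ",
           length(cells), " cells")
    dimnames(m) <- list(genes, cells)
    methods::as(m, "CsparseMatrix")
  } else {
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE))
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
}

#' Write a count matrix with gene and cell labels
#'
#' @param mat genes x cells matrix with dimnames.
#' @param path output path; `.mtx` writes Matrix Market plus
#'   `<path>.genes.txt` / `<path>.cells.txt`, anything else a dense
#'   tab-delimited table.
#' @return the path, invisibly.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(mat), paste0(path, ".genes.txt"))
    writeLines(colnames(mat), paste0(path, ".cells.txt"))
  } else {
    write.table(as.matrix(mat), path, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}

#' Read / write a run configuration
#'
#' Plain-text YAML configuration holding module parameters and the seed.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list of parameters.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its effective parameters, seed, and outputs
#' in a JSON manifest so it can be reproduced exactly.
#'
#' @param manifest named list (parameters, seed, outputs, ...).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
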