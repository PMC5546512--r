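#' Read a gene annotation table
#'
#' Expects a tab-delimited file with columns `gene_id`, `chrom`, `strand`,
#' `tss` (0-based transcription start position).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per gene.
#' @export
read_genes <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(g)))
    stop("genes table must have columns: ", paste(need, collapse = ", "))
  if (any(!g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(g$tss < 0)) stop("negative tss in gene annotation")
  g
}

#' Read a BED3 interval file (0-based, half-open)
#'
#' @param path Path to the BED file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  b <- b[, 1:3]
  if (any(b$start >= b$end)) stop("malformed BED interval: start >= end")
  b
}

#' Write intervals as BED3
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired-interval records (BEDPE, first six columns)
#'
#' @param path Path to the BEDPE file.
#' @return data.frame with `chrom1,start1,end1,chrom2,start2,end2` and, when
#'   present, `name` and `score`.
#' @export
read_bedpe <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 6) stop("BEDPE requires at least six columns")
  names(b)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(b) >= 7) names(b)[7] <- "name"
  if (ncol(b) >= 8) names(b)[8] <- "score"
  b
}

#' Write paired-interval records as BEDPE
#' @param inter data.frame with the six BEDPE coordinate columns.
#' @param path Output path.
#' @export
write_bedpe <- function(inter, path) {
  cols <- intersect(
    c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score"),
    names(inter))
  utils::write.table(inter[, cols], path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CpG probe manifest
#'
#' Tab-delimited with columns `probe_id`, `chrom`, `pos` (0-based position of
#' the interrogated CpG).
#'
#' @param path Path to the TSV file.
#' @return data.frame of probes.
#' @export
read_probes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(p)))
    stop("probe manifest must have columns: ", paste(need, collapse = ", "))
  p
}

#' Read a numeric matrix stored as TSV
#'
#' First column holds row identifiers (probes or genes), remaining columns are
#' samples.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with rownames and sample column names.
#' @export
read_matrix_tsv <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- m[[1]]
  m <- as.matrix(m[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("matrix file contains non-numeric entries")
  rownames(m) <- rn
  m
}

#' Write a numeric matrix as TSV
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited with columns `sample_id`, `group` (normal/tumor), `subtype`
#' (basal/non_basal, may be empty for normals), `os_time`, `os_event`.
#'
#' @param path Path to the TSV file.
#' @return data.frame of samples.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "subtype", "os_time", "os_event")
  if (!all(need %in% names(cl)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  cl
}

#' Read gene sets in GMT format
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> member gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Second-column description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
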