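#' Read a BED3/BED6 file
#'
#' Headerless tab-separated BED. Columns beyond the third are kept as
#' `name`, `score`, `strand` when present.
#'
#' @param path file path
#' @return interval data.frame
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(empty_intervals())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' Emits sorted, tab-separated, newline-terminated records without headers.
#'
#' @param x interval data.frame
#' @param path output path
#' @param columns which columns to write (default: all present, BED order)
#' @export
write_bed <- function(x, path, columns = NULL) {
  validate_intervals(x)
  x <- iv_sort(x)
  if (is.null(columns)) {
    bed_order <- c("chrom", "start", "end", "name", "score", "strand")
    columns <- c(intersect(bed_order, names(x)),
                 setdiff(names(x), bed_order))
  }
  out <- x[, columns, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak (BED6+4) file
#'
#' @param path file path
#' @return interval data.frame with payload columns name, score, strand,
#'   signal, p, q, summit
#' @export
read_narrowpeak <- function(path) {
  if (file.size(path) == 0) return(empty_intervals())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) != 10) {
    stop(sprintf("narrowPeak file %s has %d columns, expected 10", path, ncol(df)))
  }
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signal", "p", "q", "summit")
  validate_intervals(df)
  df
}

#' Write intervals as narrowPeak
#'
#' Missing payload columns are filled with narrowPeak placeholders
#' (name ".", score 0, strand ".", signal/p/q -1, summit -1).
#'
#' @param x interval data.frame
#' @param path output path
#' @export
write_narrowpeak <- function(x, path) {
  validate_intervals(x)
  x <- iv_sort(x)
  defaults <- list(name = ".", score = 0, strand = ".",
                   signal = -1, p = -1, q = -1, summit = -1)
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  }
  write_bed(x, path, columns = c("chrom", "start", "end", "name", "score",
                                 "strand", "signal", "p", "q", "summit"))
}

#' Read a chrom.sizes file
#'
#' Two-column TSV (chromosome, length in bp).
#'
#' @param path file path
#' @return named numeric vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#'
#' @param sizes named numeric vector of chromosome lengths
#' @param path output path
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(chrom = names(sizes),
               length = format(unname(sizes), scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a headered TSV table
#'
#' Used for correlation-peak tables, gene annotations, DE results, sample
#' metadata and manifests.
#'
#' @param path file path
#' @return data.frame
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", check.names = FALSE)
}

#' Write a headered TSV table
#'
#' @param x data.frame
#' @param path output path
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix TSV (genes x samples)
#'
#' First column holds gene ids; remaining columns are samples.
#'
#' @param path file path
#' @return numeric matrix with gene ids as rownames
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV (genes x samples)
#'
#' @param m numeric matrix with gene rownames
#' @param path output path
#' @param id_col name of the gene id column (default "gene_id")
#' @export
write_expression_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_table(df, path)
}
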