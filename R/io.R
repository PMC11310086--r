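#' Read / write tab-separated pipeline tables
#'
#' Thin wrappers fixing the conventions used across the pipeline: tab
#' separation, no quoting, no row names, header line.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as gene_id + one column per sample
#'
#' @param mat gene x sample matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_expression_tsv
#' @return matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a gene map as BED-like TSV (0-based half-open)
#'
#' Each gene occupies `[position, position + 1)` in ordinal coordinates.
#'
#' @param genome data.frame (gene_id, chromosome, position).
#' @param path file path.
#' @export
write_gene_bed <- function(genome, path) {
  bed <- data.frame(chrom = genome$chromosome, start = genome$position,
                    end = genome$position + 1L, name = genome$gene_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @return data.frame (gene_id, chromosome, position).
#' @export
read_gene_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = bed[[4L]], chromosome = bed[[1L]],
             position = bed[[2L]], stringsAsFactors = FALSE)
}
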