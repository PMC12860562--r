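## Readers/writers for on-disk formats. All internal coordinates are
## 0-based half-open; conversion to/from 1-based closed (GFF3, methylation
## position column) happens only here, at the file boundary.

#' Validate a set of genomic intervals
#'
#' Every interval used anywhere in the package must satisfy
#' 0 <= start < end with a non-empty chromosome name.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return `x` invisibly; stops on violation.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
    stop("interval with empty chromosome name")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Convert an interval data.frame to a GRanges
#'
#' Internal 0-based half-open coordinates become the 1-based closed
#' convention of GenomicRanges. '.' strands map to '*'.
#' @param x interval data.frame (see [validate_intervals()]).
#' @return a [GenomicRanges::GRanges] object.
#' @export
as_granges <- function(x) {
  validate_intervals(x)
  strand <- if ("strand" %in% names(x)) sub("^\\.$", "*", x$strand) else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Convert a GRanges back to a 0-based half-open data.frame
#' @param gr a GRanges.
#' @return data.frame with chrom/start/end/strand columns.
#' @export
from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("^\\*$", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

## ---- gene annotation (GFF3-like) ------------------------------------------

#' Read a GFF3-like gene annotation
#'
#' Parses `gene` records from a GFF3-like file (1-based closed coordinates)
#' into 0-based half-open gene models. The TSS is derived from strand:
#' the interval start on '+', end - 1 on '-'. TF status is carried by the
#' optional `tf_family=` attribute.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss,
#'   is_tf, tf_family (NA when not a TF).
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      tss = integer(), is_tf = logical(), tf_family = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GFF3 line ", idx[which(nf != 9L)[1]], ": expected 9 fields, got ",
         nf[which(nf != 9L)[1]])
  m <- do.call(rbind, fields)
  type <- m[, 3]
  m <- m[type == "gene", , drop = FALSE]
  ln <- idx[type == "gene"]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1))
    stop("malformed GFF3 line ", ln[which(is.na(start1) | is.na(end1))[1]],
         ": non-integer coordinates")
  attr_field <- strsplit(m[, 9], ";", fixed = TRUE)
  get_attr <- function(key) {
    pre <- paste0(key, "=")
    vapply(attr_field, function(kv) {
      hit <- kv[startsWith(kv, pre)]
      if (length(hit)) sub(pre, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  gene_id <- get_attr("ID")
  if (anyNA(gene_id))
    stop("malformed GFF3 line ", ln[which(is.na(gene_id))[1]], ": missing ID attribute")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in annotation: ", gene_id[duplicated(gene_id)][1])
  tf_family <- get_attr("tf_family")
  strand <- m[, 7]
  genes <- data.frame(
    gene_id = gene_id, chrom = m[, 1],
    start = start1 - 1L, end = end1,                # to 0-based half-open
    strand = strand,
    tss = ifelse(strand == "-", end1 - 1L, start1 - 1L),
    is_tf = !is.na(tf_family), tf_family = tf_family,
    stringsAsFactors = FALSE
  )
  validate_intervals(genes)
  genes
}

#' Write gene models as GFF3
#' @param genes gene model data.frame (see [read_annotation()]).
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  validate_intervals(genes)
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(genes$is_tf & !is.na(genes$tf_family),
                         paste0(";tf_family=", genes$tf_family), ""))
  lines <- c("##gff-version 3",
             paste(genes$chrom, "seasomics", "gene",
                   genes$start + 1L, genes$end, ".", genes$strand, ".", attrs,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## ---- peaks (narrowPeak-like, BED6+4) --------------------------------------

#' Read a narrowPeak-like peak file
#'
#' BED-style 0-based half-open, ten columns: chrom, start, end, name, score,
#' strand, signalValue, pValue, qValue, summit offset. The absolute summit
#' position is start + offset (offset -1 means unknown and yields NA).
#'
#' @param path file path.
#' @return data.frame of peaks with a `summit` column (absolute, 0-based).
#' @export
read_peaks <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0 || !length(readLines(path, n = 1)))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      signal = numeric(), p = numeric(), q = numeric(),
                      summit_offset = integer(), summit = integer(),
                      stringsAsFactors = FALSE))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name", "score",
                                       "strand", "signal", "p", "q", "summit_offset"),
                         colClasses = "character", stringsAsFactors = FALSE)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  ## '.' placeholders in numeric columns become NA
  for (col in c("score", "signal", "p", "q"))
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  x$summit_offset <- as.integer(x$summit_offset)
  validate_intervals(x)
  x$summit <- ifelse(x$summit_offset >= 0, x$start + x$summit_offset, NA_integer_)
  x
}

#' Write peaks in narrowPeak format
#' @param peaks peak data.frame (see [read_peaks()]).
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_intervals(peaks)
  utils::write.table(
    peaks[, c("chrom", "start", "end", "name", "score", "strand",
              "signal", "p", "q", "summit_offset")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- methylation -----------------------------------------------------------

#' Methylation context vocabulary
#' @export
METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a per-cytosine methylation table
#'
#' Tab-separated columns: chrom, pos (1-based in the file), strand,
#' context (CG/CHG/CHH), methylated count, total count. Positions are
#' stored 0-based internally.
#'
#' @param path file path.
#' @return data.frame with columns chrom, pos (0-based), strand, context,
#'   methylated, total.
#' @export
read_methylation <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "character",
                                        "character", "integer", "integer"),
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "pos", "strand", "context", "methylated", "total")
  bad <- !x$context %in% METH_CONTEXTS
  if (any(bad))
    stop("unknown methylation context '", x$context[which(bad)[1]], "'")
  if (any(x$methylated > x$total))
    stop("methylated count exceeds total at row ", which(x$methylated > x$total)[1])
  if (any(x$methylated < 0 | x$total < 0)) stop("negative methylation counts")
  x$pos <- x$pos - 1L
  x
}

#' Write a per-cytosine methylation table (1-based positions on disk)
#' @param sites methylation data.frame (0-based `pos`).
#' @param path output path.
#' @export
write_methylation <- function(sites, path) {
  out <- sites[, c("chrom", "pos", "strand", "context", "methylated", "total")]
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- Hi-C contact matrices -------------------------------------------------

#' Construct a contact matrix object
#'
#' @param mat square nonnegative matrix; symmetrized by the elementwise max
#'   of the two triangles.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param mask optional logical vector of masked (bad) bins.
#' @return list of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bin_size, chrom = "chr", mask = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0)) stop("negative contact counts")
  mat <- pmax(mat, t(mat))
  if (is.null(mask)) mask <- rep(FALSE, nrow(mat))
  stopifnot(length(mask) == nrow(mat))
  structure(list(matrix = mat, bin_size = as.integer(bin_size),
                 chrom = chrom, mask = mask),
            class = "contact_matrix")
}

#' Read a binned Hi-C contact matrix
#'
#' Accepts COO triplets (three columns: 0-based bin_i, bin_j, count) or a
#' dense TSV (n rows of n numbers). The matrix is symmetrized by the max
#' of the two triangles; dimension is `ceiling(chrom_length / bin_size)`.
#'
#' @param path file path.
#' @param bin_size bin width (bp).
#' @param chrom_length chromosome length (bp).
#' @param chrom chromosome name.
#' @return a `contact_matrix`.
#' @export
read_contacts <- function(path, bin_size, chrom_length, chrom = "chr") {
  stopifnot(file.exists(path))
  n <- as.integer(ceiling(chrom_length / bin_size))
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(first)) {
    return(contact_matrix(matrix(0, n, n), bin_size, chrom))
  }
  ncol1 <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol1 == 3L) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("i", "j", "count"))
    if (any(x$count < 0)) stop("negative contact counts")
    if (any(x$i < 0 | x$j < 0 | x$i >= n | x$j >= n))
      stop("bin index out of range for ", n, " bins")
    m <- matrix(0, n, n)
    m[cbind(x$i + 1L, x$j + 1L)] <- x$count
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop("dense matrix is ", nrow(m), "x", ncol(m), ", expected ", n, "x", n)
    if (any(m < 0)) stop("negative contact counts")
  }
  contact_matrix(m, bin_size, chrom)
}

#' Write a contact matrix as COO triplets (upper triangle incl. diagonal)
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @export
write_contacts <- function(cm, path) {
  m <- cm$matrix
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  ## bin_i <= bin_j, 0-based
  out <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                    count = m[idx])
  out <- out[order(out$i, out$j), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- matrices and tables ---------------------------------------------------

#' Read a feature-by-sample count/abundance matrix from TSV
#' @param path file path; first column holds feature ids.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' Write a feature-by-sample matrix as TSV
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
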