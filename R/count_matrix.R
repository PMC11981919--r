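#' Construct a variant count matrix
#'
#' The substrate of every statistical stage: per-variant annotations plus
#' matrices of variant-supporting read counts (`NV`) and total depths (`NR`),
#' one column per microdissection, and a per-cell flag marking loci that are
#' largely diploid in that sample (used to select samples for the germline
#' test).
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `var_class` (`"SNV"` or `"indel"`). Quality columns `asmd`/`clpm` and
#'   annotation columns (`context`, `channel`, `gene`, `consequence`, ...) are
#'   carried through.
#' @param NV,NR Integer matrices, variants x samples, `0 <= NV <= NR`.
#' @param diploid Logical matrix of the same dimension; defaults to all TRUE.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(variants, NV, NR, diploid = NULL) {
  NV <- as.matrix(NV); NR <- as.matrix(NR)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt", "var_class") %in%
                  names(variants)),
            nrow(variants) == nrow(NV),
            all(dim(NV) == dim(NR)))
  if (any(NV < 0) || any(NV > NR))
    stop("count_matrix: NV must satisfy 0 <= NV <= NR elementwise")
  if (any(variants$pos < 1)) stop("count_matrix: pos must be >= 1")
  if (is.null(diploid)) diploid <- matrix(TRUE, nrow(NV), ncol(NV))
  diploid <- as.matrix(diploid)
  stopifnot(all(dim(diploid) == dim(NV)))
  if (is.null(colnames(NV))) colnames(NV) <- paste0("S", seq_len(ncol(NV)))
  colnames(NR) <- colnames(NV)
  colnames(diploid) <- colnames(NV)
  structure(list(variants = variants, NV = NV, NR = NR, diploid = diploid),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$NV), "variants x", ncol(x$NV), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$variants$var_class)),
                                  table(x$variants$var_class)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$NV)

#' Write a count matrix as TSV
#'
#' Layout: variant annotation columns, then paired `NV:<sample>` and
#' `NR:<sample>` columns.
#'
#' @param cm A [count_matrix].
#' @param path Output path.
#' @export
write_count_matrix <- function(cm, path) {
  sam <- colnames(cm$NV)
  counts <- cbind(cm$NV, cm$NR)[, rep(seq_along(sam), each = 2) +
                                  c(0, length(sam)), drop = FALSE]
  colnames(counts) <- as.vector(rbind(paste0("NV:", sam), paste0("NR:", sam)))
  write.table(cbind(cm$variants, counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_count_matrix()] (or any TSV using the
#'   same `NV:`/`NR:` column convention).
#' @return A [count_matrix] (diploid mask all TRUE; real-data users supply
#'   their own from copy-number calls).
#' @export
read_count_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nv_cols <- grep("^NV:", names(d), value = TRUE)
  nr_cols <- grep("^NR:", names(d), value = TRUE)
  if (!length(nv_cols) || length(nv_cols) != length(nr_cols))
    stop("no paired NV:/NR: columns found in ", path)
  sam <- sub("^NV:", "", nv_cols)
  NV <- as.matrix(d[nv_cols]); NR <- as.matrix(d[paste0("NR:", sam)])
  colnames(NV) <- colnames(NR) <- sam
  count_matrix(d[setdiff(names(d), c(nv_cols, nr_cols))], NV, NR)
}
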