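## NF-kB expression index: geometric mean of an 11-gene target signature on
## variance-stabilized expression values, standardized across the cohort, with
## samples called NF-kB+ when the index is positive and at least one signature
## gene exceeds its cohort upper quartile.

#' The 11-gene NF-kB target signature
#'
#' Default signature used by the NF-kB expression index: direct NF-kB target
#' genes whose joint expression tracks pathway activity in myeloma cohorts.
#' @format Character vector of 11 gene symbols.
#' @export
nfkbSignatureGenes <- c("BIRC3", "NFKB2", "TNFAIP3", "IL2RG", "NFKBIE",
                        "RELB", "NFKBIA", "CD74", "PLEK", "MALT1", "WNT10A")

checkSignature <- function(expr, signature) {
    if (length(signature) < 2L)
        stop("a signature needs at least 2 genes")
    missing <- setdiff(signature, rownames(expr))
    if (length(missing))
        stop("signature gene(s) absent from the expression matrix: ",
             paste(missing, collapse = ", "))
    sub <- expr[signature, , drop = FALSE]
    bad <- which(sub <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop("non-positive expression for signature gene '",
             signature[bad[1L, 1L]], "' in sample '",
             colnames(sub)[bad[1L, 2L]],
             "'; the index expects positive variance-stabilized values")
    sub
}

#' Geometric mean of signature-gene expression per sample
#'
#' @param expr Numeric matrix of positive expression values, genes in rows
#'   (rownames = symbols), samples in columns.
#' @param signature Character vector of signature gene symbols
#'   (default \code{nfkbSignatureGenes}).
#' @return Named numeric vector: per-sample geometric mean of the signature
#'   values, \code{exp(mean(log(x)))}.
#' @examples
#' m <- matrix(6, nrow = 2, ncol = 3,
#'             dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' geometricMeanIndex(m, c("A", "B"))
#' @export
geometricMeanIndex <- function(expr, signature = nfkbSignatureGenes) {
    sub <- checkSignature(expr, signature)
    exp(colMeans(log(sub)))
}

#' Standardize raw index values to z-scores
#'
#' Converts per-sample geometric means to standard scores over the cohort
#' (mean 0, unit sd; sample sd with n - 1 denominator).
#'
#' @param raw Named numeric vector of per-sample raw values.
#' @return Named numeric vector of z-scores.
#' @export
standardizeIndex <- function(raw) {
    if (length(raw) < 2L)
        stop("degenerate cohort: need at least 2 samples to standardize")
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0)
        stop("degenerate cohort: zero variance in the raw index")
    (raw - mean(raw)) / s
}

#' Classify cohort samples as NF-kB+ / NF-kB-
#'
#' A sample is \code{NFkB_plus} iff its standardized index is positive and at
#' least one signature gene's expression strictly exceeds that gene's 75th
#' percentile across the cohort (type-7 linear-interpolation quantile);
#' otherwise \code{NFkB_minus}.
#'
#' @inheritParams geometricMeanIndex
#' @param index Optional precomputed standardized index (parallel to the
#'   samples); computed from \code{expr} when NULL.
#' @return Factor with levels \code{NFkB_plus}, \code{NFkB_minus}, named by
#'   sample.
#' @export
classifyNFkB <- function(expr, signature = nfkbSignatureGenes, index = NULL) {
    sub <- checkSignature(expr, signature)
    if (is.null(index))
        index <- standardizeIndex(geometricMeanIndex(expr, signature))
    q3 <- apply(sub, 1L, stats::quantile, probs = 0.75, type = 7, names = FALSE)
    beyondQ3 <- colSums(sub > q3) > 0L
    grp <- ifelse(index > 0 & beyondQ3, "NFkB_plus", "NFkB_minus")
    factor(stats::setNames(grp, colnames(expr)),
           levels = c("NFkB_plus", "NFkB_minus"))
}

#' Compute the full NF-kB index result for a cohort
#'
#' @inheritParams geometricMeanIndex
#' @return A \code{DataFrame} with one row per sample: \code{sample},
#'   \code{raw_gm}, \code{index} (z-score) and \code{group}.
#' @export
nfkbIndex <- function(expr, signature = nfkbSignatureGenes) {
    raw <- geometricMeanIndex(expr, signature)
    idx <- standardizeIndex(raw)
    grp <- classifyNFkB(expr, signature, index = idx)
    DataFrame(sample = colnames(expr), raw_gm = unname(raw),
              index = unname(idx), group = unname(grp))
}

#' Read an expression matrix from TSV
#'
#' Expects a header of sample identifiers and a first column of gene symbols.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicate gene symbols in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids in ", path)
    rownames(m) <- genes
    storage.mode(m) <- "double"
    m
}

#' Write an NF-kB index result table as TSV
#'
#' @param result A \code{DataFrame} as returned by \code{nfkbIndex}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeIndexResult <- function(result, path) {
    utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
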