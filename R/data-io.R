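#' Construct an ExpressionMatrix
#'
#' @param values numeric genes-by-samples matrix. Row names are used as gene
#'   identifiers when \code{geneIds} is missing.
#' @param geneIds character vector of unique gene identifiers (one per row).
#' @param sampleNames character vector of sample/time-point names (one per
#'   column).
#' @param logScale logical; \code{TRUE} when values are on the log2 scale.
#'   On the linear scale (default) all values must be strictly positive.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' em <- ExpressionMatrix(matrix(1:6 + 0, 2, 3), geneIds = c("g1", "g2"))
#' dim(em)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             sampleNames = colnames(values),
                             logScale = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(geneIds))
        stop("gene identifiers are required (rownames or 'geneIds')")
    if (is.null(sampleNames))
        sampleNames <- paste0("t", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(geneIds), as.character(sampleNames))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("ExpressionMatrix", se, logScale = isTRUE(logScale))
}

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
    function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("isLogScale", "ExpressionMatrix", function(x) x@logScale)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
        nrow(object), ncol(object),
        if (object@logScale) "log2" else "linear"))
    cat("samples:", paste(colnames(object), collapse = ", "), "\n")
})

#' Read a gene expression matrix from a tab-separated file
#'
#' Expects a header row (gene-id column followed by sample names) and one
#' row per gene: identifier then numeric expression values. Ragged rows,
#' non-numeric cells and duplicate identifiers are rejected with the
#' offending row number.
#'
#' @param path path to a UTF-8 TSV file.
#' @param logScale logical, passed through to [ExpressionMatrix()].
#' @return An \linkS4class{ExpressionMatrix} with rows in file order.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, logScale = FALSE) {
    if (!file.exists(path))
        stop(sprintf("expression file not found: %s", path))
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("expression file needs a header row and at least one gene row")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    nCol <- length(header)
    if (nCol < 2L)
        stop("header must contain a gene-id column and at least one sample")
    ids <- character(length(fields) - 1L)
    values <- matrix(NA_real_, length(fields) - 1L, nCol - 1L)
    seen <- new.env(hash = TRUE)
    for (r in seq.int(2L, length(fields))) {
        row <- fields[[r]]
        if (length(row) != nCol)
            stop(sprintf("row %d has %d fields, expected %d",
                r, length(row), nCol))
        id <- row[1L]
        if (!is.null(seen[[id]]))
            stop(sprintf("duplicate gene id '%s' on row %d", id, r))
        seen[[id]] <- TRUE
        num <- suppressWarnings(as.numeric(row[-1L]))
        if (anyNA(num))
            stop(sprintf("non-numeric value on row %d (gene '%s')", r, id))
        ids[r - 1L] <- id
        values[r - 1L, ] <- num
    }
    ExpressionMatrix(values, geneIds = ids, sampleNames = header[-1L],
        logScale = logScale)
}

#' Write an expression matrix as TSV
#'
#' Full-precision (\code{format} with 17 significant digits) so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param idColumn name for the gene-id header field.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "gene_id") {
    v <- exprValues(x)
    header <- paste(c(idColumn, colnames(v)), collapse = "\t")
    body <- vapply(seq_len(nrow(v)), function(i) {
        paste(c(rownames(v)[i],
            format(v[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path, useBytes = TRUE)
    invisible(path)
}

#' Filter genes by fold change across the time course
#'
#' Keeps gene i when \code{low <= max_t(x_i)/min_t(x_i) <= high} (both
#' bounds inclusive), the criterion used to restrict a time course to
#' genes whose expression varies within a given fold-change window. On
#' log2-scale data the ratio is \code{2^(max - min)}.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param low,high positive fold-change bounds, \code{1 <= low <= high}.
#'   Defaults 4 and 26.
#' @return A new \linkS4class{ExpressionMatrix} with surviving genes in
#'   their original order.
#' @examples
#' em <- ExpressionMatrix(rbind(a = c(1, 5), b = c(1, 2)))
#' geneIds(foldChangeFilter(em, 4, 26))   # only "a" (ratio 5)
#' @export
foldChangeFilter <- function(x, low = 4, high = 26) {
    low <- assertPositiveScalar(low, "low")
    high <- assertPositiveScalar(high, "high")
    if (low < 1 || low > high)
        stop("fold-change bounds must satisfy 1 <= low <= high")
    fc <- foldChanges(x)
    keep <- fc >= low & fc <= high
    if (!any(keep))
        stop("no genes survive the fold-change filter")
    v <- exprValues(x)[keep, , drop = FALSE]
    ExpressionMatrix(v, logScale = isLogScale(x))
}

#' Per-gene fold change (max over min across samples)
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return Named numeric vector of per-gene fold changes on the linear
#'   scale.
#' @export
foldChanges <- function(x) {
    v <- exprValues(x)
    if (isLogScale(x)) {
        2^(apply(v, 1L, max) - apply(v, 1L, min))
    } else {
        if (any(v <= 0))
            stop("non-positive value on linear scale; fold change undefined")
        apply(v, 1L, max) / apply(v, 1L, min)
    }
}

#' Log2-transform a linear-scale expression matrix
#'
#' Spectral embeddings with a fixed heat-kernel bandwidth operate on the
#' log2 scale, where expression distances are comparable across intensity
#' ranges; linear-scale intensities would make almost all heat-kernel
#' weights underflow. A matrix already flagged log-scale is returned
#' unchanged.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return A log2-scale \linkS4class{ExpressionMatrix}.
#' @export
logTransform <- function(x) {
    if (isLogScale(x)) return(x)
    ExpressionMatrix(log2(exprValues(x)), logScale = TRUE)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (category -> members);
#'   members are de-duplicated.
#' @param descriptions optional named character vector of descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(descriptions)) {
        descriptions <- setNames(rep("", length(sets)), names(sets))
    }
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)])
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets", length(object@sets)))
    if (length(object@sets))
        cat(sprintf(" (sizes %d-%d)", min(lengths(object@sets)),
            max(lengths(object@sets))))
    cat("\n")
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one category per line,
#' \code{name TAB description TAB member TAB member ...}. Members are
#' de-duplicated within a set; lines with fewer than three fields and
#' duplicate category names are errors. An empty file yields an empty
#' collection with a warning.
#'
#' @param path path to a GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path))
        stop(sprintf("GMT file not found: %s", path))
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
        warning("empty GMT file; returning an empty collection")
        return(new("GeneSetCollection", sets = list(),
            descriptions = character(0)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop(sprintf("duplicate category name '%s'",
            nm[duplicated(nm)][1L]))
    sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(sets) <- nm
    desc <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
    GeneSetCollection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(x, path) {
    lines <- vapply(names(x@sets), function(nm) {
        paste(c(nm, x@descriptions[[nm]], x@sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a label list (one gene id per line, '#' comments allowed)
#'
#' @param path path to a plain-text label file.
#' @return Character vector of unique gene identifiers.
#' @export
readLabelSet <- function(path) {
    if (!file.exists(path))
        stop(sprintf("label file not found: %s", path))
    lines <- trimws(readLines(path, encoding = "UTF-8"))
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    unique(lines[nzchar(lines)])
}
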