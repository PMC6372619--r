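#' Construct an expression matrix with control annotations
#'
#' The entry-point container: a dense genes x samples matrix of raw
#' expression values plus a logical mask flagging control (vehicle) samples.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param control_mask Logical vector, one entry per sample (`TRUE` =
#'   control). Recycled from `FALSE` if missing entries are implied by a
#'   character vector of control sample ids.
#' @return An object of class `olsa_expression` with elements `values` and
#'   `control_mask`.
#' @export
expression_matrix <- function(values, control_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  if (is.null(control_mask)) control_mask <- rep(FALSE, ncol(values))
  if (is.character(control_mask)) {
    unknown <- setdiff(control_mask, colnames(values))
    if (length(unknown))
      stop("unknown control sample ids: ", paste(unknown, collapse = ", "))
    control_mask <- colnames(values) %in% control_mask
  }
  if (!is.logical(control_mask) || length(control_mask) != ncol(values))
    stop("`control_mask` must be logical with one entry per sample")
  names(control_mask) <- colnames(values)
  structure(list(values = values, control_mask = control_mask),
            class = "olsa_expression")
}

#' @export
print.olsa_expression <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$control_mask)))
  invisible(x)
}

#' @export
dim.olsa_expression <- function(x) dim(x$values)

.numeric_or_stop <- function(df, path) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.numeric(col)) next
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value %s in '%s' at row %d, data column %d",
                   dQuote(col[bad[1]]), path, bad[1], j))
    df[[j]] <- num
  }
  df
}

#' Read an expression or response matrix from TSV, CSV or GCT
#'
#' TSV/CSV dialect: first column holds gene ids, header row holds sample
#' ids, '.' decimal. GCT versions 1.2 (`#1.2`) and 1.3 (`#1.3`) are
#' supported; 1.3 row/column metadata are skipped.
#'
#' @param path File path.
#' @param format One of `"auto"` (from the extension / `#1.x` magic),
#'   `"tsv"`, `"csv"`, `"gct"`.
#' @param controls Control designation: a character vector of sample ids, or
#'   the path of a plain-text file with one sample id per line.
#' @param controls_regex Optional regular expression; samples whose ids match
#'   are flagged as controls (combined with `controls` by union).
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv", "gct"),
                                   controls = NULL, controls_regex = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- readLines(path, n = 1L)
    format <- if (ext == "gct" || startsWith(first, "#1.")) "gct"
              else if (ext == "csv") "csv" else "tsv"
  }
  values <- switch(format,
    gct = .read_gct(path),
    csv = .read_delim_matrix(path, ","),
    tsv = .read_delim_matrix(path, "\t"))
  if (!is.null(controls) && length(controls) == 1 && file.exists(controls))
    controls <- readLines(controls, warn = FALSE)
  controls <- setdiff(trimws(controls %||% character()), "")
  if (!is.null(controls_regex))
    controls <- union(controls,
                      grep(controls_regex, colnames(values), value = TRUE))
  expression_matrix(values, if (length(controls)) controls else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_delim_matrix <- function(path, sep) {
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs a gene-id column and >= 1 sample")
  genes <- df[[1]]
  df <- .numeric_or_stop(df[-1], path)
  m <- as.matrix(df)
  rownames(m) <- genes
  m
}

.read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("truncated GCT file: ", path)
  version <- trimws(lines[1])
  if (!version %in% c("#1.2", "#1.3"))
    stop("unsupported GCT version header: ", version)
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (version == "#1.2") {
    if (length(dims) < 2 || anyNA(dims[1:2]))
      stop("malformed GCT dimension line: ", lines[2])
    n_rmeta <- 1L; n_cmeta <- 0L
  } else {
    if (length(dims) < 4 || anyNA(dims[1:4]))
      stop("GCT 1.3 requires 4 dimension fields, got: ", lines[2])
    n_rmeta <- dims[3]; n_cmeta <- dims[4]
  }
  nr <- dims[1]; nc <- dims[2]
  header <- strsplit(lines[3], "\t")[[1]]
  sample_ids <- header[(2 + n_rmeta):length(header)]
  if (length(sample_ids) != nc)
    stop(sprintf("GCT dimension mismatch in '%s': header declares %d samples, stated %d",
                 path, length(sample_ids), nc))
  body <- lines[-(seq_len(3 + n_cmeta))]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("GCT dimension mismatch in '%s': %d data rows, stated %d",
                 path, length(body), nr))
  fields <- strsplit(body, "\t")
  nfield <- lengths(fields)
  if (any(nfield != 1 + n_rmeta + nc))
    stop(sprintf("GCT dimension mismatch in '%s': row %d has %d fields, expected %d",
                 path, which(nfield != 1 + n_rmeta + nc)[1],
                 nfield[nfield != 1 + n_rmeta + nc][1], 1 + n_rmeta + nc))
  genes <- vapply(fields, `[`, "", 1L)
  vals <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[(2 + n_rmeta):(1 + n_rmeta + nc)]))
    v
  }, numeric(nc))
  m <- if (nc == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value in '%s' at data row %d, sample column %d",
                 path, idx[1], idx[2]))
  }
  dimnames(m) <- list(genes, sample_ids)
  m
}

#' Write a genes x samples matrix to TSV, CSV or GCT 1.2
#'
#' @param x An `olsa_expression`, `olsa_response`, or plain numeric matrix
#'   with dimnames.
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"gct"`.
#' @param id_column Header of the gene-id column for TSV/CSV output.
#' @export
write_matrix <- function(x, path, format = c("tsv", "csv", "gct"),
                         id_column = "gene") {
  format <- match.arg(format)
  m <- if (inherits(x, "olsa_expression")) x$values
       else if (inherits(x, "olsa_response")) x$z
       else x
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"), con)
    body <- cbind(rownames(m), rownames(m),
                  format(m, trim = TRUE, digits = 15, scientific = FALSE))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_column
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
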