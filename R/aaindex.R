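# AAindex1 parsing and the PCA amino-acid embedding.
#
# Each AAindex1 record stores one physicochemical index over the 20 standard
# amino acids.  The embedding pipeline is: parse -> drop indices with missing
# values -> robust (median/IQR) per-index normalization -> PCA over the 20
# residues, keeping the top components as the per-residue feature vector.

#' Parse an AAindex1 flat-format file
#'
#' Reads the classic AAindex1 format: records start with an `H <accession>`
#' line, carry a `D` title line and an `I` block whose header row names ten
#' residue pairs (e.g. `A/L`) and whose two following rows hold ten values
#' each; records end with `//`.  The literal string `NA` marks a missing
#' value.
#'
#' @param x Path to an AAindex1 file, or a character vector of its lines
#'   (anything of length > 1, or containing a newline, is treated as text).
#' @return An object of class `raw_index_table`: a list with element
#'   `records`, each record a list with `index_id`, `title`, `values` (named
#'   numeric of length 20 in [AA_ALPHABET20] order, `NA` where missing) and
#'   `missing` (logical flag).
#' @examples
#' f <- system.file("extdata", "aaindex1_synthetic.txt", package = "immunograph")
#' raw <- parse_aaindex(f)
#' length(raw$records)
#' @export
parse_aaindex <- function(x) {
  if (!is.character(x) || length(x) == 0)
    stop("parse_aaindex: input must be a file path or character lines")
  lines <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE)) {
    if (!file.exists(x)) stop("parse_aaindex: file not found: ", x)
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^\\s*$", lines) | TRUE]  # keep blanks; block logic below
  if (all(grepl("^\\s*$", lines)))
    stop("parse_aaindex: empty stream")

  term <- grep("^//\\s*$", lines)
  if (length(term) == 0) stop("parse_aaindex: no record terminators ('//') found")
  starts <- c(1L, head(term, -1L) + 1L)
  records <- vector("list", length(term))
  for (r in seq_along(term)) {
    block <- lines[starts[r]:(term[r] - 1L)]
    block <- block[!grepl("^\\s*$", block)]
    if (length(block) == 0) next
    h <- grep("^H ", block, value = TRUE)
    if (length(h) != 1)
      stop("parse_aaindex: record ", r, " lacks a single H (accession) line")
    acc <- trimws(sub("^H ", "", h[1]))
    d <- grep("^D ", block, value = TRUE)
    title <- if (length(d)) trimws(sub("^D ", "", d[1])) else ""
    i_at <- grep("^I[ \t]", block)
    if (length(i_at) != 1)
      stop("parse_aaindex: record ", acc, " lacks a single I block")
    pairs <- strsplit(trimws(sub("^I[ \t]+", "", block[i_at])), "\\s+")[[1]]
    if (length(pairs) != 10 || !all(grepl("^[A-Z]/[A-Z]$", pairs)))
      stop("parse_aaindex: malformed I header in record ", acc)
    row1 <- substr(pairs, 1, 1)
    row2 <- substr(pairs, 3, 3)
    val_lines <- block[(i_at + 1L):length(block)]
    toks <- unlist(strsplit(trimws(val_lines), "\\s+"), use.names = FALSE)
    if (length(toks) != 20)
      stop("parse_aaindex: record ", acc, " has ", length(toks),
           " values in its I block (expected 20)")
    vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
    bad <- which(is.na(vals) & toks != "NA")
    if (length(bad))
      stop("parse_aaindex: record ", acc, " has non-numeric value '",
           toks[bad[1]], "'")
    names(vals) <- c(row1, row2)
    if (!setequal(names(vals), AA_ALPHABET20))
      stop("parse_aaindex: record ", acc, " I block does not cover the 20 standard residues")
    vals <- vals[AA_ALPHABET20]
    records[[r]] <- list(index_id = acc, title = title, values = vals,
                         missing = anyNA(vals))
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (length(records) == 0) stop("parse_aaindex: no records parsed")
  ids <- vapply(records, `[[`, character(1), "index_id")
  if (anyDuplicated(ids))
    stop("parse_aaindex: duplicated accession(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records), class = "raw_index_table")
}

#' @export
print.raw_index_table <- function(x, ...) {
  n_miss <- sum(vapply(x$records, `[[`, logical(1), "missing"))
  cat("AAindex raw table:", length(x$records), "indices (",
      n_miss, "with missing values )\n")
  invisible(x)
}

#' Drop indices containing missing values
#'
#' Removes every index (column) with one or more missing residue values,
#' keeping file order, and assembles the complete 20 x F matrix.
#'
#' @param raw A `raw_index_table` from [parse_aaindex()].
#' @return An object of class `complete_index_matrix`: list with `matrix`
#'   (20 rows in [AA_ALPHABET20] order x F index columns) and `column_ids`.
#' @export
drop_missing <- function(raw) {
  if (inherits(raw, "complete_index_matrix")) return(raw)  # idempotent entry
  stopifnot(inherits(raw, "raw_index_table"))
  keep <- Filter(function(r) !r$missing, raw$records)
  if (length(keep) == 0) stop("drop_missing: no complete indices survive")
  m <- vapply(keep, `[[`, numeric(20), "values")
  rownames(m) <- AA_ALPHABET20
  colnames(m) <- vapply(keep, `[[`, character(1), "index_id")
  structure(list(matrix = m, column_ids = colnames(m),
                 normalization_params = NULL),
            class = "complete_index_matrix")
}

#' Robustly normalize index columns (median/IQR)
#'
#' Per column: subtract the median over the 20 residues and divide by the
#' interquartile range (Q3 - Q1, linear-interpolation quantiles, R type 7).
#' Columns with zero IQR carry no usable spread and are dropped with a
#' warning.
#'
#' @param cim A `complete_index_matrix`.
#' @return A `complete_index_matrix` whose columns have median 0, with
#'   `normalization_params` (data.frame: column_id, median, iqr) recorded.
#' @export
robust_normalize <- function(cim) {
  stopifnot(inherits(cim, "complete_index_matrix"))
  m <- cim$matrix
  med <- apply(m, 2, median)
  q1 <- apply(m, 2, quantile, probs = 0.25, names = FALSE, type = 7)
  q3 <- apply(m, 2, quantile, probs = 0.75, names = FALSE, type = 7)
  iqr <- q3 - q1
  drop <- iqr == 0
  if (all(drop)) stop("robust_normalize: all columns constant (zero IQR)")
  if (any(drop))
    warning("robust_normalize: dropping ", sum(drop),
            " zero-IQR column(s): ", paste(colnames(m)[drop], collapse = ", "))
  keep <- !drop
  out <- sweep(sweep(m[, keep, drop = FALSE], 2, med[keep], "-"),
               2, iqr[keep], "/")
  structure(list(matrix = out, column_ids = colnames(out),
                 normalization_params = data.frame(
                   column_id = colnames(out),
                   median = unname(med[keep]),
                   iqr = unname(iqr[keep]),
                   stringsAsFactors = FALSE)),
            class = "complete_index_matrix")
}

#' Fit the PCA residue embedding
#'
#' Runs principal component analysis on the 20-residue x F-index matrix
#' (column-centered, unscaled) and keeps the scores of the top
#' `n_components` components as the per-residue embedding.  A centered
#' 20-row matrix has rank at most 19, so when all 20 components are
#' requested the last one carries (numerically) zero variance; its variance
#' ratio is reported via `message()` rather than treated as an error.
#'
#' Sign convention for reproducibility: each loading column is flipped so
#' that its largest-magnitude entry is positive.
#'
#' @param cim A robust-normalized `complete_index_matrix`.
#' @param n_components Number of principal components to keep (default 20).
#' @return An object of class `aa_feature_table`: list with `embedding`
#'   (20 x n_components score matrix, rows in [AA_ALPHABET20] order),
#'   `component_loadings` (F x n_components), `explained_variance`,
#'   `center` (column means), `normalization_params` and `column_ids`.
#' @export
fit_pca_embedding <- function(cim, n_components = 20) {
  stopifnot(inherits(cim, "complete_index_matrix"))
  m <- cim$matrix
  if (ncol(m) < n_components)
    stop("fit_pca_embedding: ", ncol(m), " columns available but ",
         n_components, " components requested")
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  if (k < n_components)
    stop("fit_pca_embedding: decomposition yields only ", k, " components")
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  load <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev[seq_len(n_components)]^2
  if (ev[1] > 0 && ev[n_components] / ev[1] < 1e-8)
    message(sprintf(
      "fit_pca_embedding: component %d variance ratio %.3g (rank-deficiency of the centered %d-row matrix)",
      n_components, ev[n_components] / ev[1], nrow(m)))
  rownames(scores) <- AA_ALPHABET20
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(embedding = scores,
                 component_loadings = load,
                 explained_variance = ev,
                 center = pr$center,
                 normalization_params = cim$normalization_params,
                 column_ids = cim$column_ids),
            class = "aa_feature_table")
}

#' @export
print.aa_feature_table <- function(x, ...) {
  cat("Amino-acid feature table:", nrow(x$embedding), "residues x",
      ncol(x$embedding), "components (from", length(x$column_ids), "indices)\n")
  invisible(x)
}

#' Build the embedding table from an AAindex1 file in one call
#'
#' Convenience pipeline: [parse_aaindex()] -> [drop_missing()] ->
#' [robust_normalize()] -> [fit_pca_embedding()].
#'
#' @inheritParams parse_aaindex
#' @inheritParams fit_pca_embedding
#' @return An `aa_feature_table`.
#' @export
build_embedding <- function(x, n_components = 20) {
  fit_pca_embedding(robust_normalize(drop_missing(parse_aaindex(x))),
                    n_components = n_components)
}

#' Look up the embedding vector of one residue
#'
#' Standard residues return their embedding row; the degenerate one-letter
#' codes B, J, O, U, X, Z return a zero vector flagged via the
#' `"nonstandard"` attribute, so datasets containing rare codes degrade
#' gracefully instead of erroring.  Lowercase input is upper-cased.
#'
#' @param residue Single one-letter amino-acid code.
#' @param table An `aa_feature_table`.
#' @return Numeric vector of length `ncol(table$embedding)`; attribute
#'   `nonstandard` is `TRUE` for the zero-vector codes.
#' @export
embed_residue <- function(residue, table) {
  stopifnot(inherits(table, "aa_feature_table"))
  if (!is.character(residue) || length(residue) != 1 || nchar(residue) != 1)
    stop("embed_residue: expected a single one-letter code")
  r <- toupper(residue)
  if (!grepl("^[A-Z]$", r))
    stop("embed_residue: '", residue, "' is not a letter")
  if (r %in% AA_ALPHABET20) {
    v <- table$embedding[r, ]
    attr(v, "nonstandard") <- FALSE
    return(v)
  }
  if (r %in% NONSTANDARD_AA) {
    v <- numeric(ncol(table$embedding))
    names(v) <- colnames(table$embedding)
    attr(v, "nonstandard") <- TRUE
    return(v)
  }
  stop("embed_residue: unknown residue code '", residue, "'")
}

#' Write / read an embedding table as plain text
#'
#' The embedding is stored as a TSV (residue + component columns) with a
#' JSON sidecar holding the index accessions, explained variances,
#' normalization parameters, PCA column means and loadings.
#'
#' @param table An `aa_feature_table`.
#' @param dir Directory to write into (created if needed).
#' @return `write_embedding_table` returns `dir` invisibly;
#'   `read_embedding_table` returns the restored `aa_feature_table`.
#' @export
write_embedding_table <- function(table, dir) {
  stopifnot(inherits(table, "aa_feature_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- data.frame(residue = rownames(table$embedding), table$embedding,
                    check.names = FALSE)
  write.table(emb, file.path(dir, "embedding.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(column_ids = table$column_ids,
               explained_variance = table$explained_variance,
               center = as.numeric(table$center),
               normalization_params = as.list(table$normalization_params),
               component_loadings = unname(apply(table$component_loadings, 2,
                                                 as.numeric, simplify = FALSE)))
  jsonlite::write_json(meta, file.path(dir, "embedding_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(dir) {
  emb <- read.delim(file.path(dir, "embedding.tsv"), check.names = FALSE)
  m <- as.matrix(emb[, -1, drop = FALSE])
  rownames(m) <- emb$residue
  meta <- jsonlite::read_json(file.path(dir, "embedding_meta.json"),
                              simplifyVector = FALSE)
  ids <- unlist(meta$column_ids)
  load <- do.call(cbind, lapply(meta$component_loadings, unlist))
  rownames(load) <- ids
  colnames(load) <- colnames(m)
  np <- as.data.frame(lapply(meta$normalization_params, unlist),
                      stringsAsFactors = FALSE)
  structure(list(embedding = m,
                 component_loadings = load,
                 explained_variance = unlist(meta$explained_variance),
                 center = setNames(unlist(meta$center), ids),
                 normalization_params = np,
                 column_ids = ids),
            class = "aa_feature_table")
}
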