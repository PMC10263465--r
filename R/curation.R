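# Curation of T-cell assay records into a labeled training set, following
# the evidence rules used for class I epitope data: restrict to human class
# I cytokine-release/cytotoxicity assays, require 4-digit HLA typing and
# explicit experiment counts, demand at least four all-negative experiments
# for a negative instance and at least one responding subject for a
# positive one, then collapse redundant peptide-HLA instances.  Also
# provides alignment-based similarity search against a peptide database.

#' Curation policy
#'
#' @param min_negative_experiments Minimum number of (all-negative)
#'   experiments required to keep a negative record.  The default 4 reads
#'   the evidence rule as "at least four"; set 5 for the strict
#'   "more than four" reading.
#' @param min_positive_responders Minimum responding subjects for a
#'   positive record (default 1).
#' @param conflict How to resolve duplicated peptide-allele instances with
#'   discordant labels: `"discard"` both (default), `"majority"` vote
#'   (ties discarded), or `"positive"` wins.
#' @param require_human Keep only human-host records.
#' @param require_class_i Keep only MHC class I records.
#' @param allowed_assay_classes Assay classes retained (case-insensitive).
#' @return A `curation_policy` list.
#' @export
curation_policy <- function(min_negative_experiments = 4,
                            min_positive_responders = 1,
                            conflict = c("discard", "majority", "positive"),
                            require_human = TRUE,
                            require_class_i = TRUE,
                            allowed_assay_classes = c("cytokine release",
                                                      "cytotoxicity")) {
  conflict <- match.arg(conflict)
  stopifnot(min_negative_experiments >= 0, min_positive_responders >= 0)
  structure(list(min_negative_experiments = min_negative_experiments,
                 min_positive_responders = min_positive_responders,
                 conflict = conflict,
                 require_human = require_human,
                 require_class_i = require_class_i,
                 allowed_assay_classes = tolower(allowed_assay_classes)),
            class = "curation_policy")
}

ASSAY_COLUMNS <- c("peptide", "allele", "assay_class", "qualitative_outcome",
                   "n_experiments", "n_subjects_tested",
                   "n_subjects_responded", "host", "mhc_class")

#' Read a TSV of T-cell assay records
#'
#' @param path TSV file path.
#' @param column_map Optional named character vector mapping the canonical
#'   column names (see Details) to the file's column names, so real export
#'   dialects can be adapted without rewriting files.
#' @details Canonical columns: `peptide`, `allele`, `assay_class`,
#'   `qualitative_outcome` (`positive`/`negative`), `n_experiments`,
#'   `n_subjects_tested`, `n_subjects_responded`, `host`, `mhc_class`.
#' @return Data frame with the canonical columns.
#' @export
read_assay_records <- function(path, column_map = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop("read_assay_records: mapped column '", src, "' absent")
      df[[canon]] <- df[[src]]
    }
  }
  missing_cols <- setdiff(ASSAY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("read_assay_records: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in c("n_experiments", "n_subjects_tested", "n_subjects_responded"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df[ASSAY_COLUMNS]
}

is_human <- function(host) grepl("homo sapiens|human", tolower(host))
is_class_i <- function(x) {
  x <- toupper(trimws(x))
  x %in% c("I", "1", "CLASS I", "MHC I", "HLA-I", "HLA I")
}

#' Filter assay records into a curated training dataset
#'
#' Pipeline (each step logs its drop count):
#' scope (host / MHC class / assay class per policy); reject malformed
#' rows; drop alleles below 4-digit resolution; drop records missing the
#' count field their label requires; keep negatives only with
#' `n_experiments >= min_negative_experiments`; keep positives only with
#' `n_subjects_responded >= min_positive_responders`; collapse duplicate
#' peptide-allele instances (concordant to one; discordant per the
#' conflict policy).
#'
#' @param records Data frame of assay records (see [read_assay_records()]).
#' @param policy A [curation_policy()].
#' @param verbose Emit per-step drop counts via `message()`.
#' @return A `curated_dataset`: list with `instances` (data frame:
#'   `peptide`, `allele` canonical, `label` 0/1, `provenance`
#'   semicolon-joined source row ids), `drop_counts` (named integer),
#'   `rejects` (malformed rows with a `reject_reason`), and `policy`.
#'   Conservation holds: kept source records + dropped + rejected =
#'   input records.
#' @export
filter_records <- function(records, policy = curation_policy(),
                           verbose = FALSE) {
  stopifnot(inherits(policy, "curation_policy"))
  records <- as.data.frame(records)
  missing_cols <- setdiff(ASSAY_COLUMNS, names(records))
  if (length(missing_cols))
    stop("filter_records: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n_in <- nrow(records)
  records$.row_id <- seq_len(nrow(records))
  drops <- c(scope = 0L, allele_resolution = 0L,
             missing_counts = 0L, negative_evidence = 0L,
             positive_evidence = 0L, duplicate_collapsed = 0L,
             conflict_discarded = 0L)
  note <- function(step, n) {
    drops[[step]] <<- drops[[step]] + as.integer(n)
    if (verbose) message("filter_records: ", step, " dropped ", n)
  }

  # scope filters (the query-level restrictions of the evidence source)
  keep <- rep(TRUE, nrow(records))
  if (policy$require_human) keep <- keep & is_human(records$host)
  if (policy$require_class_i) keep <- keep & is_class_i(records$mhc_class)
  keep <- keep & tolower(trimws(records$assay_class)) %in%
    policy$allowed_assay_classes
  note("scope", sum(!keep))
  records <- records[keep, , drop = FALSE]

  # malformed rows -> reject report
  outcome <- tolower(trimws(records$qualitative_outcome))
  bad_pep <- !grepl("^[A-Za-z]+$", records$peptide)
  bad_out <- !outcome %in% c("positive", "negative")
  bad_cnt <- (!is.na(records$n_experiments) & records$n_experiments < 0) |
    (!is.na(records$n_subjects_responded) & records$n_subjects_responded < 0)
  bad <- bad_pep | bad_out | bad_cnt
  rejects <- records[bad, , drop = FALSE]
  if (nrow(rejects))
    rejects$reject_reason <- ifelse(bad_pep[bad], "invalid peptide",
                             ifelse(bad_out[bad], "invalid outcome",
                                    "negative count"))
  if (verbose) message("filter_records: rejected ", sum(bad),
                       " malformed row(s)")
  records <- records[!bad, , drop = FALSE]
  outcome <- outcome[!bad]

  # 4-digit allele resolution
  canon <- vapply(records$allele, function(a)
    tryCatch(normalize_allele(a), error = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  note("allele_resolution", sum(is.na(canon)))
  records <- records[!is.na(canon), , drop = FALSE]
  outcome <- outcome[!is.na(canon)]
  records$allele_canonical <- canon[!is.na(canon)]

  # explicit experimental information required by the label
  has_info <- ifelse(outcome == "negative",
                     !is.na(records$n_experiments),
                     !is.na(records$n_subjects_responded))
  note("missing_counts", sum(!has_info))
  records <- records[has_info, , drop = FALSE]
  outcome <- outcome[has_info]

  # evidence thresholds
  neg_ok <- outcome != "negative" |
    records$n_experiments >= policy$min_negative_experiments
  note("negative_evidence", sum(!neg_ok))
  records <- records[neg_ok, , drop = FALSE]
  outcome <- outcome[neg_ok]

  pos_ok <- outcome != "positive" |
    records$n_subjects_responded >= policy$min_positive_responders
  note("positive_evidence", sum(!pos_ok))
  records <- records[pos_ok, , drop = FALSE]
  outcome <- outcome[pos_ok]

  # collapse redundant peptide-HLA instances
  records$label <- as.integer(outcome == "positive")
  records$peptide <- toupper(records$peptide)
  key <- paste(records$peptide, records$allele_canonical, sep = "|")
  inst <- list()
  for (kk in unique(key)) {
    grp <- records[key == kk, , drop = FALSE]
    labs <- unique(grp$label)
    lab <- NA_integer_
    if (length(labs) == 1) {
      lab <- labs
      drops[["duplicate_collapsed"]] <- drops[["duplicate_collapsed"]] +
        nrow(grp) - 1L
    } else {
      if (policy$conflict == "discard") {
        note("conflict_discarded", nrow(grp))
      } else if (policy$conflict == "positive") {
        lab <- 1L
        drops[["duplicate_collapsed"]] <- drops[["duplicate_collapsed"]] +
          nrow(grp) - 1L
      } else {  # majority
        tab <- table(grp$label)
        if (length(tab) == 2 && tab[["0"]] == tab[["1"]]) {
          note("conflict_discarded", nrow(grp))
        } else {
          lab <- as.integer(names(which.max(tab)))
          drops[["duplicate_collapsed"]] <- drops[["duplicate_collapsed"]] +
            nrow(grp) - 1L
        }
      }
    }
    if (!is.na(lab))
      inst[[length(inst) + 1L]] <- data.frame(
        peptide = grp$peptide[1], allele = grp$allele_canonical[1],
        label = lab, provenance = paste(grp$.row_id, collapse = ";"),
        stringsAsFactors = FALSE)
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(peptide = character(0), allele = character(0),
               label = integer(0), provenance = character(0))
  stopifnot(nrow(instances) + sum(drops) + nrow(rejects) == n_in)
  structure(list(instances = instances, drop_counts = drops,
                 rejects = rejects, policy = policy),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated dataset:", nrow(x$instances), "instances (",
      sum(x$instances$label == 1), "positive /",
      sum(x$instances$label == 0), "negative );",
      sum(x$drop_counts), "records dropped,", nrow(x$rejects), "rejected\n")
  invisible(x)
}

#' @export
as.data.frame.curated_dataset <- function(x, ...) x$instances

#' Write / read a curated dataset TSV (peptide, allele, label)
#' @param dataset A `curated_dataset` or a data frame with those columns.
#' @param path File path.
#' @return `write_curated_dataset` returns `path` invisibly;
#'   `read_curated_dataset` a data frame.
#' @export
write_curated_dataset <- function(dataset, path) {
  df <- if (inherits(dataset, "curated_dataset")) dataset$instances else
    as.data.frame(dataset)
  write.table(df[, c("peptide", "allele", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curated_dataset
#' @export
read_curated_dataset <- function(path) read.delim(path,
                                                  stringsAsFactors = FALSE)

#' Similarity search against a peptide database
#'
#' Global (Needleman-Wunsch) alignment of the query against every database
#' peptide with BLOSUM62, gap open 11 / extend 1.  The reported similarity
#' is the self-normalized score `S(q,d) / sqrt(S(q,q) * S(d,d))`, so any
#' sequence matches itself at exactly 1.
#'
#' @param query Query peptide (standard residues only).
#' @param database Character vector of peptides, or a data frame with a
#'   `peptide` column plus metadata columns carried into the result.
#' @param top_n Number of hits to return (default 10).
#' @return Data frame ranked by descending similarity (ties keep database
#'   order): `rank`, `peptide`, `similarity`, plus any metadata columns.
#' @export
similarity_search <- function(query, database, top_n = 10) {
  meta <- NULL
  if (is.data.frame(database)) {
    stopifnot("peptide" %in% names(database))
    meta <- database[setdiff(names(database), "peptide")]
    database <- database$peptide
  }
  if (length(database) == 0) stop("similarity_search: empty database")
  query <- toupper(query)
  database <- toupper(database)
  aa_ok <- function(x) grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""),
                                    "]+$"), x)
  if (!aa_ok(query)) stop("similarity_search: invalid residues in query")
  if (!all(aa_ok(database)))
    stop("similarity_search: invalid residues in database entries ",
         paste(which(!aa_ok(database)), collapse = ", "))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  align_score <- function(patterns, subject)
    Biostrings::score(Biostrings::pairwiseAlignment(
      patterns, subject, type = "global", substitutionMatrix = B62,
      gapOpening = 11, gapExtension = 1))
  B62d <- setNames(diag(B62), rownames(B62))
  self_score <- function(seqs)
    vapply(seqs, function(s) sum(B62d[strsplit(s, "")[[1]]]),
           numeric(1), USE.NAMES = FALSE)
  sqq <- self_score(query)
  sdd <- self_score(database)
  sqd <- align_score(database, query)
  sim <- sqd / sqrt(sqq * sdd)
  ord <- order(-sim)  # stable: ties keep database order
  keep <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(rank = seq_along(keep), peptide = database[keep],
                    similarity = sim[keep], stringsAsFactors = FALSE)
  if (!is.null(meta) && ncol(meta)) out <- cbind(out, meta[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}
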