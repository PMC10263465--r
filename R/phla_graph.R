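# Peptide-HLA graph construction.
#
# A peptide-HLA instance becomes a fully connected directed graph: one node
# per peptide residue (N- to C-terminal), one per position of the allele's
# 34-residue pseudo-sequence (the peptide-contacting HLA positions), plus a
# virtual readout node connected to everything.  Node features concatenate
# the 20-dim PCA residue embedding, a 3-way node-type one-hot
# (peptide/HLA/virtual) and, for peptide nodes, absolute-position one-hots
# counted from both termini, so attention can key on the anchor positions
# (P2 and the C-terminus) that dominate class I binding motifs.
# Pseudo-sequence nodes carry no positional channel: the pseudo-sequence
# is a fixed-length allele fingerprint, constant per allele.

PHLA_TYPE_DIM <- 3L
PHLA_MAX_PEP <- 14L                      # longest supported peptide
PHLA_POS_DIM <- 2L * PHLA_MAX_PEP        # forward + reverse one-hots
PSEUDO_LEN <- 34L

#' Normalize an HLA class I allele name
#'
#' Accepts the common spellings of a 4-digit class I allele
#' (`"A0201"`, `"A*02:01"`, `"HLA-A*0201"`, `"HLA-A*02:01"`, ...) and maps
#' them to the canonical `"HLA-A*02:01"` form.  Alleles given at less than
#' 4-digit resolution (e.g. `"HLA-A2"`) are rejected: serology-level names
#' do not identify a pseudo-sequence.
#'
#' @param name Character vector of allele names.
#' @return Character vector of canonical names.
#' @examples
#' normalize_allele(c("A0201", "HLA-B*5701"))
#' @export
normalize_allele <- function(name) {
  if (!is.character(name) || length(name) == 0 || any(is.na(name)) ||
      any(!nzchar(trimws(name))))
    stop("normalize_allele: empty or missing allele name")
  vapply(name, function(nm) {
    x <- toupper(trimws(nm))
    x <- sub("^HLA[-_ ]?", "", x)
    if (grepl("*", x, fixed = TRUE)) {
      parts <- strsplit(x, "*", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !grepl("^[A-Z][A-Z0-9]*$", parts[1]) ||
          !grepl("^[0-9:]+$", parts[2]))
        stop("normalize_allele: cannot parse allele name '", nm, "'")
      gene <- parts[1]
      digits <- parts[2]
    } else {
      mm <- regmatches(x, regexec("^([A-Z]+)([0-9:]+)$", x))[[1]]
      if (length(mm) != 3)
        stop("normalize_allele: cannot parse allele name '", nm, "'")
      gene <- mm[2]
      digits <- mm[3]
    }
    if (grepl(":", digits, fixed = TRUE)) {
      fields <- strsplit(digits, ":", fixed = TRUE)[[1]]
      if (length(fields) < 2 || !all(grepl("^[0-9]{1,3}$", fields[1:2])))
        stop("normalize_allele: cannot parse allele name '", nm, "'")
      g1 <- fields[1]; g2 <- fields[2]
    } else {
      if (!grepl("^[0-9]+$", digits) || nchar(digits) < 4)
        stop("normalize_allele: allele '", nm,
             "' lacks 4-digit resolution")
      if (nchar(digits) == 4) {
        g1 <- substr(digits, 1, 2); g2 <- substr(digits, 3, 4)
      } else if (nchar(digits) == 5) {
        # three-digit allele group followed by two-digit protein
        g1 <- substr(digits, 1, 3); g2 <- substr(digits, 4, 5)
      } else
        stop("normalize_allele: ambiguous digit run in '", nm, "'")
    }
    if (nchar(g1) < 2 || nchar(g2) < 2 || as.integer(g2) == 0 && g2 == "0")
      stop("normalize_allele: allele '", nm, "' lacks 4-digit resolution")
    sprintf("HLA-%s*%s:%s", gene,
            formatC(as.integer(g1), width = max(2, nchar(g1)), flag = "0"),
            formatC(as.integer(g2), width = max(2, nchar(g2)), flag = "0"))
  }, character(1), USE.NAMES = FALSE)
}

#' Read an HLA pseudo-sequence table
#'
#' TSV with two columns (allele, 34-mer pseudo-sequence); `#` starts a
#' comment.  Allele names are normalized to canonical form.
#'
#' @param path File path.
#' @return A `pseudo_sequence_table`: named character vector, names are
#'   canonical alleles, values are 34-character residue strings.
#' @export
read_pseudo_table <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_pseudo_table: expected two TSV columns")
  as_pseudo_table(setNames(toupper(trimws(df[[2]])), df[[1]]))
}

#' Construct a pseudo-sequence table from a named character vector
#' @param x Named character vector (allele -> 34-mer).
#' @return A `pseudo_sequence_table`.
#' @export
as_pseudo_table <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  names(x) <- normalize_allele(names(x))
  if (anyDuplicated(names(x)))
    stop("as_pseudo_table: duplicated allele(s) after normalization")
  bad <- nchar(x) != PSEUDO_LEN | !grepl("^[A-Z]+$", x)
  if (any(bad))
    stop("as_pseudo_table: pseudo-sequences must be 34 residue letters; bad: ",
         paste(names(x)[bad], collapse = ", "))
  structure(x, class = "pseudo_sequence_table")
}

#' Look up the 34-mer pseudo-sequence of an allele
#'
#' @param allele Allele name in any accepted spelling.
#' @param table A `pseudo_sequence_table`.
#' @return The 34-character pseudo-sequence.
#' @export
lookup_pseudo_sequence <- function(allele, table) {
  stopifnot(inherits(table, "pseudo_sequence_table"))
  key <- normalize_allele(allele)
  if (!key %in% names(table)) {
    near <- names(table)[order(adist(key, names(table)))]
    stop("lookup_pseudo_sequence: allele '", key, "' not in table; nearest: ",
         paste(head(near, 3), collapse = ", "))
  }
  unname(table[[key]])
}

# Positional block for the peptide chain: one-hot of the 1-based forward
# position and of the reverse position (1 = C-terminal residue), both
# capped at the maximum peptide length.
position_features <- function(chain_len) {
  fwd <- pmin(seq_len(chain_len), PHLA_MAX_PEP)
  rev <- pmin(chain_len - seq_len(chain_len) + 1, PHLA_MAX_PEP)
  m <- matrix(0, chain_len, PHLA_POS_DIM)
  m[cbind(seq_len(chain_len), fwd)] <- 1
  m[cbind(seq_len(chain_len), PHLA_MAX_PEP + rev)] <- 1
  m
}

#' Number of node-feature columns implied by an embedding table
#' @param emb An `aa_feature_table`.
#' @return Integer feature width (embedding dims + type one-hot + positional).
#' @export
phla_feature_width <- function(emb) {
  ncol(emb$embedding) + PHLA_TYPE_DIM + PHLA_POS_DIM
}

#' Build the fully connected peptide-HLA graph
#'
#' Nodes: peptide residues N- to C-terminal, then pseudo-sequence positions
#' 1-34, then one virtual readout node.  Edges: every ordered pair of
#' distinct nodes (no self-loops), so a graph with `N + 1` nodes has
#' `(N + 1) * N` directed edges.  The virtual node's embedding block is all
#' zero; its type one-hot identifies it.
#'
#' @param peptide Peptide string (length within `length_range`).
#' @param allele Allele name (any accepted spelling).
#' @param table A `pseudo_sequence_table`.
#' @param emb An `aa_feature_table`.
#' @param length_range Allowed peptide lengths, default `c(8, 14)`.
#' @return A `phla_graph`: list with `node_features`
#'   ((N+1) x width matrix), `node_types`, `edges` (2-column integer
#'   matrix of ordered pairs), `peptide_length`, `allele`, `peptide`.
#' @examples
#' \dontrun{
#' g <- build_phla_graph("SIINFEKLM", "HLA-A*02:01", ptab, emb)
#' nrow(g$node_features)  # 9 + 34 + 1 = 44
#' }
#' @export
build_phla_graph <- function(peptide, allele, table, emb,
                             length_range = c(8, 14)) {
  stopifnot(inherits(emb, "aa_feature_table"))
  pep <- toupper(peptide)
  if (!grepl("^[A-Z]+$", pep))
    stop("build_phla_graph: invalid character in peptide '", peptide, "'")
  L <- nchar(pep)
  if (L < length_range[1] || L > length_range[2])
    stop("build_phla_graph: peptide length ", L, " outside [",
         length_range[1], ", ", length_range[2], "]")
  pseudo <- lookup_pseudo_sequence(allele, table)
  d_emb <- ncol(emb$embedding)
  n_nodes <- L + PSEUDO_LEN + 1L

  feat <- matrix(0, n_nodes, d_emb + PHLA_TYPE_DIM + PHLA_POS_DIM)
  pep_res <- strsplit(pep, "", fixed = TRUE)[[1]]
  hla_res <- strsplit(pseudo, "", fixed = TRUE)[[1]]
  for (i in seq_len(L))
    feat[i, seq_len(d_emb)] <- embed_residue(pep_res[i], emb)
  for (i in seq_len(PSEUDO_LEN))
    feat[L + i, seq_len(d_emb)] <- embed_residue(hla_res[i], emb)
  # type one-hot
  feat[seq_len(L), d_emb + 1L] <- 1
  feat[L + seq_len(PSEUDO_LEN), d_emb + 2L] <- 1
  feat[n_nodes, d_emb + 3L] <- 1
  # positional block: peptide nodes only (HLA and virtual stay zero)
  pos_cols <- d_emb + PHLA_TYPE_DIM + seq_len(PHLA_POS_DIM)
  feat[seq_len(L), pos_cols] <- position_features(L)

  from <- rep(seq_len(n_nodes), each = n_nodes)
  to <- rep(seq_len(n_nodes), times = n_nodes)
  keep <- from != to
  edges <- cbind(from = from[keep], to = to[keep])

  structure(list(node_features = feat,
                 node_types = c(rep("peptide", L),
                                rep("hla", PSEUDO_LEN), "virtual"),
                 edges = edges,
                 peptide_length = L,
                 allele = normalize_allele(allele),
                 peptide = pep),
            class = "phla_graph")
}

#' @export
print.phla_graph <- function(x, ...) {
  cat("pHLA graph:", x$peptide, "x", x$allele, "-",
      nrow(x$node_features), "nodes,", nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Serialize / restore a pHLA graph as JSON (debug aid)
#' @param graph A `phla_graph`.
#' @param path Output / input file path.
#' @return `graph_to_json` returns `path` invisibly; `graph_from_json`
#'   the restored `phla_graph`.
#' @export
graph_to_json <- function(graph, path) {
  stopifnot(inherits(graph, "phla_graph"))
  jsonlite::write_json(
    list(node_features = unname(apply(graph$node_features, 1, as.numeric,
                                      simplify = FALSE)),
         node_types = graph$node_types,
         edges = unname(apply(graph$edges, 1, as.integer, simplify = FALSE)),
         peptide_length = graph$peptide_length,
         allele = graph$allele,
         peptide = graph$peptide),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname graph_to_json
#' @export
graph_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  feat <- do.call(rbind, lapply(o$node_features, unlist))
  edges <- do.call(rbind, lapply(o$edges, function(e) as.integer(unlist(e))))
  colnames(edges) <- c("from", "to")
  structure(list(node_features = feat, node_types = unlist(o$node_types),
                 edges = edges, peptide_length = as.integer(o$peptide_length),
                 allele = o$allele, peptide = o$peptide),
            class = "phla_graph")
}
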