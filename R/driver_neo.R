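# The driver-mutation neoantigen cascade: enumerate mutant/wild-type
# peptide windows around a missense change, query a pluggable predictor
# suite for binding, stability, processing and immunogenicity, and apply
# the multi-feature filter (mutant binding %Rank, differential
# agretopicity index, stability and processing %Ranks, and a consensus
# vote over immunogenicity tools).

#' Apply a missense mutation to a protein sequence
#'
#' @param seq Protein sequence (one-letter codes).
#' @param position 1-based residue position.
#' @param ref_aa Expected reference residue at `position`.
#' @param alt_aa Substituted residue.
#' @return The mutant sequence, differing from `seq` only at `position`.
#' @examples
#' mutate_protein("ACDEFGHIK", 5, "F", "L")  # "ACDELGHIK"
#' @export
mutate_protein <- function(seq, position, ref_aa, alt_aa) {
  seq <- toupper(seq)
  stopifnot(length(seq) == 1, nchar(ref_aa) == 1, nchar(alt_aa) == 1)
  if (position < 1 || position > nchar(seq))
    stop("mutate_protein: position ", position, " out of range 1..",
         nchar(seq))
  obs <- substr(seq, position, position)
  if (obs != toupper(ref_aa))
    stop("mutate_protein: reference mismatch at position ", position,
         ": expected ", toupper(ref_aa), " but sequence has ", obs)
  if (toupper(ref_aa) == toupper(alt_aa))
    stop("mutate_protein: ref and alt residues are identical")
  mt <- seq
  substr(mt, position, position) <- toupper(alt_aa)
  mt
}

#' Enumerate mutant/wild-type peptide windows around a mutation
#'
#' For every length in `lengths`, every window that contains the mutated
#' position and lies fully inside the protein yields one mutant/wild-type
#' peptide pair.  An interior mutation with at least 13 residues on both
#' flanks yields 8 + 9 + ... + 14 = 77 pairs; a terminal mutation yields
#' one pair per length.
#'
#' @param wt_seq,mt_seq Equal-length protein sequences differing only at
#'   `position`.
#' @param position 1-based mutated position.
#' @param lengths Window lengths (default 8:14).
#' @return Data frame ordered by (length, start): `length`, `start`,
#'   `offset_of_mutation` (1-based within the peptide), `wt_peptide`,
#'   `mt_peptide`.  Duplicate (mt, wt) pairs are removed (first kept).
#' @export
extract_peptide_pairs <- function(wt_seq, mt_seq, position, lengths = 8:14) {
  wt_seq <- toupper(wt_seq); mt_seq <- toupper(mt_seq)
  n <- nchar(wt_seq)
  if (nchar(mt_seq) != n)
    stop("extract_peptide_pairs: sequences differ in length")
  diffs <- which(strsplit(wt_seq, "")[[1]] != strsplit(mt_seq, "")[[1]])
  if (!identical(diffs, as.integer(position)) &&
      !identical(diffs, position))
    stop("extract_peptide_pairs: sequences must differ exactly at position ",
         position)
  rows <- list()
  for (L in sort(lengths)) {
    if (L > n) next
    for (s in max(1L, position - L + 1L):min(position, n - L + 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, start = s, offset_of_mutation = position - s + 1L,
        wt_peptide = substr(wt_seq, s, s + L - 1L),
        mt_peptide = substr(mt_seq, s, s + L - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(length = integer(0), start = integer(0),
                      offset_of_mutation = integer(0),
                      wt_peptide = character(0), mt_peptide = character(0)))
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("mt_peptide", "wt_peptide")]), , drop = FALSE]
}

#' Differential agretopicity index
#'
#' DAI = IC50 of the wild-type peptide divided by IC50 of the mutant
#' peptide; values above 1 mean the mutation improves HLA binding.
#'
#' @param ic50_wt,ic50_mt Positive IC50 values in nM (vectorized).
#' @return `ic50_wt / ic50_mt`.
#' @export
compute_dai <- function(ic50_wt, ic50_mt) {
  if (any(ic50_wt <= 0) || any(ic50_mt <= 0))
    stop("compute_dai: IC50 values must be positive")
  ic50_wt / ic50_mt
}

#' Filter thresholds for the neoantigen cascade
#'
#' Defaults mirror the published screen: mutant binding %Rank < 2,
#' DAI > 1 (strict), stability %Rank < 2, processing (cleavage + TAP)
#' combined %Rank < 2, immunogenicity score >= 0.8 for score-type tools and
#' %Rank < 2 for rank-type tools, and a consensus of more than two tools
#' (`min_votes = 3`); `min_votes = 2` selects the laxer reading of
#' "more than two methods".
#'
#' @param binding_rank_max,stability_rank_max,processing_rank_max Strict
#'   upper %Rank bounds.
#' @param dai_min Strict lower DAI bound.
#' @param immuno_score_min Inclusive score threshold for score-type tools.
#' @param prime_rank_max Strict %Rank bound for rank-type tools.
#' @param min_votes Minimum number of voting immunogenicity tools.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(binding_rank_max = 2, dai_min = 1,
                              stability_rank_max = 2,
                              processing_rank_max = 2,
                              immuno_score_min = 0.8, prime_rank_max = 2,
                              min_votes = 3) {
  vals <- c(binding_rank_max, dai_min, stability_rank_max,
            processing_rank_max, immuno_score_min, prime_rank_max, min_votes)
  stopifnot(all(vals > 0))
  structure(list(binding_rank_max = binding_rank_max, dai_min = dai_min,
                 stability_rank_max = stability_rank_max,
                 processing_rank_max = processing_rank_max,
                 immuno_score_min = immuno_score_min,
                 prime_rank_max = prime_rank_max,
                 min_votes = as.integer(min_votes)),
            class = "filter_thresholds")
}

#' Assemble a predictor suite
#'
#' The pluggable contract standing in for external binding / stability /
#' processing / immunogenicity tools.  Adapters wrapping real predictors
#' need only satisfy these signatures.
#'
#' @param binding `function(peptide, allele)` returning
#'   `list(ic50 = <nM>, percent_rank = <0..100>)`.
#' @param stability `function(peptide, allele)` returning a %Rank.
#' @param processing `function(peptide, allele)` returning the combined
#'   (cleavage + TAP) %Rank.
#' @param immunogenicity Named list of `function(peptide, allele)` score
#'   functions, one per tool.
#' @param tool_types Named character vector typing each immunogenicity
#'   tool as `"score"` or `"rank"`; defaults to `"rank"` for tool names
#'   containing `rank` or `prime` (case-insensitive), `"score"` otherwise.
#' @return A `predictor_suite`.
#' @export
predictor_suite <- function(binding, stability, processing, immunogenicity,
                            tool_types = NULL) {
  stopifnot(is.function(binding), is.function(stability),
            is.function(processing), is.list(immunogenicity),
            length(immunogenicity) >= 1,
            !is.null(names(immunogenicity)))
  if (is.null(tool_types))
    tool_types <- setNames(ifelse(
      grepl("rank|prime", names(immunogenicity), ignore.case = TRUE),
      "rank", "score"), names(immunogenicity))
  if (!all(tool_types %in% c("score", "rank")))
    stop("predictor_suite: tool types must be 'score' or 'rank'")
  structure(list(binding = binding, stability = stability,
                 processing = processing, immunogenicity = immunogenicity,
                 tool_types = tool_types),
            class = "predictor_suite")
}

#' Count immunogenicity votes
#'
#' A score-type tool votes when its score is at or above
#' `immuno_score_min` (the 0.8 boundary is inclusive); a rank-type tool
#' votes when its %Rank is strictly below `prime_rank_max`.
#'
#' @param scores Named numeric vector or list, one value per tool.
#' @param thresholds A [filter_thresholds()].
#' @param tool_types Named character vector (`"score"`/`"rank"`); inferred
#'   from tool names as in [predictor_suite()] when `NULL`.
#' @return Integer vote count.
#' @export
vote_immunogenicity <- function(scores, thresholds = filter_thresholds(),
                                tool_types = NULL) {
  scores <- unlist(scores)
  if (length(scores) == 0 || is.null(names(scores)) ||
      any(!nzchar(names(scores))))
    stop("vote_immunogenicity: named per-tool scores required")
  if (is.null(tool_types))
    tool_types <- setNames(ifelse(
      grepl("rank|prime", names(scores), ignore.case = TRUE),
      "rank", "score"), names(scores))
  missing_type <- setdiff(names(scores), names(tool_types))
  if (length(missing_type))
    stop("vote_immunogenicity: unknown tool type for ",
         paste(missing_type, collapse = ", "))
  if (!all(tool_types %in% c("score", "rank")))
    stop("vote_immunogenicity: tool types must be 'score' or 'rank'")
  votes <- vapply(names(scores), function(nm) {
    if (tool_types[[nm]] == "score") scores[[nm]] >= thresholds$immuno_score_min
    else scores[[nm]] < thresholds$prime_rank_max
  }, logical(1))
  sum(votes)
}

#' Screen mutations for candidate neoantigens
#'
#' For every mutation x allele x peptide window, queries the predictor
#' suite and applies the cascade: mutant binding %Rank <
#' `binding_rank_max`, DAI > `dai_min`, stability %Rank <
#' `stability_rank_max`, processing %Rank < `processing_rank_max`, and at
#' least `min_votes` immunogenicity votes.  The final pass flag is the
#' pure conjunction of the per-filter flags, so filter order cannot change
#' the outcome.  The wild-type %Rank is recorded but never filtered on.
#'
#' @param mutations Data frame with columns `gene`, `protein_seq`,
#'   `position`, `ref_aa`, `alt_aa` (one row per missense mutation).
#' @param alleles Character vector of HLA alleles.
#' @param suite A [predictor_suite()].
#' @param thresholds A [filter_thresholds()].
#' @param keep_all Keep failing candidates with all flags recorded
#'   (default FALSE: return passing candidates only).
#' @param lengths Peptide window lengths (default 8:14).
#' @return Data frame of candidates (scores, per-filter flags, `votes`,
#'   `pass`, `errored`); attribute `"summary"` holds per-filter counts.
#' @export
screen_candidates <- function(mutations, alleles, suite,
                              thresholds = filter_thresholds(),
                              keep_all = FALSE, lengths = 8:14) {
  stopifnot(inherits(suite, "predictor_suite"),
            inherits(thresholds, "filter_thresholds"))
  mutations <- as.data.frame(mutations)
  need <- c("gene", "protein_seq", "position", "ref_aa", "alt_aa")
  if (nrow(mutations) == 0)
    return(structure(data.frame(), summary = list(n_candidates = 0L)))
  stopifnot(all(need %in% names(mutations)))
  alleles <- normalize_allele(alleles)
  rows <- list()
  n_err <- 0L
  for (mi in seq_len(nrow(mutations))) {
    mrow <- mutations[mi, ]
    mt_seq <- mutate_protein(mrow$protein_seq, mrow$position, mrow$ref_aa,
                             mrow$alt_aa)
    pairs <- extract_peptide_pairs(mrow$protein_seq, mt_seq, mrow$position,
                                   lengths)
    mutation_id <- sprintf("%s_%s%d%s", mrow$gene, toupper(mrow$ref_aa),
                           mrow$position, toupper(mrow$alt_aa))
    for (al in alleles) {
      for (pi in seq_len(nrow(pairs))) {
        pr <- pairs[pi, ]
        res <- tryCatch({
          b_mt <- suite$binding(pr$mt_peptide, al)
          b_wt <- suite$binding(pr$wt_peptide, al)
          st <- suite$stability(pr$mt_peptide, al)
          pc <- suite$processing(pr$mt_peptide, al)
          im <- vapply(suite$immunogenicity,
                       function(f) f(pr$mt_peptide, al), numeric(1))
          dai <- compute_dai(b_wt$ic50, b_mt$ic50)
          votes <- vote_immunogenicity(im, thresholds, suite$tool_types)
          flags <- c(pass_binding = b_mt$percent_rank <
                       thresholds$binding_rank_max,
                     pass_dai = dai > thresholds$dai_min,
                     pass_stability = st < thresholds$stability_rank_max,
                     pass_processing = pc < thresholds$processing_rank_max,
                     pass_votes = votes >= thresholds$min_votes)
          c(list(mutation = mutation_id, gene = mrow$gene, allele = al),
            pr[c("length", "start", "offset_of_mutation", "wt_peptide",
                 "mt_peptide")],
            list(ic50_mt = b_mt$ic50, ic50_wt = b_wt$ic50,
                 rank_mt = b_mt$percent_rank, rank_wt = b_wt$percent_rank,
                 dai = dai, stability_rank = st, processing_rank = pc),
            as.list(im),
            list(votes = votes),
            as.list(flags),
            list(pass = all(flags), errored = FALSE))
        }, error = function(e) NULL)
        if (is.null(res)) {
          n_err <- n_err + 1L
          res <- c(list(mutation = mutation_id, gene = mrow$gene,
                        allele = al),
                   pr[c("length", "start", "offset_of_mutation",
                        "wt_peptide", "mt_peptide")],
                   list(ic50_mt = NA_real_, ic50_wt = NA_real_,
                        rank_mt = NA_real_, rank_wt = NA_real_,
                        dai = NA_real_, stability_rank = NA_real_,
                        processing_rank = NA_real_),
                   setNames(as.list(rep(NA_real_,
                                        length(suite$immunogenicity))),
                            names(suite$immunogenicity)),
                   list(votes = NA_integer_, pass_binding = FALSE,
                        pass_dai = FALSE, pass_stability = FALSE,
                        pass_processing = FALSE, pass_votes = FALSE,
                        pass = FALSE, errored = TRUE))
        }
        rows[[length(rows) + 1L]] <- as.data.frame(res,
                                                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  smry <- list(n_candidates = nrow(out),
               n_pass_binding = sum(out$pass_binding),
               n_pass_dai = sum(out$pass_dai),
               n_pass_stability = sum(out$pass_stability),
               n_pass_processing = sum(out$pass_processing),
               n_pass_votes = sum(out$pass_votes),
               n_pass = sum(out$pass),
               n_errored = n_err)
  if (!keep_all) out <- out[out$pass & !out$errored, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, summary = smry)
}

#' Allele x peptide matrix of one mutation's candidates
#'
#' @param candidates Output of [screen_candidates()] restricted to a
#'   single mutation.
#' @param value Column to tabulate (default `"rank_mt"`, the mutant
#'   binding %Rank; e.g. `"ic50_mt"`, `"dai"`).
#' @return Numeric matrix, rows = alleles, columns = mutant peptides;
#'   missing combinations are `NA`.
#' @export
heatmap_matrix <- function(candidates, value = "rank_mt") {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0) stop("heatmap_matrix: no candidates")
  if (length(unique(candidates$mutation)) > 1)
    stop("heatmap_matrix: candidates span multiple mutations")
  if (!value %in% names(candidates) || !is.numeric(candidates[[value]]))
    stop("heatmap_matrix: '", value, "' is not a numeric candidate column")
  alleles <- unique(candidates$allele)
  peps <- unique(candidates$mt_peptide)
  m <- matrix(NA_real_, length(alleles), length(peps),
              dimnames = list(alleles, peps))
  for (i in seq_len(nrow(candidates)))
    m[candidates$allele[i], candidates$mt_peptide[i]] <-
      candidates[[value]][i]
  m
}
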