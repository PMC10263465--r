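# Seeded generators for every input the toolkit consumes: pseudo-sequence
# tables, labeled peptide-HLA datasets with a planted anchor-position
# signal, assay-record exports engineered to exercise every curation
# branch, a deterministic toy predictor suite, and missense mutation
# tables.  Every generator is a pure function of its arguments (seed
# included) and leaves the caller's RNG stream untouched.

#' Synthetic study configuration
#'
#' @param seed Master seed fixing all draws.
#' @param n_peptides Number of labeled peptide-HLA instances.
#' @param length_range Peptide length range (default 8-14).
#' @param n_alleles Number of synthetic alleles.
#' @param planted_effect_size Log-odds scale of the planted anchor signal
#'   (default 6, a strong, comfortably learnable effect).
#' @param label_noise SD of Gaussian log-odds noise (default 0.5).
#' @param n_assay_records Number of synthetic assay records (default 50).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_peptides = 2000,
                             length_range = c(8, 14), n_alleles = 6,
                             planted_effect_size = 6, label_noise = 0.5,
                             n_assay_records = 50) {
  stopifnot(n_peptides >= 1, n_alleles >= 1, n_assay_records >= 1,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            planted_effect_size >= 0, label_noise >= 0)
  structure(list(seed = as.integer(seed),
                 n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 n_alleles = as.integer(n_alleles),
                 planted_effect_size = planted_effect_size,
                 label_noise = label_noise,
                 n_assay_records = as.integer(n_assay_records)),
            class = "synthetic_config")
}

random_peptides <- function(n, lengths) {
  vapply(lengths, function(L)
    paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic pseudo-sequence table
#'
#' `n_alleles` canonical class I allele names with random 34-mer
#' pseudo-sequences; a stand-in for the real contact-residue table, which
#' is an input artifact not redistributed here.
#'
#' @param n_alleles Number of alleles (>= 1).
#' @param seed Seed.
#' @return A `pseudo_sequence_table`.
#' @export
gen_pseudo_table <- function(n_alleles, seed = 1) {
  if (n_alleles < 1) stop("gen_pseudo_table: n_alleles must be >= 1")
  with_local_seed(seed, {
    genes <- sample(c("A", "B", "C"), n_alleles, replace = TRUE)
    codes <- sample(99 * 99, n_alleles)  # unique (group, protein) pairs
    names <- sprintf("HLA-%s*%02d:%02d", genes, (codes - 1) %/% 99 + 1,
                     (codes - 1) %% 99 + 1)
    seqs <- random_peptides(n_alleles, rep(34L, n_alleles))
    as_pseudo_table(setNames(seqs, names))
  })
}

#' Generate a labeled peptide-HLA dataset with a planted anchor signal
#'
#' Emulates the anchor-position biology seen in validated neoantigen
#' sequence logos (positions 2 and last are the most conserved): the label
#' probability is `sigmoid(effect * s + allele_offset + noise)` where `s`
#' is a standardized random projection `w . (f(p2) + f(pL))` of the residue
#' embeddings at peptide position 2 and the C-terminal position.  Ground
#' truth (projection, offsets, noiseless log-odds, Bayes scores) is
#' returned for recovery tests.
#'
#' @param cfg A [synthetic_config()].
#' @param emb An `aa_feature_table`.
#' @param pseudo_table A `pseudo_sequence_table`.
#' @return A list of class `synthetic_dataset`: `data` (data frame
#'   `peptide`, `allele`, `label`), `truth` (list: `w`, `allele_offsets`,
#'   `true_logodds`, `bayes_score`), `config`.
#' @export
gen_labeled_dataset <- function(cfg, emb, pseudo_table) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(emb, "aa_feature_table"),
            inherits(pseudo_table, "pseudo_sequence_table"))
  if (cfg$planted_effect_size > 0 && cfg$label_noise == 0)
    warning("gen_labeled_dataset: zero label noise with a planted effect; ",
            "labels are near-deterministic")
  with_local_seed(cfg$seed, {
    n <- cfg$n_peptides
    lens <- sample(cfg$length_range[1]:cfg$length_range[2], n, replace = TRUE)
    peptides <- random_peptides(n, lens)
    alleles <- sample(names(pseudo_table), n, replace = TRUE)
    w <- rnorm(ncol(emb$embedding))
    anchor2 <- substr(peptides, 2, 2)
    anchorL <- substr(peptides, nchar(peptides), nchar(peptides))
    s <- emb$embedding[anchor2, , drop = FALSE] %*% w +
      emb$embedding[anchorL, , drop = FALSE] %*% w
    s <- as.numeric(scale(s))
    offsets <- setNames(rnorm(length(pseudo_table), 0, 0.25),
                        names(pseudo_table))
    logodds <- cfg$planted_effect_size * s + offsets[alleles]
    noise <- rnorm(n, 0, cfg$label_noise)
    labels <- rbinom(n, 1, plogis(logodds + noise))
    structure(list(data = data.frame(peptide = peptides, allele = alleles,
                                     label = labels,
                                     stringsAsFactors = FALSE),
                   truth = list(w = w, allele_offsets = offsets,
                                true_logodds = as.numeric(logodds),
                                bayes_score = plogis(as.numeric(logodds))),
                   config = cfg),
              class = "synthetic_dataset")
  })
}

#' Generate assay records exercising every curation branch
#'
#' A deterministic skeleton guarantees coverage of each filtering rule:
#' serology-level alleles, missing count fields, negatives with 3/4/5
#' experiments, positives with 0/1 responding subjects, concordant and
#' discordant duplicates, non-human hosts, class II records and
#' off-scope assay classes.  Because each record's fate under the default
#' policy is fixed by construction, the generator also emits the expected
#' survivor list as an independent oracle.
#'
#' @param cfg A [synthetic_config()] (`n_assay_records` >= 24).
#' @return List: `records` (assay data frame), `expected` (data frame
#'   `peptide`, `allele`, `label` surviving the default
#'   [curation_policy()]), `coverage` (TRUE).
#' @export
gen_assay_records <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_assay_records
  if (n < 24) stop("gen_assay_records: need at least 24 records for coverage")
  with_local_seed(cfg$seed + 7L, {
    mk <- function(peptide, allele, outcome, n_exp = NA, n_resp = NA,
                   host = "Homo sapiens", mhc = "I",
                   assay = "cytokine release")
      data.frame(peptide = peptide, allele = allele, assay_class = assay,
                 qualitative_outcome = outcome, n_experiments = n_exp,
                 n_subjects_tested = if (is.na(n_resp)) NA else n_resp + 2,
                 n_subjects_responded = n_resp, host = host,
                 mhc_class = mhc, stringsAsFactors = FALSE)
    alle <- function(i) sprintf("HLA-A*02:%02d", i)
    fixed <- list(
      # scope drops
      mk("AAPEPTIDEK", alle(1), "positive", n_resp = 2, host = "Mus musculus"),
      mk("ACPEPTIDEK", alle(1), "positive", n_resp = 2, mhc = "II"),
      mk("ADPEPTIDEK", alle(1), "positive", n_resp = 2, assay = "B cell"),
      # allele resolution drop
      mk("AEPEPTIDEK", "HLA-A2", "positive", n_resp = 2),
      # missing required counts
      mk("AFPEPTIDEK", alle(2), "negative", n_exp = NA),
      mk("AGPEPTIDEK", alle(2), "positive", n_resp = NA),
      # negative evidence boundary: 3 drops, 4 and 5 survive
      mk("AHPEPTIDEK", alle(3), "negative", n_exp = 3),
      mk("AIPEPTIDEK", alle(3), "negative", n_exp = 4),
      mk("AKPEPTIDEK", alle(3), "negative", n_exp = 5),
      # positive evidence boundary: 0 drops, 1 survives
      mk("ALPEPTIDEK", alle(4), "positive", n_resp = 0),
      mk("AMPEPTIDEK", alle(4), "positive", n_resp = 1),
      # concordant duplicate -> one instance
      mk("ANPEPTIDEK", alle(5), "positive", n_resp = 2),
      mk("ANPEPTIDEK", alle(5), "positive", n_resp = 3),
      # discordant duplicate -> both discarded under default policy
      mk("APPEPTIDEK", alle(6), "positive", n_resp = 2),
      mk("APPEPTIDEK", alle(6), "negative", n_exp = 6),
      # malformed rows -> reject report
      mk("AQ PEPT!", alle(7), "positive", n_resp = 2),
      mk("ARPEPTIDEK", alle(7), "maybe", n_resp = 2))
    records <- do.call(rbind, fixed)
    expected <- data.frame(
      peptide = c("AIPEPTIDEK", "AKPEPTIDEK", "AMPEPTIDEK", "ANPEPTIDEK"),
      allele = c("HLA-A*02:03", "HLA-A*02:03", "HLA-A*02:04", "HLA-A*02:05"),
      label = c(0L, 0L, 1L, 1L), stringsAsFactors = FALSE)
    # filler: clean records with known fates (alternating labels)
    n_fill <- n - nrow(records)
    if (n_fill > 0) {
      peps <- random_peptides(n_fill, sample(9:11, n_fill, replace = TRUE))
      for (i in seq_len(n_fill)) {
        al <- sprintf("HLA-B*%02d:%02d", 7 + (i %% 5), 1 + (i %% 9))
        if (i %% 2 == 0) {
          records <- rbind(records, mk(peps[i], al, "positive", n_resp = 1))
          expected <- rbind(expected,
                            data.frame(peptide = peps[i],
                                       allele = normalize_allele(al),
                                       label = 1L))
        } else {
          records <- rbind(records, mk(peps[i], al, "negative", n_exp = 5))
          expected <- rbind(expected,
                            data.frame(peptide = peps[i],
                                       allele = normalize_allele(al),
                                       label = 0L))
        }
      }
    }
    rownames(records) <- rownames(expected) <- NULL
    list(records = records, expected = expected, coverage = TRUE)
  })
}

# Deterministic string hash onto [0, 1): polynomial rolling hash modulo
# 2^31 - 1 with multiplicative scrambling; exact in double arithmetic.
hash_unit <- function(s, seed = 0) {
  M <- 2147483647
  vapply(s, function(x) {
    h <- (as.numeric(seed) * 2654435 + 12345) %% M
    for (cc in utf8ToInt(x)) h <- (h * 131 + cc) %% M
    for (i in 1:3) h <- (h * 48271 + 11) %% M
    h / M
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic toy predictor suite
#'
#' A pure, seed-reproducible stand-in for external binding / stability /
#' processing / immunogenicity tools: every channel hashes
#' (channel, peptide, allele, seed) onto plausible ranges - IC50
#' log-uniform on 1-50000 nM, %Ranks uniform on 0-100, immunogenicity
#' scores uniform on 0-1.  Three score-type tools (`immuno_a/b/c`) and one
#' rank-type tool (`prime_rank`) are provided.
#'
#' @param seed Seed baked into every hash.
#' @return A [predictor_suite()].
#' @export
gen_toy_predictor_suite <- function(seed = 1) {
  u <- function(channel, peptide, allele)
    hash_unit(paste(channel, peptide, allele, sep = "|"), seed)
  predictor_suite(
    binding = function(peptide, allele)
      list(ic50 = 10^(u("ic50", peptide, allele) * log10(50000)),
           percent_rank = 100 * u("brank", peptide, allele)),
    stability = function(peptide, allele)
      100 * u("stab", peptide, allele),
    processing = function(peptide, allele)
      100 * u("proc", peptide, allele),
    immunogenicity = list(
      immuno_a = function(peptide, allele) u("ia", peptide, allele),
      immuno_b = function(peptide, allele) u("ib", peptide, allele),
      immuno_c = function(peptide, allele) u("ic", peptide, allele),
      prime_rank = function(peptide, allele)
        100 * u("prime", peptide, allele)))
}

#' Generate random missense mutations with their proteins
#'
#' Random proteins over the standard alphabet with one missense change
#' each; when `n >= 5` the set is guaranteed to include a position-1 and a
#' C-terminal mutation for boundary testing.
#'
#' @param n Number of mutations.
#' @param protein_length Protein length (>= 27 gives full interior
#'   windows for 14-mers).
#' @param seed Seed.
#' @return Data frame: `gene`, `protein_seq`, `position`, `ref_aa`,
#'   `alt_aa`.
#' @export
gen_mutations <- function(n, protein_length = 40, seed = 1) {
  stopifnot(n >= 1, protein_length >= 8)
  with_local_seed(seed, {
    seqs <- random_peptides(n, rep(protein_length, n))
    pos <- sample(protein_length, n, replace = TRUE)
    if (n >= 5) {
      pos[1] <- 1L
      pos[2] <- protein_length
    }
    ref <- substr(seqs, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_ALPHABET20, r), 1),
                  character(1), USE.NAMES = FALSE)
    data.frame(gene = sprintf("GENE%03d", seq_len(n)), protein_seq = seqs,
               position = pos, ref_aa = ref, alt_aa = alt,
               stringsAsFactors = FALSE)
  })
}

#' Write mutations as TSV + FASTA
#' @param mutations Output of [gen_mutations()].
#' @param tsv_path,fasta_path Output paths.
#' @return Invisibly, `tsv_path`.
#' @export
write_mutations <- function(mutations, tsv_path, fasta_path) {
  df <- mutations[, c("gene", "position", "ref_aa", "alt_aa")]
  df$sequence_id <- mutations$gene
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", mutations$gene),
                             mutations$protein_seq)), fasta_path)
  invisible(tsv_path)
}

#' Read mutations from TSV + FASTA
#' @param tsv_path TSV with `gene`, `position`, `ref_aa`, `alt_aa`,
#'   `sequence_id` (or an inline `protein_seq` column, making the FASTA
#'   optional).
#' @param fasta_path Protein FASTA keyed by `sequence_id`.
#' @return Data frame as from [gen_mutations()].
#' @export
read_mutations <- function(tsv_path, fasta_path = NULL) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!"protein_seq" %in% names(df)) {
    if (is.null(fasta_path))
      stop("read_mutations: no inline protein_seq and no FASTA given")
    fa <- Biostrings::readAAStringSet(fasta_path)
    seqs <- setNames(as.character(fa), sub("\\s.*", "", names(fa)))
    if (!all(df$sequence_id %in% names(seqs)))
      stop("read_mutations: sequence_id(s) missing from FASTA")
    df$protein_seq <- unname(seqs[df$sequence_id])
  }
  df[, c("gene", "protein_seq", "position", "ref_aa", "alt_aa")]
}
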