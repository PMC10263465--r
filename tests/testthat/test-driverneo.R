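test_that("protein mutation substitutes exactly one residue with guards", {
  expect_equal(mutate_protein("ACDEFGHIK", 5, "F", "L"), "ACDELGHIK")
  expect_equal(mutate_protein("ACDEFGHIK", 9, "K", "R"), "ACDEFGHIR")
  expect_error(mutate_protein("ACDEFGHIK", 2, "A", "V"), "sequence has C")
  expect_error(mutate_protein("ACDEFGHIK", 10, "K", "R"), "out of range")
  expect_error(mutate_protein("ACDEFGHIK", 3, "D", "D"), "identical")
})

test_that("window extraction matches the exhaustive enumeration oracle", {
  window_oracle <- function(n, pos, lengths = 8:14) {
    count <- 0
    for (L in lengths) for (s in seq_len(max(0, n - L + 1)))
      if (s <= pos && pos <= s + L - 1) count <- count + 1
    count
  }
  wt <- paste(rep(AA_ALPHABET20, 3), collapse = "")  # 60-mer
  # interior mutation, >= 13 residues each side
  mt <- mutate_protein(wt, 30, substr(wt, 30, 30),
                       if (substr(wt, 30, 30) == "A") "C" else "A")
  pp <- extract_peptide_pairs(wt, mt, 30)
  expect_equal(nrow(pp), 77)
  expect_equal(nrow(pp), window_oracle(60, 30))
  # N-terminal mutation: one window per length
  mt1 <- mutate_protein(wt, 1, substr(wt, 1, 1), "W")
  pp1 <- extract_peptide_pairs(wt, mt1, 1)
  expect_equal(nrow(pp1), 7)
  expect_equal(nrow(pp1), window_oracle(60, 1))
  # C-terminal mutation
  mtL <- mutate_protein(wt, 60, substr(wt, 60, 60), "A")
  expect_equal(nrow(extract_peptide_pairs(wt, mtL, 60)), window_oracle(60, 60))
  # construction invariants
  for (i in seq_len(nrow(pp))) {
    off <- pp$offset_of_mutation[i]
    expect_equal(nchar(pp$mt_peptide[i]), pp$length[i])
    expect_equal(substr(pp$mt_peptide[i], off, off),
                 substr(mt, 30, 30))
    diffs <- which(strsplit(pp$wt_peptide[i], "")[[1]] !=
                     strsplit(pp$mt_peptide[i], "")[[1]])
    expect_equal(diffs, off)
  }
})

test_that("DAI is the WT/MT IC50 ratio with positivity guards", {
  expect_equal(compute_dai(1000, 100), 10)
  expect_equal(compute_dai(500, 500), 1)
  expect_equal(compute_dai(100, 1000), 0.1)
  expect_error(compute_dai(0, 10), "positive")
  expect_error(compute_dai(10, -1), "positive")
  # boundary: DAI of exactly 1 fails the strict filter
  th <- filter_thresholds()
  expect_false(compute_dai(500, 500) > th$dai_min)
})

test_that("immunogenicity votes follow tool types and boundaries", {
  th <- filter_thresholds()
  expect_equal(vote_immunogenicity(
    c(A = 0.9, B = 0.85, C = 0.1, PRIME_rank = 5), th), 2)
  expect_equal(vote_immunogenicity(c(A = 0.8), th), 1)  # inclusive 0.8
  expect_equal(vote_immunogenicity(c(A = 0.1, B = 0.2), th), 0)
  expect_equal(vote_immunogenicity(c(PRIME_rank = 1.9), th), 1)
  expect_equal(vote_immunogenicity(c(PRIME_rank = 2), th), 0)  # strict <
  expect_error(vote_immunogenicity(c(A = 1), th,
                                   tool_types = c(A = "fuzzy")), "score")
  expect_error(vote_immunogenicity(c(0.9), th), "named")
})

test_that("screening agrees with a brute-force re-evaluation oracle", {
  suite <- gen_toy_predictor_suite(seed = 2)
  muts <- gen_mutations(3, protein_length = 40, seed = 8)
  alleles <- names(test_pseudo())[1:5]
  th <- filter_thresholds(binding_rank_max = 30, dai_min = 1,
                          stability_rank_max = 50, processing_rank_max = 50,
                          immuno_score_min = 0.5, prime_rank_max = 50,
                          min_votes = 2)
  cand <- screen_candidates(muts, alleles, suite, th, keep_all = TRUE)
  # brute force: enumerate and re-apply every inequality independently
  keys_pass <- character(0)
  for (i in seq_len(nrow(muts))) {
    mt_seq <- mutate_protein(muts$protein_seq[i], muts$position[i],
                             muts$ref_aa[i], muts$alt_aa[i])
    pairs <- extract_peptide_pairs(muts$protein_seq[i], mt_seq,
                                   muts$position[i])
    for (al in normalize_allele(alleles)) for (j in seq_len(nrow(pairs))) {
      mtp <- pairs$mt_peptide[j]; wtp <- pairs$wt_peptide[j]
      bm <- suite$binding(mtp, al); bw <- suite$binding(wtp, al)
      votes <- sum(c(suite$immunogenicity$immuno_a(mtp, al) >= 0.5,
                     suite$immunogenicity$immuno_b(mtp, al) >= 0.5,
                     suite$immunogenicity$immuno_c(mtp, al) >= 0.5,
                     suite$immunogenicity$prime_rank(mtp, al) < 50))
      ok <- bm$percent_rank < 30 && (bw$ic50 / bm$ic50) > 1 &&
        suite$stability(mtp, al) < 50 && suite$processing(mtp, al) < 50 &&
        votes >= 2
      if (ok) keys_pass <- c(keys_pass, paste(i, al, mtp))
    }
  }
  got <- cand[cand$pass, ]
  mut_ids <- sprintf("%s_%s%d%s", muts$gene, muts$ref_aa, muts$position,
                     muts$alt_aa)
  expect_setequal(paste(match(got$mutation, mut_ids), got$allele,
                        got$mt_peptide), keys_pass)
})

test_that("screening output is conserved, deterministic and threshold-monotone", {
  suite <- gen_toy_predictor_suite(seed = 4)
  muts <- gen_mutations(2, protein_length = 30, seed = 13)
  alleles <- names(test_pseudo())[1:2]
  all1 <- screen_candidates(muts, alleles, suite, keep_all = TRUE)
  all2 <- screen_candidates(muts, alleles, suite, keep_all = TRUE)
  expect_identical(all1, all2)
  # conservation: every window x allele appears exactly once under keep_all
  n_windows <- sum(vapply(seq_len(nrow(muts)), function(i) {
    mt_seq <- mutate_protein(muts$protein_seq[i], muts$position[i],
                             muts$ref_aa[i], muts$alt_aa[i])
    nrow(extract_peptide_pairs(muts$protein_seq[i], mt_seq,
                               muts$position[i]))
  }, numeric(1)))
  expect_equal(nrow(all1), n_windows * length(alleles))
  expect_false(any(duplicated(
    all1[c("mutation", "allele", "mt_peptide", "wt_peptide")])))
  # pass flag is the conjunction of the per-filter flags
  expect_equal(all1$pass,
               all1$pass_binding & all1$pass_dai & all1$pass_stability &
                 all1$pass_processing & all1$pass_votes)
  # tightening any threshold never increases survivors; loosening never decreases
  base_th <- filter_thresholds(binding_rank_max = 20, immuno_score_min = 0.5,
                               min_votes = 2)
  n_at <- function(th) sum(screen_candidates(muts, alleles, suite, th,
                                             keep_all = TRUE)$pass)
  n0 <- n_at(base_th)
  for (fld in c("binding_rank_max", "stability_rank_max",
                "processing_rank_max", "prime_rank_max")) {
    tighter <- looser <- base_th
    tighter[[fld]] <- base_th[[fld]] / 2
    looser[[fld]] <- base_th[[fld]] * 2
    expect_lte(n_at(tighter), n0)
    expect_gte(n_at(looser), n0)
  }
  tighter <- base_th; tighter$dai_min <- 2
  expect_lte(n_at(tighter), n0)
  tighter <- base_th; tighter$min_votes <- 3L
  expect_lte(n_at(tighter), n0)
  # empty input
  expect_equal(nrow(screen_candidates(muts[0, ], alleles, suite)), 0)
})

test_that("predictor failures mark rows without aborting the screen", {
  flaky <- predictor_suite(
    binding = function(p, a) {
      if (substr(p, 1, 1) == "A") stop("tool crashed")
      list(ic50 = 100, percent_rank = 1)
    },
    stability = function(p, a) 1,
    processing = function(p, a) 1,
    immunogenicity = list(s1 = function(p, a) 0.9))
  mut <- data.frame(gene = "G", protein_seq = paste(rep("ACDEFGHIKL", 3),
                                                    collapse = ""),
                    position = 15, ref_aa = "F", alt_aa = "Y")
  out <- screen_candidates(mut, "HLA-A*02:01", flaky,
                           filter_thresholds(min_votes = 1), keep_all = TRUE)
  expect_true(any(out$errored))
  expect_true(any(!out$errored))
  expect_false(any(out$pass[out$errored]))
  expect_equal(attr(out, "summary")$n_errored, sum(out$errored))
})

test_that("heatmap matrix lays out alleles x peptides for one mutation", {
  suite <- gen_toy_predictor_suite(seed = 6)
  muts <- gen_mutations(2, protein_length = 30, seed = 3)
  alleles <- names(test_pseudo())[1:2]
  cand <- screen_candidates(muts, alleles, suite, keep_all = TRUE)
  one <- cand[cand$mutation == cand$mutation[1], ]
  hm <- heatmap_matrix(one)
  expect_equal(nrow(hm), 2)
  expect_equal(ncol(hm), length(unique(one$mt_peptide)))
  expect_equal(hm[one$allele[1], one$mt_peptide[1]], one$rank_mt[1])
  hm2 <- heatmap_matrix(one, value = "ic50_mt")
  expect_identical(dimnames(hm2), dimnames(hm))
  expect_error(heatmap_matrix(cand), "multiple mutations")
  expect_error(heatmap_matrix(one[0, ]), "no candidates")
})
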