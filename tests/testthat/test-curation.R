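mk_rec <- function(peptide = "SIINFEKLM", allele = "HLA-A*02:01",
                   outcome = "positive", n_exp = NA, n_resp = 1,
                   host = "Homo sapiens", mhc = "I",
                   assay = "cytokine release") {
  data.frame(peptide = peptide, allele = allele, assay_class = assay,
             qualitative_outcome = outcome, n_experiments = n_exp,
             n_subjects_tested = NA, n_subjects_responded = n_resp,
             host = host, mhc_class = mhc, stringsAsFactors = FALSE)
}

test_that("each evidence rule drops exactly its records", {
  recs <- rbind(
    mk_rec(allele = "HLA-A2"),                              # 2-digit allele
    mk_rec(outcome = "negative", n_exp = 3, n_resp = NA),   # too few experiments
    mk_rec(peptide = "AANEGFOUR", outcome = "negative", n_exp = 4,
           n_resp = NA),                                    # boundary: kept
    mk_rec(peptide = "AAPOSZERO", n_resp = 0),              # no responder
    mk_rec(peptide = "AAPOSONE", n_resp = 1),               # boundary: kept
    mk_rec(peptide = "AAMOUSE", host = "Mus musculus"),     # scope
    mk_rec(peptide = "AACLASSII", mhc = "II"),              # scope
    mk_rec(peptide = "AANOCOUNT", outcome = "negative", n_exp = NA,
           n_resp = NA))                                    # missing info
  cd <- filter_records(recs)
  expect_setequal(cd$instances$peptide,
                  c("AANEGFOUR", "AAPOSONE"))
  expect_equal(cd$drop_counts[["scope"]], 2)
  expect_equal(cd$drop_counts[["allele_resolution"]], 1)
  expect_equal(cd$drop_counts[["missing_counts"]], 1)
  expect_equal(cd$drop_counts[["negative_evidence"]], 1)
  expect_equal(cd$drop_counts[["positive_evidence"]], 1)
  expect_true(all(cd$instances$allele == "HLA-A*02:01"))
})

test_that("duplicate collapse is concordant-keeps-one, discordant-per-policy", {
  recs <- rbind(
    mk_rec(peptide = "AACONCORD", n_resp = 1),
    mk_rec(peptide = "AACONCORD", n_resp = 2),
    mk_rec(peptide = "AACONFLICT", n_resp = 1),
    mk_rec(peptide = "AACONFLICT", outcome = "negative", n_exp = 5,
           n_resp = NA))
  cd <- filter_records(recs)
  expect_equal(cd$instances$peptide, "AACONCORD")
  expect_equal(cd$drop_counts[["duplicate_collapsed"]], 1)
  expect_equal(cd$drop_counts[["conflict_discarded"]], 2)
  cd_pos <- filter_records(recs, curation_policy(conflict = "positive"))
  expect_setequal(cd_pos$instances$peptide, c("AACONCORD", "AACONFLICT"))
  expect_equal(cd_pos$instances$label[cd_pos$instances$peptide ==
                                        "AACONFLICT"], 1L)
})

test_that("generated records match the generator-embedded survivor oracle", {
  ar <- gen_assay_records(synthetic_config(seed = 21, n_assay_records = 50))
  expect_equal(nrow(ar$records), 50)
  expect_true(ar$coverage)
  cd <- filter_records(ar$records)
  got <- cd$instances[order(cd$instances$peptide),
                      c("peptide", "allele", "label")]
  want <- ar$expected[order(ar$expected$peptide), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("curation conserves records, is idempotent and monotone", {
  ar <- gen_assay_records(synthetic_config(seed = 33, n_assay_records = 60))
  cd <- filter_records(ar$records)
  expect_equal(nrow(cd$instances) + sum(cd$drop_counts) + nrow(cd$rejects),
               nrow(ar$records))
  expect_false(any(duplicated(cd$instances[c("peptide", "allele")])))
  expect_true(all(grepl("^HLA-[A-Z]+\\*[0-9]+:[0-9]+$", cd$instances$allele)))
  # idempotence: re-filtering the survivors changes nothing
  surv <- cd$instances
  refeed <- data.frame(peptide = surv$peptide, allele = surv$allele,
                       assay_class = "cytokine release",
                       qualitative_outcome = ifelse(surv$label == 1,
                                                    "positive", "negative"),
                       n_experiments = 5, n_subjects_tested = 3,
                       n_subjects_responded = 1, host = "Homo sapiens",
                       mhc_class = "I")
  cd2 <- filter_records(refeed)
  expect_equal(nrow(cd2$instances), nrow(surv))
  expect_setequal(paste(cd2$instances$peptide, cd2$instances$allele,
                        cd2$instances$label),
                  paste(surv$peptide, surv$allele, surv$label))
  # monotonicity in the negative-evidence threshold.  At the instance level
  # this holds under positive-wins conflict resolution; under discard, a
  # raised threshold can break a label conflict and release the positive,
  # so there the guaranteed monotone quantity is the count of records
  # surviving the evidence filters (pre-deduplication).
  inst_counts <- vapply(c(2, 4, 6, 8), function(th)
    nrow(filter_records(ar$records, curation_policy(
      min_negative_experiments = th, conflict = "positive"))$instances),
    numeric(1))
  expect_true(all(diff(inst_counts) <= 0))
  rec_counts <- vapply(c(2, 4, 6, 8), function(th) {
    cd <- filter_records(ar$records, curation_policy(
      min_negative_experiments = th))
    nrow(cd$instances) + cd$drop_counts[["duplicate_collapsed"]] +
      cd$drop_counts[["conflict_discarded"]]
  }, numeric(1))
  expect_true(all(diff(rec_counts) <= 0))
})

test_that("assay TSVs round-trip with a column map", {
  ar <- gen_assay_records(synthetic_config(seed = 5, n_assay_records = 30))
  f <- withr::local_tempfile(fileext = ".tsv")
  recs <- ar$records
  names(recs)[names(recs) == "peptide"] <- "Epitope.Description"
  write.table(recs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_assay_records(f, column_map = c(peptide = "Epitope.Description"))
  expect_equal(back$peptide, ar$records$peptide)
  expect_equal(back$n_experiments, ar$records$n_experiments)
})

test_that("similarity search self-normalizes and orders by similarity", {
  hits <- similarity_search("AAAAAAAA", c("AAAAAAAA", "WWWWWWWW"))
  expect_equal(hits$peptide[1], "AAAAAAAA")
  expect_equal(hits$similarity[1], 1.0, tolerance = 1e-12)
  expect_lt(hits$similarity[2], hits$similarity[1])
  db <- data.frame(peptide = c("SIINFEKLM", "SIINFEKLV", "KVAELVHFL"),
                   gene = c("g1", "g2", "g3"))
  hits2 <- similarity_search("SIINFEKLM", db, top_n = 2)
  expect_equal(hits2$peptide[1], "SIINFEKLM")
  expect_equal(hits2$gene[1], "g1")
  expect_equal(nrow(hits2), 2)
  expect_error(similarity_search("SIINFEKLM", character(0)), "empty")
  expect_error(similarity_search("SIINFEK1M", "AAAA"), "invalid")
})

test_that("similarity ranking matches an independent alignment oracle", {
  set.seed(17)
  db <- rand_peptides(10)
  query <- rand_peptides(1)
  hits <- similarity_search(query, db, top_n = 10)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  self <- function(s) sum(setNames(diag(B62), rownames(B62))[
    strsplit(s, "")[[1]]])
  sim_or <- vapply(db, function(d)
    nw_score_oracle(query, d, B62) / sqrt(self(query) * self(d)),
    numeric(1), USE.NAMES = FALSE)
  ord_or <- order(-sim_or)
  expect_equal(hits$peptide, db[ord_or])
  expect_equal(hits$similarity, sim_or[ord_or], tolerance = 1e-10)
})
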