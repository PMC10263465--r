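# Shared fixtures (memoized) and independent oracles used across tests.

.fixtures <- new.env(parent = emptyenv())

test_embedding <- function() {
  if (is.null(.fixtures$emb))
    .fixtures$emb <- suppressMessages(build_embedding(
      system.file("extdata", "aaindex1_synthetic.txt",
                  package = "immunograph")))
  .fixtures$emb
}

test_pseudo <- function() {
  if (is.null(.fixtures$pt))
    .fixtures$pt <- read_pseudo_table(
      system.file("extdata", "pseudoseq_synthetic.tsv",
                  package = "immunograph"))
  .fixtures$pt
}

# Build a small AAindex1-format text from named value vectors (in the
# file's A R N D C Q E G H I / L K M F P S T V W Y order); "NA" allowed.
make_aaindex_text <- function(values_list) {
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")
  out <- character(0)
  for (nm in names(values_list)) {
    v <- values_list[[nm]]
    fmt <- function(x) paste(formatC(ifelse(is.na(x), "NA",
                                            formatC(x, format = "f",
                                                    digits = 3)),
                                     width = 10), collapse = "")
    out <- c(out,
             paste0("H ", nm),
             paste0("D test index ", nm),
             paste0("I    ", paste(paste0(row1, "/", row2), collapse = "   ")),
             fmt(v[row1]), fmt(v[row2]), "//")
  }
  out
}

# Independent type-7 quantile oracle (linear interpolation on sorted x).
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Independent affine-gap global alignment oracle (Gotoh), matching the
# gap model score = sum(substitution) - (open + len * extend) per gap.
nw_score_oracle <- function(a, b, submat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
    Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Random peptide helper for tests (uses the ambient RNG).
rand_peptides <- function(n, len_min = 8, len_max = 14) {
  vapply(sample(len_min:len_max, n, replace = TRUE), function(L)
    paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
    character(1))
}
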