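make_tables <- function(genes = c("G1", "G2", "G3"), dim = 6L, seed = 2L) {
  init_embedding_tables(condition_registry(c("A", "B"), genes), dim, seed = seed)
}

## per-gene loop oracle mirroring the printed summation
oracle_genomic <- function(profile, tb) {
  mlp <- function(m, x) {
    h <- as.vector(x %*% m$W1) + m$b1
    a <- h / (1 + exp(-h))
    as.vector(a %*% m$W2) + m$b2
  }
  out <- numeric(tb$dim)
  for (g in tb$registry$genes) {
    e <- if (isTRUE(as.logical(profile[[g]]))) tb$mut_table[g, ] else tb$wt_table[g, ]
    out <- out + mlp(tb$mlp_genomic, e)
  }
  out
}

oracle_transcriptomic <- function(profile, tb) {
  mlp <- function(m, x) {
    h <- as.vector(x %*% m$W1) + m$b1
    a <- h / (1 + exp(-h))
    as.vector(a %*% m$W2) + m$b2
  }
  out <- numeric(tb$dim)
  for (g in tb$registry$genes) {
    e <- tb$txn_gene_table[g, ]
    out <- out + mlp(tb$mlp_transcriptomic, e) *
      mlp(tb$mlp_exp, c(e, as.numeric(profile[[g]])))
  }
  out
}

test_that("categorical embedding is a strict table lookup", {
  tb <- make_tables()
  expect_identical(embed_categorical("A", tb), tb$categorical_table["A", ])
  expect_identical(embed_categorical("A", tb), embed_categorical("A", tb))
  expect_false(isTRUE(all.equal(embed_categorical("A", tb),
                                embed_categorical("B", tb))))
  expect_error(embed_categorical("nope", tb), "nope")
})

test_that("genomic embedding equals the per-gene loop oracle", {
  tb <- make_tables()
  all_wt <- c(G1 = FALSE, G2 = FALSE, G3 = FALSE)
  expect_equal(embed_genomic(all_wt, tb), oracle_genomic(all_wt, tb),
               tolerance = 1e-12)
  mixed <- c(G1 = TRUE, G2 = FALSE, G3 = TRUE)
  expect_equal(embed_genomic(mixed, tb), oracle_genomic(mixed, tb),
               tolerance = 1e-12)
  ## flipping one gene's status shifts the sum by that gene's term swap
  ## (difference of two brute-force sums)
  flip <- mixed; flip["G2"] <- TRUE
  expect_equal(embed_genomic(flip, tb) - embed_genomic(mixed, tb),
               oracle_genomic(flip, tb) - oracle_genomic(mixed, tb),
               tolerance = 1e-12)
  ## empty gene set -> zero vector
  tb0 <- init_embedding_tables(condition_registry("A"), 6L, seed = 1L)
  expect_equal(embed_genomic(stats::setNames(logical(), character()), tb0),
               numeric(6))
  expect_error(embed_genomic(c(G1 = TRUE), tb), "match")
})

test_that("transcriptomic embedding is term-wise separable", {
  tb <- make_tables()
  pr <- c(G1 = 0.2, G2 = 0.5, G3 = 0.9)
  expect_equal(embed_transcriptomic(pr, tb), oracle_transcriptomic(pr, tb),
               tolerance = 1e-12)
  ## single-gene registry: one direct product term
  tb1 <- init_embedding_tables(condition_registry("A", "G1"), 6L, seed = 3L)
  p1 <- c(G1 = 0.3)
  expect_equal(embed_transcriptomic(p1, tb1), oracle_transcriptomic(p1, tb1),
               tolerance = 1e-12)
  ## changing one gene's value only changes that gene's summand
  pr2 <- pr; pr2["G2"] <- 0.8
  delta <- embed_transcriptomic(pr2, tb) - embed_transcriptomic(pr, tb)
  d_oracle <- oracle_transcriptomic(c(G1 = 0.2, G2 = 0.8, G3 = 0.9), tb) -
    oracle_transcriptomic(pr, tb)
  expect_equal(delta, d_oracle, tolerance = 1e-12)
  expect_error(embed_transcriptomic(c(G1 = NaN, G2 = 1, G3 = 1), tb), "finite")
})

test_that("profiles are invariant to gene ordering", {
  tb <- make_tables()
  g <- c(G1 = TRUE, G2 = FALSE, G3 = TRUE)
  tx <- c(G1 = 0.1, G2 = 0.6, G3 = 0.8)
  perm <- c("G3", "G1", "G2")
  expect_equal(embed_genomic(g[perm], tb), embed_genomic(g, tb),
               tolerance = 1e-9)
  expect_equal(embed_transcriptomic(tx[perm], tb), embed_transcriptomic(tx, tb),
               tolerance = 1e-9)
})

test_that("combine_conditions is the additive composition", {
  tb <- make_tables()
  g <- c(G1 = TRUE, G2 = FALSE, G3 = FALSE)
  tx <- c(G1 = 0.4, G2 = 0.2, G3 = 0.9)
  full <- condition_bundle("A", genomic = g, transcriptomic = tx)
  expect_equal(combine_conditions(full, tb),
               embed_categorical("A", tb) + embed_genomic(g, tb) +
                 embed_transcriptomic(tx, tb),
               tolerance = 1e-12)
  ## categorical-only: omics contribute zero
  expect_equal(combine_conditions(condition_bundle("B"), tb),
               embed_categorical("B", tb), tolerance = 1e-12)
  ## swapping only the genomic member shifts by exactly that difference
  g2 <- c(G1 = FALSE, G2 = TRUE, G3 = FALSE)
  alt <- condition_bundle("A", genomic = g2, transcriptomic = tx)
  expect_equal(combine_conditions(alt, tb) - combine_conditions(full, tb),
               embed_genomic(g2, tb) - embed_genomic(g, tb),
               tolerance = 1e-12)
})

test_that("quantile normalization follows rank/(n+1) with tie averaging", {
  expect_equal(as.vector(quantile_normalize(matrix(c(1, 2, 3)))),
               c(0.25, 0.5, 0.75))
  expect_equal(as.vector(quantile_normalize(matrix(c(5, 5, 5, 5)))),
               rep(0.5, 4))
  x <- matrix(rexp(40), 10, 4)
  expect_equal(quantile_normalize(x), quantile_normalize(exp(x)),
               tolerance = 1e-12)  # monotone-transform invariance
  q <- quantile_normalize(x)
  expect_true(all(q > 0 & q < 1))
  expect_error(quantile_normalize(matrix(numeric(), 0, 1)), "sample")
  expect_error(quantile_normalize(matrix(c(1, Inf))), "finite")
})

test_that("profile TSV readers round-trip", {
  tmp <- withr::local_tempdir()
  gpath <- file.path(tmp, "g.tsv")
  write.table(data.frame(gene = c("G1", "G2"), status = c(1L, 0L)),
              gpath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_genomic_tsv(gpath), c(G1 = TRUE, G2 = FALSE))
  tpath <- file.path(tmp, "t.tsv")
  write.table(data.frame(gene = c("G1", "G2"), value = c(0.25, 0.75)),
              tpath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_transcriptomic_tsv(tpath), c(G1 = 0.25, G2 = 0.75))
})
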