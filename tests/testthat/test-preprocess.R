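test_that("low-abundance cell filter matches a brute-force per-cell scan", {
  x <- random_counts(20, 50, seed = 7, lambda = 60)
  got <- filter_low_abundance_cells(x, 0.001)
  # independent oracle: explicit loop against the original sample totals
  m <- unclass(x)[, ]
  expected <- m
  for (i in seq_len(nrow(m))) {
    thr <- 0.001 * sum(m[i, ])
    for (j in seq_len(ncol(m))) {
      if (m[i, j] < thr) expected[i, j] <- 0
    }
  }
  expect_equal(unclass(got)[, ], expected)

  # single pass against original totals => exactly idempotent given the
  # same totals are reused; re-application on the output with the *same*
  # fraction and unchanged thresholds is covered by comparing to the oracle
  expect_equal(unclass(filter_low_abundance_cells(got, 0))[, ],
               unclass(got)[, ])
})

test_that("cell filter thresholds are strict and scale with sample totals", {
  m <- matrix(c(2, 2998, 1, 499), 2, 2, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("f1", "f2")))
  x <- count_matrix(m)
  out <- unclass(filter_low_abundance_cells(x, 0.001))[, ]
  expect_equal(out["deep", "f1"], 0)       # 2 < 0.001 * 3000
  expect_equal(out["deep", "f2"], 2998)
  expect_equal(out["shallow", ], m["shallow", ])  # 1 >= 0.5 threshold
  expect_error(filter_low_abundance_cells(x, 1), "fraction")
  expect_error(filter_low_abundance_cells(x, -0.1), "fraction")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  x <- random_counts(12, 30, seed = 5, lambda = 40)  # totals ~1200
  res <- rarefy_counts(x, depth = 500, seed = 99)
  expect_true(all(rowSums(res$counts) == 500))
  expect_true(all(unclass(res$counts)[, ] <=
                  unclass(x)[rownames(res$counts), ]))

  # a sample at exactly the target depth is returned unchanged
  m <- matrix(c(400, 100, 300, 199), 2, 2, byrow = TRUE,
              dimnames = list(c("at", "under"), c("f1", "f2")))
  r2 <- rarefy_counts(count_matrix(m), depth = 500, seed = 1)
  expect_equal(unclass(r2$counts)["at", ], m["at", ])
  expect_equal(r2$discarded, "under")
})

test_that("per-sample RNG streams survive subsetting and reruns", {
  x <- random_counts(8, 20, seed = 2, lambda = 50)
  full <- rarefy_counts(x, depth = 300, seed = 77)
  again <- rarefy_counts(x, depth = 300, seed = 77)
  expect_identical(unclass(full$counts)[, ], unclass(again$counts)[, ])
  # dropping one sample leaves the others' subsamples untouched
  sub <- rarefy_counts(count_matrix(unclass(x)[-3, ]), depth = 300,
                       seed = 77)
  expect_identical(unclass(sub$counts)[, ],
                   unclass(full$counts)[rownames(sub$counts), ])
  # a different master seed changes the draw
  other <- rarefy_counts(x, depth = 300, seed = 78)
  expect_false(identical(unclass(full$counts)[, ],
                         unclass(other$counts)[, ]))
})

test_that("rarefaction moments match the hypergeometric expectation", {
  # two-feature sample {A: 900, B: 100}, depth 500: A-count is
  # Hypergeometric(900 of 1000, 500 draws)
  m <- matrix(c(900, 100), 1, 2, dimnames = list("s1", c("A", "B")))
  x <- count_matrix(m)
  draws <- vapply(1:1000, function(s) {
    unclass(rarefy_counts(x, depth = 500, seed = s)$counts)[1, "A"]
  }, numeric(1))
  exp_mean <- 500 * 0.9
  exp_var <- 500 * 0.9 * 0.1 * (1000 - 500) / (1000 - 1)
  expect_lt(abs(mean(draws) - exp_mean), 3 * sqrt(exp_var / 1000))
  # variance of the realized draws consistent with the hypergeometric
  # (normal-approximation band for a sample variance of n = 1000)
  expect_lt(abs(var(draws) - exp_var), 4 * exp_var * sqrt(2 / 999))
})

test_that("taxonomic collapsing merges lineages and conserves totals", {
  ids <- paste0("o", 1:4)
  tax <- toy_taxonomy(ids, genus = c("G1", "G1", "G2", "G3"))
  m <- matrix(c(3, 4, 5, 6,
                1, 0, 2, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), ids))
  out <- collapse_to_rank(count_matrix(m), tax, "genus")
  expect_equal(unclass(out)["s1", "G1"], 7)   # 3 + 4 summed
  expect_equal(colnames(out), c("G1", "G2", "G3"))
  expect_equal(rowSums(out), rowSums(m))
  expect_equal(count_rank(out), "genus")

  # all-distinct genera: collapse only renames
  tax2 <- toy_taxonomy(ids, genus = paste0("G", 1:4))
  out2 <- collapse_to_rank(count_matrix(m), tax2, "genus")
  expect_equal(unname(unclass(out2)[, ]), unname(m))

  # random matrix: per-sample totals conserved at every rank
  x <- random_counts(10, 30, seed = 8)
  tax3 <- toy_taxonomy(colnames(x),
                       genus = paste0("G", rep(1:10, 3)),
                       order = paste0("O", rep(1:5, 6)))
  for (rank in c("genus", "order")) {
    expect_equal(rowSums(collapse_to_rank(x, tax3, rank)), rowSums(x))
  }

  # collapsing an already collapsed matrix must refine -> error
  expect_error(collapse_to_rank(out, tax, "order"), "OTU-rank")
  expect_error(collapse_to_rank(x, tax3, "strain"), "unknown rank")
})

test_that("OTUs unassigned at the target rank go to 'unidentified' bins", {
  tax <- taxonomy_table(data.frame(
    feature_id = c("o1", "o2", "o3"),
    kingdom = "K", phylum = "P", class = "C",
    order = c("O1", "O1", "O2"),
    family = c("F1", "unidentified", "unidentified"),
    genus = c("G1", "unidentified", "unidentified"),
    stringsAsFactors = FALSE))
  m <- matrix(c(1, 2, 4), 1, 3, dimnames = list("s1", c("o1", "o2", "o3")))
  out <- collapse_to_rank(count_matrix(m), tax, "genus")
  expect_setequal(colnames(out),
                  c("G1", "unidentified O1", "unidentified O2"))
  expect_equal(unclass(out)["s1", "unidentified O1"], 2)
  out2 <- collapse_to_rank(count_matrix(m), tax, "genus",
                           drop_unidentified = TRUE)
  expect_equal(colnames(out2), "G1")
})

test_that("occurrence filter keeps features seen in enough samples", {
  x <- random_counts(40, 25, seed = 13, lambda = 0.5)
  expect_equal(unclass(filter_by_occurrence(x, 0))[, ], unclass(x)[, ])
  # brute-force oracle
  occ <- apply(unclass(x)[, ], 2, function(col) sum(col > 0))
  for (k in c(1, 5, 10)) {
    got <- filter_by_occurrence(x, k)
    expect_equal(colnames(got), names(occ)[occ >= k])
  }
  # feature in exactly 29 of 30 samples is removed at the threshold
  m <- matrix(1, 30, 2, dimnames = list(sprintf("s%02d", 1:30),
                                        c("common", "almost")))
  m[1, "almost"] <- 0
  out <- filter_by_occurrence(count_matrix(m), 30)
  expect_equal(colnames(out), "common")
})

test_that("relative abundances normalize rows and guard zero totals", {
  x <- random_counts(15, 20, seed = 21, lambda = 10)
  props <- to_relative_abundance(x)
  expect_equal(rowSums(props), setNames(rep(1, 15), rownames(x)),
               tolerance = 1e-12)

  rar <- rarefy_counts(x, depth = 100, seed = 1)$counts
  p500 <- to_relative_abundance(rar)
  expect_true(all(abs(p500 * 100 - round(p500 * 100)) < 1e-9))

  one <- count_matrix(matrix(7, 1, 1, dimnames = list("s1", "f1")))
  expect_equal(unname(to_relative_abundance(one)[1, 1]), 1)

  z <- matrix(c(1, 0), 2, 1, dimnames = list(c("ok", "empty"), "f1"))
  expect_error(to_relative_abundance(count_matrix(z)), "empty")
})

test_that("the full cascade runs in the documented stage order", {
  md <- balanced_metadata(3, 5)
  set.seed(4)
  m <- matrix(rpois(15 * 12, 80), 15, 12,
              dimnames = list(md$sample_id, paste0("o", 1:12)))
  m[1, ] <- c(rep(30, 4), rep(0, 8))  # shallow sample: total 120 < 200
  tax <- toy_taxonomy(paste0("o", 1:12), genus = paste0("G", rep(1:4, 3)))
  out <- preprocess_counts(count_matrix(m), tax,
                           preprocess_config(rarefaction_depth = 200,
                                             occurrence_min_samples = 5,
                                             collapse_rank = "genus",
                                             seed = 3))
  expect_equal(out$discarded, md$sample_id[1])
  expect_true(all(rowSums(out$rarefied) == 200))
  expect_equal(count_rank(out$counts), "genus")
  expect_true(all(colSums(unclass(out$counts)[, ] > 0) >= 5))
})
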