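test_that("count tables round-trip through the TSV dialect", {
  # tiny explicit table
  m <- count_matrix(matrix(c(5, 3, 0, 500), 2, 2,
                           dimnames = list(c("a", "b"), c("f1", "f2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, path)
  back <- read_count_table(path)
  expect_equal(unclass(back)[, ], unclass(m)[, ])

  # random matrix round-trip
  x <- random_counts(10, 30, seed = 42)
  write_count_table(x, path)
  expect_equal(unclass(read_count_table(path))[, ], unclass(x)[, ])

  # writing the same matrix twice gives identical bytes
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(x, p2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("BIOM-json and TSV dialects agree on the same matrix", {
  x <- random_counts(6, 12, seed = 3)
  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  p_biom <- withr::local_tempfile(fileext = ".biom")
  write_count_table(x, p_tsv, dialect = "tsv")
  write_count_table(x, p_biom, dialect = "biom-json")
  a <- read_count_table(p_tsv, dialect = "tsv")
  b <- read_count_table(p_biom, dialect = "biom-json")
  expect_equal(unclass(a)[rownames(x), colnames(x)],
               unclass(b)[rownames(x), colnames(x)])
})

test_that("degenerate and malformed count tables are handled", {
  # empty matrix -> header-only TSV
  empty <- count_matrix(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("f1", "f2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(empty, path)
  expect_length(readLines(path), 1L)

  # negative / non-integer cells named in the error
  writeLines(c("sample_id\tf1\tf2", "s1\t3\t-2"), path)
  expect_error(read_count_table(path), "s1.*f2")
  writeLines(c("sample_id\tf1\tf2", "s1\t3\t2.5"), path)
  expect_error(read_count_table(path), "non-integer")

  # duplicate ids rejected
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate")
})

test_that("transposed tables are detected against metadata", {
  x <- random_counts(5, 8, seed = 9)
  md <- sample_metadata(data.frame(sample_id = rownames(x),
                                   variety = "V1", location = "L1",
                                   line = "line1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  # write samples-in-columns by transposing manually
  tx <- count_matrix(t(unclass(x)[, ]))
  write_count_table(tx, path)
  auto <- read_count_table(path, orientation = "auto", metadata = md)
  expect_equal(unclass(auto)[rownames(x), colnames(x)], unclass(x)[, ])
})

test_that("sample metadata is validated and its design recovered", {
  md <- balanced_metadata(9, 15)
  expect_equal(nrow(md), 135L)
  expect_equal(nlevels(md$variety), 9L)
  expect_equal(nlevels(md$location), 15L)

  one <- sample_metadata(data.frame(sample_id = "s1", variety = "V1",
                                    location = "L1", line = "l1"))
  expect_equal(nlevels(one$variety), 1L)

  dup <- data.frame(sample_id = c("s1", "s1"), variety = "V1",
                    location = "L1", line = "l1")
  expect_error(sample_metadata(dup), "duplicate")
  expect_error(sample_metadata(data.frame(sample_id = "s1")), "missing")
  expect_error(sample_metadata(data.frame(sample_id = "s1", variety = "bad",
                                          location = "L1", line = "l1"),
                               variety_levels = c("V1", "V2")),
               "unknown variety")
})

test_that("taxonomy lineages are parsed, padded, and validated", {
  tax <- parse_lineage(c("o1", "o2"),
                       c("Bacteria;Proteobacteria", "Fungi"))
  expect_equal(tax$phylum, c("Proteobacteria", "unidentified"))
  expect_equal(tax$genus, c("unidentified", "unidentified"))

  # assigned rank below an unidentified one violates the cascade
  bad <- data.frame(feature_id = "o1", kingdom = "K", phylum = "unidentified",
                    class = "C", order = "O", family = "F", genus = "G")
  expect_error(taxonomy_table(bad), "unidentified")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, path)
  expect_equal(read_taxonomy(path), tax)
})

test_that("align_dataset intersects ids, reports drops, and is idempotent", {
  x <- random_counts(10, 6, seed = 1)
  md <- balanced_metadata(2, 5)  # s001..s010
  rownames(x) <- md$sample_id
  tax <- toy_taxonomy(colnames(x), genus = paste0("G", 1:6))

  # identical id sets -> unchanged
  al <- align_dataset(x, md, tax)
  expect_equal(unclass(al$counts)[, ], unclass(x)[, ])
  expect_length(unlist(al$dropped), 0L)

  # metadata missing 3 samples -> exactly those rows dropped
  al2 <- align_dataset(x, md[-c(2, 5, 7), ], tax)
  expect_equal(nrow(al2$counts), 7L)
  expect_setequal(al2$dropped$samples_from_counts,
                  md$sample_id[c(2, 5, 7)])

  # shuffled metadata order gives the same aligned result
  al3 <- align_dataset(x, md[sample.int(10), ], tax)
  expect_equal(unclass(al3$counts)[, ], unclass(al$counts)[, ])
  expect_equal(al3$metadata$sample_id, al$metadata$sample_id)

  # idempotence
  al4 <- align_dataset(al2$counts, al2$metadata, al2$taxonomy)
  expect_equal(unclass(al4$counts)[, ], unclass(al2$counts)[, ])

  expect_error(align_dataset(x, md[0, ], tax), "no samples")
})

test_that("result tables round-trip losslessly", {
  df <- data.frame(term = c("variety", "location"), df = c(8L, 14L),
                   pseudo_F = c(1.125, 2.0625), p = c(0.37, 0.0035),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(df, path)
  back <- read_result_table(path)
  expect_equal(back$term, df$term)
  expect_equal(back$pseudo_F, df$pseudo_F)
  expect_equal(back$p, df$p)
})
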