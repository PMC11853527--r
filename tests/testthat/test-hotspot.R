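test_that("database merging keeps recurrences and dedups by protein change", {
  primary <- data.frame(position = c(205, 208, 208, 208, 208),
                        ref_aa = "R", alt_aa = c("W", "Q", "Q", "Q", "Q"),
                        source_db = "DB-A", tissue = "x", sample_id = letters[1:5])
  secondary <- data.frame(position = c(205, 208), ref_aa = "R",
                          alt_aa = c("W", "W"), source_db = "DB-B",
                          tissue = "y", sample_id = c("f", "g"))
  merged <- merge_databases(primary, list(secondary))
  # all 5 primary records retained (4x recurrent R208Q), plus only the new key
  expect_equal(nrow(merged), 6)
  keys <- unique(paste(merged$position, merged$ref_aa, merged$alt_aa))
  expect_setequal(keys, c("205 R W", "208 R Q", "208 R W"))
  expect_equal(sum(merged$position == 208 & merged$alt_aa == "Q"), 4)

  # empty secondary is a no-op; merging again with the same secondary is idempotent
  expect_identical(merge_databases(primary, list())[], primary)
  merged2 <- merge_databases(merged, list(secondary))
  expect_equal(nrow(merged2), nrow(merged))
})

test_that("reference-residue conflicts warn and keep the primary annotation", {
  primary <- data.frame(position = 10, ref_aa = "R", alt_aa = "W")
  secondary <- data.frame(position = 10, ref_aa = "K", alt_aa = "E")
  expect_warning(merged <- merge_databases(primary, list(secondary)),
                 "conflict")
  expect_equal(merged$ref_aa[merged$alt_aa == "W"], "R")
})

test_that("mutation classification covers the three classes", {
  expect_equal(classify_mutation("R", "W"), "missense")
  expect_equal(classify_mutation("G", "="), "silent")
  expect_equal(classify_mutation("G", "G"), "silent")
  expect_equal(classify_mutation("Q", "*"), "stop")
  expect_error(classify_mutation("Q", "?"), "invalid")
})

test_that("window scan counts match hand-computed values and edge rules", {
  rec <- data.frame(position = c(10, 10, 12), ref_aa = "A", alt_aa = "V")
  prof <- window_scan(rec, protein_length = 273, window = 7)
  expect_equal(prof$count[10], 3)
  expect_equal(prof$count[14], 1)
  expect_equal(prof$count[16], 0)

  empty <- window_scan(rec[0, ], protein_length = 50)
  expect_true(all(empty$count == 0))

  w1 <- window_scan(rec, protein_length = 273, window = 1)
  expect_equal(w1$count, w1$raw)

  expect_error(window_scan(rec, 273, window = 6), "odd")
})

test_that("window scan equals the brute-force double loop on random tables", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(40:300, 1)
    n <- sample(0:80, 1)
    rec <- data.frame(position = sample.int(L, n, replace = TRUE),
                      ref_aa = rep("A", n), alt_aa = rep("V", n))
    w <- sample(c(1, 3, 5, 7, 9), 1)
    prof <- window_scan(rec, protein_length = L, window = w)
    expect_equal(prof$count, brute_window_counts(rec$position, L, w))
  }
})

test_that("class partition sums to the record total", {
  tab <- count_matched_table()
  cls <- classify_mutation(tab$ref_aa, tab$alt_aa)
  counts <- table(factor(cls, levels = c("missense", "silent", "stop")))
  expect_equal(unname(counts[["missense"]]), 134)
  expect_equal(unname(counts[["silent"]]), 51)
  expect_equal(unname(counts[["stop"]]), 12)
  expect_equal(sum(counts), nrow(tab))
  expect_equal(sum(counts), 197)
})

test_that("region statistics report affected fractions and densities", {
  tab <- count_matched_table()
  rs <- region_statistics(tab, data.frame(name = "full", start = 1, end = 273))
  expect_equal(rs$affected_fraction, 100 * 125 / 273, tolerance = 1e-9)
  expect_equal(round(rs$affected_fraction, 1), 45.8)
  expect_equal(rs$n_mutations, 197)

  empty <- region_statistics(tab[0, ], data.frame(name = "r", start = 1, end = 50))
  expect_equal(empty$affected_fraction, 0)
  expect_equal(empty$mutations_per_residue, 0)

  full <- region_statistics(data.frame(position = 1:50, ref_aa = "A",
                                       alt_aa = "V"),
                            data.frame(name = "r", start = 1, end = 50))
  expect_equal(full$affected_fraction, 100)
  expect_equal(full$mutations_per_residue, 1)

  expect_error(region_statistics(tab, data.frame(name = "bad", start = 50,
                                                 end = 10)),
               "inverted")
})

test_that("hotspot calls flag enriched runs only", {
  set.seed(7)
  rec <- data.frame(position = c(rep(60, 12), rep(210, 10),
                                 sample.int(273, 20)),
                    ref_aa = "A", alt_aa = "V")
  prof <- window_scan(rec, protein_length = 273)
  calls <- hotspot_calls(prof)
  expect_gt(nrow(calls), 0)
  covered <- unlist(Map(seq, calls$start, calls$end))
  expect_true(60 %in% covered && 210 %in% covered)
})
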