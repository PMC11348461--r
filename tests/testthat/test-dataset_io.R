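test_that("log_activity matches printed targets and rejects bad input", {
  expect_equal(round(log_activity(68.4), 3), 1.835)
  expect_equal(round(log_activity(33.6), 3), 1.526)
  expect_equal(round(log_activity(90.3), 3), 1.956)
  expect_equal(log_activity(100), 2)
  expect_error(log_activity(0), "outside")
  expect_error(log_activity(101), "outside")
  expect_error(log_activity(-3, compound_id = "cpd7"), "cpd7")
  # strictly increasing on (0, 100]
  x <- sort(runif(200, min = 1e-6, max = 100))
  expect_true(all(diff(log_activity(x)) > 0))
})

test_that("bundled compound table loads with the documented structure", {
  fix <- load_table1_fixture()
  expect_s3_class(fix, "compound_table")
  expect_equal(nrow(fix), 39L)
  expect_equal(sum(fix$is_test), 9L)
  expect_equal(sum(!fix$is_test), 30L)
  expect_setequal(fix$compound_id[fix$is_test],
                  c("1", "5", "8", "10", "12", "16", "18", "25", "29"))
  r1 <- fix[fix$compound_id == "1", ]
  expect_equal(r1$inhibition_pct, 68.4)
  expect_equal(r1$hm_predicted, 1.725)
  expect_equal(r1$gep_model, 1.964)
  expect_true(r1$is_test)
  expect_equal(r1$substituents[[1]][["X"]], "O")
  expect_equal(r1$substituents[[1]][["R1"]], "Ph")
  # round-trip consistency of every stored target
  expect_true(all(abs(fix$target_log -
                        round(log_activity(fix$inhibition_pct), 3)) <= 0.001))
  # scaffold blocks partition the table
  expect_equal(as.vector(table(fix$scaffold_block)), c(16L, 11L, 12L))
})

test_that("fixture audit names the known typographic defects", {
  audit <- table1_audit()
  expect_true(any(grepl("compound 6", audit$where)))
  expect_true(any(grepl("compound 28", audit$where)))
  expect_true(any(grepl("20-26", audit$where)))
  expect_true(any(grepl("test-set GEP", audit$where)))
  expect_true(any(grepl("0.5516", audit$where)))
  fix <- load_table1_fixture()
  expect_equal(fix$printed_inhibition_pct[fix$compound_id == "6"], 41.7)
  expect_equal(fix$inhibition_pct[fix$compound_id == "6"], 47.1)
})

test_that("descriptor tables validate shape, names and finiteness", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("d", 1:4)))
  tab <- descriptor_table(m, rnorm(5))
  expect_s3_class(tab, "descriptor_table")
  expect_equal(dim(tab), c(5L, 4L))
  expect_error(descriptor_table(m, rnorm(4)), "length")
  expect_error(descriptor_table(m, c(1, 2, NA, 4, 5)), "non-finite")
  m2 <- m; m2[2, 3] <- Inf
  expect_error(descriptor_table(m2, rnorm(5)), "non-finite")
  expect_error(descriptor_table(m, rnorm(5),
                                descriptor_names = c("a", "a", "b", "c")),
               "duplicated")
  expect_error(descriptor_table(m, rnorm(5),
                                compound_ids = c("1", "1", "2", "3", "4")),
               "duplicated")
})

test_that("read_descriptor_table parses delimited text and reports defects", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(compound_id = as.character(1:6),
                   act = round(rnorm(6), 4),
                   d1 = round(rnorm(6), 4), d2 = round(rnorm(6), 4))
  write.csv(df, tmp, row.names = FALSE)
  tab <- read_descriptor_table(tmp, activity_column = "act")
  expect_equal(dim(tab), c(6L, 2L))
  expect_equal(tab$descriptor_names, c("d1", "d2"))
  expect_equal(tab$activity, df$act)

  # blank activity cell names the row
  df2 <- df; df2$act[4] <- ""
  write.csv(df2, tmp, row.names = FALSE)
  expect_error(read_descriptor_table(tmp, activity_column = "act"), "4")

  # non-numeric descriptor cell names the row
  df3 <- df; df3$d2[2] <- "NA"
  write.csv(df3, tmp, row.names = FALSE)
  expect_error(read_descriptor_table(tmp, activity_column = "act"), "2")

  # duplicated descriptor names rejected
  writeLines(c("compound_id,act,d1,d1", "1,0.1,1,2", "2,0.2,3,4"), tmp)
  expect_error(read_descriptor_table(tmp, activity_column = "act"),
               "duplicated")
  # missing activity column
  write.csv(df, tmp, row.names = FALSE)
  expect_error(read_descriptor_table(tmp, activity_column = "nope"),
               "not found")
})

test_that("split_dataset partitions reproducibly and honours fixed id lists", {
  tab <- random_table(39, 4, seed = 7)
  s1 <- split_dataset(tab, n_test = 9, seed = 11)
  s2 <- split_dataset(tab, n_test = 9, seed = 11)
  expect_identical(s1, s2)
  expect_length(s1$test_ids, 9L)
  # partition property over several seeds
  for (seed in 1:5) {
    sp <- split_dataset(tab, n_test = 9, seed = seed)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_setequal(c(sp$train_ids, sp$test_ids), tab$compound_ids)
  }
  starred <- c("1", "5", "8", "10", "12", "16", "18", "25", "29")
  fixed <- split_dataset(load_table1_fixture(), test_ids = starred)
  expect_setequal(fixed$test_ids, starred)
  expect_equal(fixed$seed, "fixed")
  expect_length(fixed$train_ids, 30L)
  expect_error(split_dataset(tab, n_test = 39, seed = 1), "n_test")
  expect_error(split_dataset(tab, n_test = 0, seed = 1), "n_test")
})
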