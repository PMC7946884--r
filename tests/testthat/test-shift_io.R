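test_that("delimited shift tables are read, validated and round-tripped", {
  df <- data.frame(residue_id = rep(1:3, each = 2),
                   residue_label = rep(c("G1", "A2", "L3"), each = 2),
                   state = rep(c("apo", "ADP"), 3),
                   delta_H = c(8.31, 8.35, 7.92, 7.90, 9.01, 9.13),
                   delta_N = c(119.42, 119.90, 121.3, 121.1, 108.2, 108.9))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  st <- read_shift_table(f, "csv", states = c("apo", "ADP"))
  expect_s3_class(st, "shift_table")
  expect_equal(nrow(st), 6L)
  expect_equal(shift_states(st), c("apo", "ADP"))

  # round trip preserves every value exactly
  f2 <- tempfile(fileext = ".csv")
  write_shift_table(st, f2)
  st2 <- read_shift_table(f2, "csv", states = shift_states(st))
  expect_identical(st2$delta_H, st$delta_H)
  expect_identical(st2$delta_N, st$delta_N)
  expect_identical(st2$residue_id, st$residue_id)

  # duplicated (residue, state) is an integrity error
  dup <- rbind(df, df[1, ])
  f3 <- tempfile(fileext = ".csv")
  write.csv(dup, f3, row.names = FALSE)
  expect_error(read_shift_table(f3, "csv"), "duplicate")

  # missing required column is a format error
  f4 <- tempfile(fileext = ".csv")
  write.csv(df[, -4], f4, row.names = FALSE)
  expect_error(read_shift_table(f4, "csv"), "missing required column")
})

test_that("unparseable rows are dropped with a message, not an error", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("residue_id,state,delta_H,delta_N",
               "1,apo,8.31,119.4", "2,apo,n/a,120.0", "3,apo,7.95,118.8"), f)
  expect_message(st <- read_shift_table(f, "csv"), "1 row")
  expect_equal(st$residue_id, c(1L, 3L))
})

test_that("Sparky-style peak lists parse the assignment dialect", {
  f <- tempfile(fileext = ".list")
  writeLines(c("Assignment  w1  w2",
               "G55N-H  119.42  8.31",
               "A56N-H  121.07  7.88",
               "not-a-peak  1  2"), f)
  expect_warning(st <- read_shift_table(f, "sparky", state = "apo"),
                 "1 unparsable")
  expect_equal(st$residue_id, c(55L, 56L))
  r55 <- st[st$residue_id == 55L, ]
  expect_equal(r55$delta_N, 119.42)
  expect_equal(r55$delta_H, 8.31)
  expect_equal(r55$residue_label, "G55")
  expect_equal(r55$state, "apo")
})

test_that("complete_residues finds all-state coverage and is order-stable", {
  states <- c("apo", "ADP", "ATPgN", "tern")
  recs <- expand.grid(residue_id = 1:10, state = states,
                      stringsAsFactors = FALSE)
  recs$delta_H <- 8; recs$delta_N <- 115
  # residues 4 and 9 each miss one state
  recs <- recs[!(recs$residue_id == 4 & recs$state == "ADP"), ]
  recs <- recs[!(recs$residue_id == 9 & recs$state == "tern"), ]
  st <- shift_table(recs, states = states)
  expect_equal(complete_residues(st), setdiff(1:10, c(4L, 9L)))
  expect_equal(complete_residues(st, c("apo", "ATPgN")), 1:10)
  expect_error(complete_residues(st, "nosuch"), "unknown state")

  # row order does not matter; the call is idempotent
  shuffled <- shift_table(recs[sample.int(nrow(recs)), ], states = states)
  expect_identical(complete_residues(shuffled), complete_residues(st))
  expect_identical(complete_residues(st), complete_residues(st))
})

test_that("community maps enforce unique assignment", {
  df <- data.frame(residue_id = 1:100,
                   community = rep(c("ComA", "ComB", "ComC", "ComD", "ComE",
                                     "ComF", "ComF1", "ComG", "ComH"),
                                   length.out = 100))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  cm <- read_community_map(f)
  expect_equal(length(community_sizes(cm)), 9L)
  expect_equal(sum(community_sizes(cm)), 100L)

  dup <- rbind(df, data.frame(residue_id = 190, community = "ComF"),
               data.frame(residue_id = 190, community = "ComA"))
  f2 <- tempfile(fileext = ".csv")
  write.csv(dup, f2, row.names = FALSE)
  expect_error(read_community_map(f2), "more than one community")

  f3 <- tempfile(fileext = ".csv")
  writeLines("residue_id,community", f3)
  expect_warning(empty <- read_community_map(f3), "empty")
  expect_equal(nrow(empty), 0L)
})
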