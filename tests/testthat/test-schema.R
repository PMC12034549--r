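test_that("the schema matches the questionnaire encoding", {
  sch <- ppd_schema()
  expect_equal(nrow(sch$attributes), 10)
  expect_equal(sch$attributes$codes[[1]], 1:5)
  for (i in 2:9) expect_equal(sch$attributes$codes[[i]], 1:3)
  expect_equal(sch$attributes$codes[[10]], 1:2)
  expect_equal(sch$target_name, "Feeling anxious")
})

test_that("CSV reading decodes the target and validates codes", {
  sch <- ppd_schema()
  path <- withr::local_tempfile(fileext = ".csv")

  # one all-1 row: target code 1 means anxious -> internal label 1
  writeLines(c(paste(sprintf('"%s"', sch$attributes$name), collapse = ","),
               paste(rep("1", 10), collapse = ",")), path)
  d <- read_ppd(path)
  expect_equal(nrow(d), 1)
  expect_equal(d[["Feeling anxious"]], 1L)

  # target code 2 -> label 0
  writeLines(c(paste(sch$attributes$name, collapse = ","),
               paste(c(rep("1", 9), "2"), collapse = ",")), path)
  expect_equal(read_ppd(path)[["Feeling anxious"]], 0L)

  # Age code 7 is outside {1..5}
  writeLines(c(paste(sch$attributes$name, collapse = ","),
               paste(c("7", rep("1", 9)), collapse = ",")), path)
  expect_error(read_ppd(path), class = "ppd_validation_error")

  # non-integer cell names row and column
  writeLines(c(paste(sch$attributes$name, collapse = ","),
               paste(c("1.5", rep("1", 9)), collapse = ",")), path)
  expect_error(read_ppd(path), "Age", class = "ppd_parse_error")

  # missing column is named in the error
  writeLines(c(paste(sch$attributes$name[-7], collapse = ","),
               paste(rep("1", 9), collapse = ",")), path)
  expect_error(read_ppd(path), "Suicide attempt", class = "ppd_schema_error")
})

test_that("header matching is case/whitespace/order-insensitive and drops extras", {
  sch <- ppd_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- c("EXTRA COLUMN", toupper(sch$attributes$name[10]),
           paste0("  ", sch$attributes$name[1:9], " "))
  writeLines(c(paste(sprintf('"%s"', hdr), collapse = ","),
               paste(c("9", "2", rep("1", 9)), collapse = ",")), path)
  d <- read_ppd(path)
  expect_equal(names(d), sch$attributes$name)
  expect_equal(d[["Feeling anxious"]], 0L)
  expect_false("EXTRA COLUMN" %in% names(d))
})

test_that("write_ppd re-encodes the target and round-trips exactly", {
  d <- tiny_ppd(n = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ppd(d, path)
  # CSV carries questionnaire codes 1/2, not 0/1
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_setequal(unique(raw[["Feeling anxious"]]), c(1L, 2L))
  expect_equal(raw[["Feeling anxious"]],
               ifelse(d[["Feeling anxious"]] == 1L, 1L, 2L))
  expect_equal(as.data.frame(read_ppd(path)), as.data.frame(d))
})

test_that("validation rejects bad datasets before writing", {
  d <- tiny_ppd()
  d$Age[3] <- 9L
  expect_error(write_ppd(d, withr::local_tempfile()), "row 3",
               class = "ppd_validation_error")
  expect_error(validate_ppd(tiny_ppd()[0, ]), class = "ppd_validation_error")
  d2 <- tiny_ppd()
  d2[["Feeling anxious"]][2] <- 5L
  expect_error(validate_ppd(d2), class = "ppd_validation_error")
})

test_that("schema serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(ppd_schema(), path)
  sch <- read_schema(path)
  expect_equal(sch$attributes$name, ppd_schema()$attributes$name)
  expect_equal(sch$attributes$codes, ppd_schema()$attributes$codes)
  expect_equal(sch$positive_code, 1L)
})

test_that("split sizes follow round(n * test_fraction) and ignore the seed", {
  d <- tiny_ppd(n = 10)
  s <- split_ppd(d, train_fraction = 0.7, seed = 1)
  expect_equal(nrow(s$train), 7)
  expect_equal(nrow(s$test), 3)

  big <- generate_ppd(ppd_generator_spec(n = 1503, seed = 5))
  for (sd in c(1, 99)) {
    s <- split_ppd(big, train_fraction = 0.7, seed = sd)
    expect_equal(nrow(s$test), 451)  # round(1503 * 0.3)
    expect_equal(nrow(s$train), 1052)
  }
})

test_that("splits are deterministic, disjoint, exhaustive and stratified", {
  d <- generate_ppd(ppd_generator_spec(n = 200, seed = 2))
  d$id <- seq_len(nrow(d))
  s1 <- split_ppd(d[schema_names], 0.8, seed = 7)
  s2 <- split_ppd(d[schema_names], 0.8, seed = 7)
  expect_identical(s1, s2)

  s <- split_ppd(d, 0.8, seed = 7)
  expect_equal(sort(c(s$train$id, s$test$id)), d$id)

  y <- d[["Feeling anxious"]]
  expect_equal(sum(s$train[["Feeling anxious"]]) +
                 sum(s$test[["Feeling anxious"]]), sum(y))
  # per-class proportions preserved to within rounding
  expect_equal(mean(s$test[["Feeling anxious"]]), mean(y), tolerance = 0.03)
})

test_that("degenerate splits are rejected", {
  d <- tiny_ppd(n = 10)
  expect_error(split_ppd(d, 1.0), class = "ppd_config_error")
  expect_error(split_ppd(d, 0), class = "ppd_config_error")
  expect_error(split_ppd(d[1, ], 0.5), class = "ppd_validation_error")
  expect_error(split_ppd(d, 0.99), class = "ppd_validation_error")
})
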