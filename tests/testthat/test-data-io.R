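test_that("global standardization matches the hand computation and is idempotent", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("L1", "T1")))
  ds <- expression_dataset(m, "L1")
  std <- global_standardize(ds)
  expect_equal(std$scaler$mean, 2.5)
  expect_equal(std$scaler$sd, sqrt(1.25))
  expect_equal(std$dataset$values, (m - 2.5) / sqrt(1.25))
  expect_lt(abs(mean(std$dataset$values)), 1e-10)
  expect_lt(abs(sqrt(mean(std$dataset$values^2)) - 1), 1e-10)
  # idempotence
  again <- global_standardize(std$dataset)
  expect_equal(again$dataset$values, std$dataset$values, tolerance = 1e-10)
  # inverse round trip
  back <- inverse_standardize(std$dataset, std$scaler)
  expect_equal(back$values, m, tolerance = 1e-10)
})

test_that("per-gene structure survives global standardization", {
  withr::local_seed(1)
  big <- rnorm(50, 0, 10); small <- rnorm(50, 0, 0.01)
  m <- cbind(L1 = rnorm(50), big = big, small = small)
  rownames(m) <- sprintf("s%02d", 1:50)
  std <- global_standardize(expression_dataset(m, "L1"))
  v <- apply(std$dataset$values, 2, var)
  expect_gt(v[["big"]], 100 * v[["small"]])  # no per-gene rescaling happened
  const <- expression_dataset(matrix(5, 3, 2,
                                     dimnames = list(letters[1:3], c("L1", "T1"))),
                              "L1")
  expect_error(global_standardize(const),
               class = "taafgex_degenerate_scale_error")
})

test_that("random splits follow largest-remainder sizes and are order-stable", {
  ds <- random_dataset(n = 10, seed = 1)
  sp <- random_split(ds, c(0.7, 0.15, 0.15), seed = 3)
  expect_equal(nrow(sp$train$values), 7)
  expect_equal(nrow(sp$validation$values), 2)  # tie goes to the earlier split
  expect_equal(nrow(sp$test$values), 1)
  all_ids <- c(rownames(sp$train$values), rownames(sp$validation$values),
               rownames(sp$test$values))
  expect_setequal(all_ids, rownames(ds$values))
  expect_false(anyDuplicated(all_ids) > 0)
  # permutation of sample order leaves the split unchanged
  perm <- ds
  ord <- rev(seq_len(nrow(ds$values)))
  perm$values <- perm$values[ord, ]
  sp2 <- random_split(perm, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(rownames(sp$train$values), rownames(sp2$train$values))
  expect_error(random_split(ds, c(1, 0, 0), seed = 1),
               class = "taafgex_argument_error")
})

test_that("series-grouped splitting assigns whole series greedily", {
  withr::local_seed(4)
  series <- rep(c("A", "B", "C"), times = c(6, 2, 2))
  ds <- random_dataset(n = 10, seed = 2, series = series)
  sp <- group_aware_split(ds, c(0.6, 0.2, 0.2), seed = 1)
  expect_setequal(unique(sp$train$series), "A")
  expect_length(unique(sp$validation$series), 1)
  expect_length(unique(sp$test$series), 1)
  expect_setequal(c(unique(sp$validation$series), unique(sp$test$series)),
                  c("B", "C"))
})

test_that("series never straddle splits and fractions track targets", {
  withr::local_seed(10)
  for (i in 1:30) {
    n_series <- sample(12:25, 1)
    sizes <- sample(1:8, n_series, replace = TRUE)
    n <- sum(sizes)
    series <- rep(sprintf("G%02d", seq_len(n_series)), times = sizes)
    ds <- random_dataset(n = n, seed = i, series = sample(series))
    sp <- suppressWarnings(group_aware_split(ds, seed = i))
    for (pair in list(c("train", "validation"), c("train", "test"),
                      c("validation", "test"))) {
      expect_length(intersect(unique(sp[[pair[1]]]$series),
                              unique(sp[[pair[2]]]$series)), 0)
    }
    expect_setequal(c(rownames(sp$train$values), rownames(sp$validation$values),
                      rownames(sp$test$values)), rownames(ds$values))
    if (max(sizes) <= 0.2 * n) {
      realized <- attr(sp, "realized_fractions")
      expect_lt(max(abs(realized - c(0.7, 0.15, 0.15))), 0.05)
    }
  }
})

test_that("degenerate series structures are reported, not silently accepted", {
  series <- rep(c("BIG", "b", "c"), times = c(18, 1, 1))
  ds <- random_dataset(n = 20, seed = 3, series = series)
  expect_warning(group_aware_split(ds, seed = 1), "deviate")
  two <- random_dataset(n = 6, seed = 4, series = rep(c("x", "y"), 3))
  expect_error(group_aware_split(two, seed = 1),
               class = "taafgex_infeasibility_error")
  # samples without series labels are dropped first
  series_na <- c(rep("A", 8), rep("B", 5), rep("C", 5), NA, NA)
  ds_na <- random_dataset(n = 20, seed = 5, series = series_na)
  expect_message(sp <- suppressWarnings(group_aware_split(ds_na, seed = 1)),
                 "without a series label")
  expect_equal(nrow(sp$train$values) + nrow(sp$validation$values) +
                 nrow(sp$test$values), 18)
})

test_that("GCT and TSV files round-trip ids exactly and values to 1e-8", {
  ds <- random_dataset(n = 5, n_landmarks = 3, n_targets = 4, seed = 6)
  for (fmt in c("gct", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    lm_path <- withr::local_tempfile(fileext = ".txt")
    write_expression(ds, path, format = fmt, landmark_file = lm_path)
    back <- read_expression(path, lm_path)
    expect_identical(rownames(back$values), rownames(ds$values))
    expect_identical(colnames(back$values), colnames(ds$values))
    expect_identical(back$landmark_ids, ds$landmark_ids)
    expect_equal(back$values, ds$values, tolerance = 1e-8)
  }
})

test_that("malformed expression files fail with located format errors", {
  lm_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("L1"), lm_path)
  # GCT with dimensions that disagree with the body
  bad_gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t2", "NAME\tDescription\ts1\ts2",
               "L1\tna\t1\t2", "T1\tna\t3\t4"), bad_gct)
  expect_error(read_expression(bad_gct, lm_path, format = "gct"),
               class = "taafgex_format_error")
  # TSV with a duplicated gene column names the offender
  bad_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tL1\tT1\tT1", "s1\t1\t2\t3", "s2\t4\t5\t6"), bad_tsv)
  expect_error(read_expression(bad_tsv, lm_path, format = "tsv"), "T1",
               class = "taafgex_format_error")
  # ragged row is reported with its line number
  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tL1\tT1", "s1\t1\t2", "s2\t4"), ragged)
  expect_error(read_expression(ragged, lm_path, format = "tsv"), "line 3",
               class = "taafgex_format_error")
})

test_that("dataset construction validates roles and metadata lengths", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_error(expression_dataset(m, c("a", "b", "c")),
               class = "taafgex_schema_error")  # no targets left
  expect_error(expression_dataset(m, "zz"), class = "taafgex_schema_error")
  expect_error(expression_dataset(m, "a", series = "only-one"),
               class = "taafgex_dimension_error")
  ds <- expression_dataset(m, "a", phenotype = c("x", "y"))
  tb <- tibble::as_tibble(ds)
  expect_equal(nrow(tb), 6)
  expect_setequal(unique(tb$role[tb$gene_id == "a"]), "landmark")
})
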