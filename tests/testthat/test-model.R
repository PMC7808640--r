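test_that("network building is deterministic with chained shapes and bounded weights", {
  spec <- architecture_spec(5, 3, n_hidden_layers = 1, width = 4)
  n1 <- build_network(spec, seed = 7)
  n2 <- build_network(spec, seed = 7)
  expect_identical(n1, n2)
  expect_equal(dim(n1$layers[[1]]$W), c(5L, 4L))
  expect_equal(dim(n1$layers[[2]]$W), c(4L, 3L))
  # normalized-initialization bound over several seeds and depths
  for (s in 1:20) {
    spec2 <- architecture_spec(6, 2, n_hidden_layers = 2, width = 5,
                               hidden_mode = "taaf")
    net <- build_network(spec2, seed = s)
    dims <- c(6, 5, 5, 2)
    for (k in seq_along(net$layers)) {
      lim <- sqrt(6 / (dims[k] + dims[k + 1]))
      expect_true(all(abs(net$layers[[k]]$W) <= lim))
    }
  }
})

test_that("forward pass matches hand evaluation of a single TAAF unit", {
  spec <- architecture_spec(2, 1, width = 1, dropout_rate = 0,
                            inner_kind = "tanh", hidden_mode = "taaf",
                            output_mode = "linear")
  net <- build_network(spec, seed = 1)
  net$layers[[1]]$W <- matrix(c(0.5, -0.25), 2, 1)
  net$layers[[1]]$taaf <- taaf_parameters(2, 1, 0.5, -1)
  net$layers[[2]]$W <- matrix(1, 1, 1)
  net$layers[[2]]$bias <- 0
  out <- forward(net, matrix(c(1, 2), 1, 2))
  expect_equal(out[1, 1], 2 * tanh(0.5) - 1)
})

test_that("TAAF network at initialization equals its fixed-activation twin", {
  spec_t <- architecture_spec(4, 3, n_hidden_layers = 2, width = 5,
                              inner_kind = "sigmoid", hidden_mode = "taaf")
  spec_f <- spec_t; spec_f$hidden_mode <- "fixed"
  nt <- build_network(spec_t, seed = 3)
  nf <- build_network(spec_f, seed = 3)  # same seed -> same weights
  X <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(forward(nt, X), forward(nf, X), tolerance = 1e-15)
})

test_that("dropout is inactive and deterministic at evaluation, active in training", {
  spec <- architecture_spec(3, 2, width = 6, dropout_rate = 0.25)
  net <- build_network(spec, seed = 2)
  X <- matrix(rnorm(15), 5, 3)
  expect_identical(forward(net, X), forward(net, X))
  tr1 <- forward(net, X, training = TRUE, seed = 4)
  tr2 <- forward(net, X, training = TRUE, seed = 4)
  expect_identical(tr1, tr2)
  expect_false(isTRUE(all.equal(tr1, forward(net, X))))
  expect_error(forward(net, matrix(0, 2, 5)), class = "taafgex_dimension_error")
})

test_that("parameter counting follows the unit conventions", {
  base <- architecture_spec(3, 1, width = 2, hidden_mode = "fixed",
                            output_mode = "linear")
  expect_equal(parameter_count(base), 11)           # (3+1)*2 + (2+1)*1
  taaf_h <- base; taaf_h$hidden_mode <- "taaf"
  expect_equal(parameter_count(taaf_h), 17)         # 2*(3+4) + (2+1)
  taaf_ho <- taaf_h; taaf_ho$output_mode <- "taaf"
  expect_equal(parameter_count(taaf_ho), 20)        # 14 + (2+4)
})

test_that("parameter counts agree with brute-force enumeration of stored arrays", {
  withr::local_seed(5)
  for (i in 1:50) {
    spec <- architecture_spec(
      input_dim = sample(2:6, 1), output_dim = sample(1:5, 1),
      n_hidden_layers = sample(1:3, 1), width = sample(1:7, 1),
      inner_kind = sample(c("tanh", "sigmoid"), 1),
      hidden_mode = sample(c("fixed", "taaf"), 1),
      output_mode = sample(c("linear", "taaf"), 1),
      adaptivity_mask = unlist(sample(taaf_variants(), 1)))
    net <- build_network(spec, seed = i)
    expect_equal(parameter_count(spec), brute_param_count(net))
    expect_equal(parameter_count(spec, trainable_only = TRUE),
                 brute_param_count(net, trainable_only = TRUE))
  }
})

test_that("capacity matching finds the largest width within the parameter budget", {
  ref <- architecture_spec(5, 3, width = 10, hidden_mode = "fixed")
  expect_equal(parameter_count(ref), 93)
  tmpl <- architecture_spec(5, 3, width = 1, hidden_mode = "taaf")
  expect_equal(capacity_matched_width(ref, tmpl), 7)
  # sandwich property on random reference specs
  withr::local_seed(9)
  for (i in 1:20) {
    r <- architecture_spec(sample(3:8, 1), sample(2:6, 1),
                           n_hidden_layers = sample(1:3, 1),
                           width = sample(4:30, 1), hidden_mode = "fixed")
    t0 <- architecture_spec(r$input_dim, r$output_dim,
                            n_hidden_layers = r$n_hidden_layers,
                            width = 1, hidden_mode = "taaf")
    w <- capacity_matched_width(r, t0)
    at <- function(wi) { t1 <- t0; t1$width <- wi; parameter_count(t1) }
    expect_lte(at(w), parameter_count(r))
    expect_gt(at(w + 1L), parameter_count(r))
  }
})

test_that("a gamma-only trainable TAAF template has equal per-unit cost to the reference", {
  # fan_in + 1 trainable values per unit on both sides -> matched width is the
  # reference width exactly
  ref <- architecture_spec(7, 4, n_hidden_layers = 2, width = 12,
                           hidden_mode = "fixed")
  tmpl <- architecture_spec(7, 4, n_hidden_layers = 2, width = 1,
                            hidden_mode = "taaf", adaptivity_mask = "gamma")
  expect_equal(capacity_matched_width(ref, tmpl, trainable_only = TRUE), 12)
  expect_error(
    capacity_matched_width(architecture_spec(5, 3, width = 2),
                           architecture_spec(4, 3, width = 1)),
    class = "taafgex_argument_error")
})

test_that("target-gene splitting halves the set deterministically", {
  ids <- sprintf("g%05d", 1:9518)
  halves <- split_target_genes(ids, seed = 1)
  expect_equal(lengths(halves), c(half1 = 4759L, half2 = 4759L))
  expect_setequal(c(halves$half1, halves$half2), ids)
  expect_length(intersect(halves$half1, halves$half2), 0)
  expect_identical(halves, split_target_genes(rev(ids), seed = 1))
  odd <- split_target_genes(letters[1:5], seed = 2)
  expect_equal(sort(lengths(odd), decreasing = TRUE), c(3L, 2L),
               ignore_attr = TRUE)
  expect_error(split_target_genes("a", seed = 1),
               class = "taafgex_argument_error")
})

test_that("checkpoints round-trip through the JSON archive", {
  spec <- architecture_spec(3, 2, width = 4, inner_kind = "sigmoid",
                            hidden_mode = "taaf", output_mode = "taaf",
                            adaptivity_mask = c("alpha", "delta"))
  net <- build_network(spec, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_equal(back$spec, net$spec)
  expect_equal(back$seed, net$seed)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(forward(back, X), forward(net, X), tolerance = 1e-12)
})
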