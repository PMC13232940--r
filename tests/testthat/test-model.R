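test_that("category probabilities follow the tree branch products", {
  # certain detection forces the detection response
  expect_equal(category_probs(c(dP = 1, dA = 0.2, b = 0.9, g = 0.9),
                              "culprit_present"),
               c(suspect = 1, filler = 0, rejection = 0))
  # no detection, no bias, no guessing: rejection with certainty, both trees
  p0 <- c(dP = 0, dA = 0, b = 0, g = 0)
  for (tree in c("culprit_present", "culprit_absent"))
    expect_equal(category_probs(p0, tree),
                 c(suspect = 0, filler = 0, rejection = 1))
  # direct expansion of the three branch products, computed independently
  cc <- 0.16667
  p <- category_probs(c(dP = 0, dA = 0, b = 0.06, g = 0.44), "culprit_present",
                      guess_split = cc)
  expect_equal(unname(p),
               c(0.06 + 0.94 * 0.44 * cc,
                 0.94 * 0.44 * (1 - cc),
                 0.94 * 0.56),
               tolerance = 1e-12)
  expect_equal(round(unname(p[1]), 5), 0.12893)
})

test_that("category probabilities are a simplex on a parameter grid and obey monotonicity", {
  grid <- seq(0, 1, length.out = 20)
  worst_sum <- 0
  out_of_range <- 0L
  for (tree in c("culprit_present", "culprit_absent")) {
    for (dP in grid) for (dA in grid) for (b in grid) for (g in grid) {
      p <- lineup2ht:::.category_probs(dP, dA, b, g, tree, 0.16667)
      worst_sum <- max(worst_sum, abs(sum(p) - 1))
      out_of_range <- out_of_range + any(p < 0 | p > 1)
    }
  }
  expect_lt(worst_sum, 1e-12)
  expect_equal(out_of_range, 0L)
  # p_suspect non-decreasing in dP, b, g on the culprit-present tree
  fine <- seq(0, 1, length.out = 41)
  base <- c(dP = 0.3, dA = 0.1, b = 0.2, g = 0.4)
  for (par in c("dP", "b", "g")) {
    ps <- vapply(fine, function(v) {
      q <- base; q[par] <- v
      category_probs(q, "culprit_present")[["suspect"]]
    }, numeric(1))
    expect_true(all(diff(ps) >= -1e-12))
  }
  # p_reject non-decreasing in dA on the culprit-absent tree
  pr <- vapply(fine, function(v)
    category_probs(replace(base, "dA", v), "culprit_absent")[["rejection"]],
    numeric(1))
  expect_true(all(diff(pr) >= -1e-12))
  # with dP = dA, filler selection depends only on the non-detection mass
  for (d in seq(0, 1, by = 0.25)) for (b in c(0, 0.3)) for (g in c(0.2, 0.9)) {
    q <- c(dP = d, dA = d, b = b, g = g)
    expect_equal(category_probs(q, "culprit_present")[["filler"]],
                 category_probs(q, "culprit_absent")[["filler"]])
  }
})

test_that("invalid parameters and degenerate guessing splits are rejected by name", {
  expect_error(category_probs(c(dP = 1.2, dA = 0, b = 0, g = 0),
                              "culprit_present"), "dP")
  expect_error(category_probs(c(dP = 0.5, dA = -0.1, b = 0, g = 0),
                              "culprit_absent"), "dA")
  for (cc in c(0, 1, -0.2, 1.5))
    expect_error(category_probs(c(dP = 0.5, dA = 0.1, b = 0, g = 0),
                                "culprit_present", guess_split = cc),
                 "guess_split")
  expect_error(mpt_model("a", guess_split = 1), "guess_split")
})

test_that("model building assigns deterministic contiguous free indices", {
  m2 <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  expect_equal(m2$n_free, 6L)
  expect_equal(m2$free_labels,
               c("dP[combined]", "dP[separate]", "dA", "b",
                 "g[combined]", "g[separate]"))
  m4 <- mpt_model(paste0("c", 1:4), equal = list(b = "all", dA = "all"))
  expect_equal(m4$n_free, 10L)  # 16 slots minus two 3-merge constraints
  m1 <- mpt_model("only")
  expect_equal(m1$n_free, 4L)
  expect_identical(sort(unique(as.integer(m2$index))), 1:6)
  # unknown names rejected
  expect_error(mpt_model(c("a", "b"), equal = list(z = "all")), "unknown")
  expect_error(mpt_model(c("a", "b"), equal = list(b = list(c("a", "c")))),
               "unknown condition")
  expect_error(mpt_model(c("a", "b"), fixed = list(dA = c(q = 0.1))),
               "unknown condition")
  expect_error(mpt_model(c("a", "a")), "unique")
})

test_that("expand_params honors sharing and fixed values; collapse inverts it", {
  m1 <- mpt_model("only")
  expect_equal(expand_params(c(0.3, 0.1, 0.06, 0.44), m1)["only", ],
               c(dP = 0.3, dA = 0.1, b = 0.06, g = 0.44))
  m2 <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  pm <- expand_params(c(0.3, 0.28, 0.05, 0.06, 0.44, 0.42), m2)
  expect_equal(pm[, "b"], c(combined = 0.06, separate = 0.06))
  expect_equal(pm[, "dA"], c(combined = 0.05, separate = 0.05))
  expect_equal(pm[, "dP"], c(combined = 0.3, separate = 0.28))
  # fixed value wins regardless of the free vector
  mf <- mpt_model(c("a", "b"), fixed = list(dA = 0))
  expect_true(all(expand_params(runif(mf$n_free), mf)[, "dA"] == 0))
  expect_error(expand_params(c(0.1, 0.2), m2), "6 free parameters")
  # expand after collapse of a consistent assignment is the identity
  set.seed(42)
  for (i in 1:20) {
    theta <- runif(m2$n_free)
    expect_equal(lineup2ht:::collapse_params(expand_params(theta, m2), m2),
                 theta)
  }
})

test_that("fixed values propagate through equality groups and conflicts error", {
  m <- mpt_model(c("a", "b", "c"), equal = list(dA = list(c("a", "b"))),
                 fixed = list(dA = c(a = 0.1)))
  expect_equal(m$fixed_values["dA", ], c(a = 0.1, b = 0.1, c = NA))
  expect_error(
    mpt_model(c("a", "b"), equal = list(dA = "all"),
              fixed = list(dA = c(a = 0.1, b = 0.2))),
    "conflicting")
  expect_error(mpt_model("a", fixed = list(b = 1.5)), "\\[0, 1\\]")
})

test_that("add_equality merges overlapping groups into a nested model", {
  m <- mpt_model(paste0("c", 1:4), equal = list(b = "all", dA = "all"))
  r1 <- add_equality(m, "dP", c("c2", "c3", "c4"))
  expect_equal(r1$n_free, m$n_free - 2L)
  r2 <- add_equality(r1, "dP", c("c1", "c2"))  # chains onto the pooled group
  expect_equal(r2$n_free, r1$n_free - 1L)
  expect_equal(length(unique(r2$index["dP", ])), 1L)
  expect_error(add_equality(m, "nope", "all"), "unknown parameter")
})

test_that("model configuration files round-trip through the YAML schema", {
  path <- system.file("extdata", "exp1_model.yaml", package = "lineup2ht")
  m <- read_model_config(path)
  direct <- mpt_model(c("combined", "separate"),
                      equal = list(b = "all", dA = "all"),
                      guess_split = 0.16667)
  expect_identical(m$index, direct$index)
  expect_identical(m$guess_split, direct$guess_split)
  m4 <- read_model_config(system.file("extdata", "exp2_model.yaml",
                                      package = "lineup2ht"))
  expect_equal(m4$n_free, 10L)
  # json config with fixed values
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(conditions = c("a", "b"),
                            equal = list(b = "all"),
                            fixed = list(dA = 0)),
                       tmp, auto_unbox = TRUE)
  mj <- read_model_config(tmp)
  expect_equal(mj$n_free, 5L)
  expect_true(all(mj$fixed_values["dA", ] == 0))
})

test_that("EQN export writes one line per branch with shared symbols", {
  m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  tmp <- withr::local_tempfile(fileext = ".eqn")
  write_eqn(m, tmp)
  lines <- readLines(tmp)
  expect_equal(as.integer(lines[1]), length(lines) - 1L)
  expect_equal(length(lines) - 1L, 10L * 2L)  # 10 branches per condition
  fields <- strsplit(lines[-1], " ")
  expect_true(all(lengths(fields) == 3L))
  # shared b carries one symbol, condition-specific g two
  terms <- vapply(fields, `[`, "", 3L)
  expect_true(any(grepl("^\\(1-dP_combined_\\)\\*b$", terms)))
  expect_true(any(grepl("g_separate_", terms)))
})
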