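test_that("normalise_axis matches its closed-form contracts", {
  expect_equal(normalise_axis(c(0, 5, 10), "minmax"), c(0, 0.5, 1))
  expect_equal(normalise_axis(c(10, 20, 30), "rank"), c(0, 0.5, 1))
  for (m in c("minmax", "rank", "zscore"))
    expect_equal(normalise_axis(c(7, 7, 7), m), c(0.5, 0.5, 0.5))
  # missing stays missing, observed values still normalised
  out <- normalise_axis(c(1, NA, 3), "minmax")
  expect_identical(is.na(out), c(FALSE, TRUE, FALSE))
  expect_equal(out[c(1, 3)], c(0, 1))
  expect_error(normalise_axis(letters[1:3]), class = "pcptiles_contract_error")
})

test_that("count_crossings agrees with the quadratic oracle (with ties and NAs)", {
  expect_identical(count_crossings(c(0.1, 0.9), c(0.1, 0.9)), 0)
  expect_identical(count_crossings(c(0.1, 0.9), c(0.9, 0.1)), 1)
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(2:64, 1)
    a <- round(runif(n), 1)            # rounding forces ties
    b <- round(runif(n), 1)
    a[runif(n) < 0.1] <- NA
    b[runif(n) < 0.1] <- NA
    expect_equal(count_crossings(a, b), oracle_count_crossings(a, b))
    expect_equal(count_crossings(a, b), count_crossings(b, a))
  }
  expect_error(count_crossings(1:3, 1:4), class = "pcptiles_contract_error")
})

test_that("crossing counts are invariant to monotone transforms under rank scaling", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(40)
    y <- rnorm(40)
    base <- count_crossings(normalise_axis(x, "rank"), normalise_axis(y, "rank"))
    expect_identical(
      count_crossings(normalise_axis(exp(x), "rank"), normalise_axis(y, "rank")),
      base)
    expect_identical(
      count_crossings(normalise_axis(x, "rank"), normalise_axis(y^3, "rank")),
      base)
  }
})

test_that("crossing_matrix matches the per-pair oracle and trivial cases", {
  t <- as_typed_table(data.frame(a = c(1, 2, 3), b = c(1, 2, 3),
                                 neg = c(3, 2, 1), stringsAsFactors = FALSE),
                      overrides = list(a = "numeric", b = "numeric",
                                       neg = "numeric"))
  cm <- crossing_matrix(t)
  expect_equal(cm$counts["a", "b"], 0)
  expect_equal(cm$counts["a", "neg"], choose(3, 2))  # full inversion
  expect_equal(cm$counts, t(cm$counts))
  expect_equal(unname(diag(cm$counts)), rep(0, 3))

  tt <- gen_correlated_numeric(40, seed = 21, diag(4))
  cm2 <- crossing_matrix(tt)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- normalise_axis(tt$values[[i]], "minmax")
    b <- normalise_axis(tt$values[[j]], "minmax")
    expect_equal(unname(cm2$counts[i, j]), oracle_count_crossings(a, b))
  }
  t_cat <- as_typed_table(data.frame(x = c("a", "b"), stringsAsFactors = FALSE))
  expect_error(crossing_matrix(t_cat, axes = "x"),
               class = "pcptiles_contract_error")
})

test_that("order_axes_min_crossings is exact for small k with canonical ties", {
  one <- structure(list(axes = "only", counts = matrix(0, 1, 1)),
                   class = "crossing_matrix")
  expect_identical(order_axes_min_crossings(one), "only")
  # all-equal counts: every ordering ties, identity is the canonical pick
  m <- matrix(7, 4, 4); diag(m) <- 0
  cm <- structure(list(axes = letters[1:4], counts = m),
                  class = "crossing_matrix")
  expect_identical(order_axes_min_crossings(cm), letters[1:4])
  # seeded k = 5 instances against exhaustive enumeration
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(sample(0:30, 25, replace = TRUE), 5, 5)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    cm <- structure(list(axes = paste0("c", 1:5), counts = m),
                    class = "crossing_matrix")
    ord <- order_axes_min_crossings(cm)
    idx <- match(ord, cm$axes)
    expect_equal(path_cost_of(m, idx), oracle_min_path_cost(m))
    expect_true(idx[1] < idx[5])  # reversal canonicalisation
  }
  bad <- structure(list(axes = c("a", "b"),
                        counts = matrix(c(0, 1, 2, 0), 2, 2)),
                   class = "crossing_matrix")
  expect_error(order_axes_min_crossings(bad),
               class = "pcptiles_contract_error")
})

test_that("heuristic regime (k > 8) never underperforms the input order", {
  set.seed(77)
  for (rep in 1:5) {
    k <- 12
    m <- matrix(sample(0:100, k * k, replace = TRUE), k, k)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    cm <- structure(list(axes = sprintf("c%02d", 1:k), counts = m),
                    class = "crossing_matrix")
    ord <- order_axes_min_crossings(cm)
    idx <- match(ord, cm$axes)
    expect_lte(path_cost_of(m, idx), path_cost_of(m, seq_len(k)))
    expect_setequal(idx, seq_len(k))
  }
})

test_that("mutual_information matches closed forms and the plug-in oracle", {
  labels <- rep(c("A", "B"), each = 50)
  expect_warning(mi0 <- mutual_information(rep(1, 100), labels, 2), NA)
  expect_identical(mi0, 0)  # constant feature: zero-entropy marginal
  # strictly separated classes, equal-frequency split at the boundary
  feature <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  expect_equal(mutual_information(feature, labels, 2), 1, tolerance = 1e-12)
  # fixed 2x2 joint counts (30,20 / 20,30) vs the hand-evaluated sum
  f <- rep(c(0, 1), each = 50)
  l <- c(rep("A", 30), rep("B", 20), rep("A", 20), rep("B", 30))
  expected <- oracle_mi_from_table(matrix(c(30, 20, 20, 30), 2, byrow = TRUE))
  expect_equal(mutual_information(f, l, 2), expected, tolerance = 1e-12)
  expect_equal(expected,
               0.6 * log2(1.2) + 0.4 * log2(0.8), tolerance = 1e-12)
  # degenerate inputs warn and return 0
  expect_warning(v <- mutual_information(1, "A", 2), "degenerate")
  expect_identical(v, 0)
  expect_warning(v2 <- mutual_information(c(1, 2), c("A", "A"), 2), "degenerate")
  expect_identical(v2, 0)
})

test_that("mutual_information is non-negative and bounded for independent draws", {
  set.seed(13)
  vals <- replicate(20, {
    x <- rnorm(1000)
    y <- sample(c("A", "B"), 1000, replace = TRUE)
    mutual_information(x, y, 4)
  })
  expect_true(all(vals >= 0))
  expect_lt(median(vals), 0.05)  # estimator bias stays small at n = 1000
  expect_true(all(vals <= 2))    # <= min(log2 bins, log2 labels) + slack
})

test_that("order_axes_by_mi ranks informative axes first and tie-breaks stably", {
  t <- as_typed_table(data.frame(
    info = c(rep(0, 10), rep(9, 10)) + seq(0, 0.19, by = 0.01),
    flat = rep(5, 20),
    cls = rep(c("A", "B"), each = 10), stringsAsFactors = FALSE),
    overrides = list(info = "numeric", flat = "numeric"))
  suppressWarnings(r <- order_axes_by_mi(t, class_column = "cls", n_bins = 2))
  expect_identical(r$column[1], "info")
  # identical axes tie: original column order preserved
  t2 <- as_typed_table(data.frame(a = c(1.1, 2.2, 3.3, 4.4), b = c(1.1, 2.2, 3.3, 4.4),
                                  g = c("x", "x", "y", "y"),
                                  stringsAsFactors = FALSE))
  r2 <- order_axes_by_mi(t2, class_column = "g", n_bins = 2)
  expect_identical(r2$column, c("a", "b"))
  expect_error(order_axes_by_mi(t2, class_column = "a"),
               class = "pcptiles_contract_error")
})

test_that("build_pcp_layout drops and reports incomplete rows, flags highlights", {
  t <- as_typed_table(data.frame(x = c(1.5, 2.5, 3.5), y = c(4.5, 5.5, 6.5),
                                 stringsAsFactors = FALSE))
  lay <- build_pcp_layout(t, ordering = "given")
  expect_identical(dim(lay$polylines), c(3L, 2L))
  expect_identical(lay$dropped_rows, integer(0))

  t2 <- as_typed_table(data.frame(x = c(1.5, NA, 3.5), y = c(4.5, 5.5, 6.5),
                                  stringsAsFactors = FALSE))
  lay2 <- build_pcp_layout(t2)
  expect_identical(lay2$dropped_rows, 2L)
  expect_identical(nrow(lay2$polylines), 2L)

  t3 <- as_typed_table(data.frame(
    x = round(rnorm(9), 2), y = round(rnorm(9), 2),
    kind = rep(c("Dermason", "Bombay", "Cali"), 3), stringsAsFactors = FALSE))
  lay3 <- build_pcp_layout(t3, colour_feature = "kind",
                           highlight_level = "Dermason")
  expect_identical(lay3$foreground, t3$values$kind == "Dermason")

  expect_error(build_pcp_layout(t, axes = "x"), class = "pcptiles_input_error")
  expect_error(build_pcp_layout(t, ordering = "mi"),
               class = "pcptiles_config_error")
  expect_error(build_pcp_layout(t3, colour_feature = "kind",
                                highlight_level = "nope"),
               class = "pcptiles_config_error")
})

test_that("polyline vertex counts are conserved across random fixtures", {
  for (seed in 1:15) {
    t <- random_mixed_table(n = 40, seed = seed + 100)
    lay <- build_pcp_layout(t)
    k <- nrow(lay$axes)
    expect_identical(length(lay$polylines),
                     (t$n_rows - length(lay$dropped_rows)) * k)
    expect_true(all(lay$polylines >= 0 & lay$polylines <= 1))
  }
})

test_that("pcp layout serialises to the documented JSON shape", {
  t <- as_typed_table(data.frame(x = c(1.5, 2.5), y = c(3.5, 4.5),
                                 stringsAsFactors = FALSE))
  j <- jsonlite::fromJSON(pcp_layout_json(build_pcp_layout(t)))
  expect_named(j, c("axes", "polylines", "row_index", "colour_feature",
                    "colour_values", "highlight_level", "foreground",
                    "dropped_rows"), ignore.order = TRUE)
  expect_identical(nrow(j$axes), 2L)
})
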