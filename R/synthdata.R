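# synthdata: seeded generators for every fixture the tests and docs need.
#
# All generators draw under a private RNG state (the caller's random stream
# is untouched) and are byte-reproducible: the same spec and seed always
# yield the same table, hence the same written CSV.

#' Generate the birdwatcher missingness fixture
#'
#' A magpie-observation log kept by two birdwatchers, one of whom
#' ("Robin", the lazy observer) skips birdwatching on weekends. Observer
#' and day type are assigned uniformly at random; magpie counts are
#' Poisson with observer-specific rates (Morgan 9, Robin 4 birds/outing).
#' The count is drawn first and then masked, so missingness depends only
#' on the observed pair (Birdwatcher, Day) - a missing-at-random
#' mechanism: with probability `p_skip` the count is missing exactly on
#' rows where `Birdwatcher == "Robin"` and `Day == "Weekend"`, and never
#' anywhere else.
#'
#' @param n_rows Number of outings (default 120).
#' @param seed Integer seed; fully determines the output.
#' @param p_skip Probability in `[0,1]` that a lazy-observer weekend count
#'   is missing (default 1).
#' @return A `typed_table` with columns `Magpies` (numeric), `Birdwatcher`
#'   and `Day` (categorical).
#' @export
gen_lazy_birdwatcher <- function(n_rows = 120L, seed = 1L, p_skip = 1) {
  if (!is.numeric(n_rows) || n_rows < 1)
    stop_contract("gen_lazy_birdwatcher: n_rows must be >= 1")
  if (!is.numeric(p_skip) || length(p_skip) != 1L || is.na(p_skip) ||
      p_skip < 0 || p_skip > 1)
    stop_contract("gen_lazy_birdwatcher: p_skip must lie in [0,1]")
  n <- as.integer(n_rows)
  with_seed(seed, {
    observer <- sample(c("Morgan", "Robin"), n, replace = TRUE)
    day <- sample(c("Weekday", "Weekend"), n, replace = TRUE)
    rate <- ifelse(observer == "Morgan", 9, 4)
    magpies <- stats::rpois(n, rate)
    skip <- observer == "Robin" & day == "Weekend" &
      stats::runif(n) < p_skip
    magpies[skip] <- NA_integer_
    df <- data.frame(Magpies = magpies, Birdwatcher = observer, Day = day,
                     stringsAsFactors = FALSE)
    as_typed_table(df, overrides = list(Magpies = "numeric",
                                        Birdwatcher = "categorical",
                                        Day = "categorical"))
  })
}

#' Generate a labelled Gaussian class-mixture fixture
#'
#' Balanced classes; each informative feature has class-specific means
#' spaced `separation` standard deviations apart plus unit Gaussian noise;
#' noise features are standard Gaussian, independent of class. Feature
#' column order is shuffled per seed so axis-ordering tests cannot rely on
#' column position.
#'
#' @param n_rows Number of samples.
#' @param seed Integer seed.
#' @param k_classes Number of classes (>= 2; default 2).
#' @param n_informative Number of class-informative numeric features.
#' @param n_noise Number of class-independent numeric features.
#' @param separation Distance between adjacent class means in standard
#'   deviations (> 0 unless deliberately degenerate at 0).
#' @return A `typed_table` with a categorical `class` column and numeric
#'   features named `signal_*` / `noise_*`.
#' @export
gen_class_mixture <- function(n_rows, seed = 1L, k_classes = 2L,
                              n_informative = 3L, n_noise = 5L,
                              separation = 3) {
  if (k_classes < 2) stop_contract("gen_class_mixture: k_classes must be >= 2")
  if (n_informative < 0 || n_noise < 0 || n_informative + n_noise < 1)
    stop_contract("gen_class_mixture: need at least one feature")
  if (separation < 0) stop_contract("gen_class_mixture: separation must be >= 0")
  n <- as.integer(n_rows)
  with_seed(seed, {
    cls_idx <- sample(rep_len(seq_len(k_classes), n))  # balanced, shuffled
    feats <- list()
    for (j in seq_len(n_informative))
      feats[[sprintf("signal_%d", j)]] <-
        separation * (cls_idx - 1) + stats::rnorm(n)
    for (j in seq_len(n_noise))
      feats[[sprintf("noise_%d", j)]] <- stats::rnorm(n)
    feats[["class"]] <- sprintf("class_%d", cls_idx)
    df <- as.data.frame(feats, optional = TRUE, stringsAsFactors = FALSE)
    df <- df[, sample(ncol(df)), drop = FALSE]  # shuffle column order
    overrides <- stats::setNames(
      as.list(ifelse(names(df) == "class", "categorical", "numeric")),
      names(df))
    as_typed_table(df, overrides = overrides)
  })
}

#' Generate correlated multivariate-normal numeric features
#'
#' Draws `n_rows` samples from a zero-mean multivariate normal with the
#' requested correlation matrix (via its symmetric eigendecomposition
#' square root, so positive semi-definite matrices are accepted).
#'
#' @param n_rows Number of samples.
#' @param seed Integer seed.
#' @param correlation_matrix Symmetric PSD matrix with unit diagonal.
#' @return A `typed_table` of numeric columns (named from the matrix
#'   dimnames, else `V1..Vk`).
#' @export
gen_correlated_numeric <- function(n_rows, seed = 1L, correlation_matrix) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))) ||
      !isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m)))))
    stop_contract("gen_correlated_numeric: correlation matrix must be symmetric with unit diagonal")
  eig <- eigen(m, symmetric = TRUE)
  if (any(eig$values < -1e-8))
    stop_contract("gen_correlated_numeric: correlation matrix is not positive semi-definite")
  lam <- pmax(eig$values, 0)
  sqrtm <- eig$vectors %*% (sqrt(lam) * t(eig$vectors))
  k <- nrow(m)
  nm <- if (!is.null(colnames(m))) colnames(m) else sprintf("V%d", seq_len(k))
  n <- as.integer(n_rows)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k)
    x <- z %*% sqrtm
    colnames(x) <- nm
    df <- as.data.frame(x, optional = TRUE)
    as_typed_table(df, overrides = stats::setNames(as.list(rep("numeric", k)), nm))
  })
}
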