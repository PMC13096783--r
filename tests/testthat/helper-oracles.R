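# Independent oracles used to check the fast implementations. These stay
# deliberately naive: O(n^2) pair scans, exhaustive DFS enumeration, and
# decorate-sort-undecorate, none of which share code with the package.

# Quadratic pairwise crossing count: |{(i,j): i<j, (a_i-a_j)(b_i-b_j) < 0}|,
# after pairwise-complete filtering. Ties contribute 0.
oracle_count_crossings <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  count <- 0L
  if (n < 2L) return(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if ((a[i] - a[j]) * (b[i] - b[j]) < 0) count <- count + 1L
    }
  }
  count
}

# Exhaustive minimum of the open-path objective over all k! orderings,
# via depth-first enumeration (no shared permutation code with the package).
oracle_min_path_cost <- function(m) {
  k <- nrow(m)
  best <- Inf
  rec <- function(path, left, cost) {
    if (cost >= best) {
      if (length(left) > 0L) return(invisible(NULL))
    }
    if (length(left) == 0L) {
      if (cost < best) best <<- cost
      return(invisible(NULL))
    }
    for (nxt in left) {
      add <- if (length(path) > 0L) m[path[length(path)], nxt] else 0
      rec(c(path, nxt), setdiff(left, nxt), cost + add)
    }
  }
  rec(integer(), seq_len(k), 0)
  best
}

path_cost_of <- function(m, ord) {
  k <- length(ord)
  if (k < 2L) return(0)
  sum(m[cbind(ord[-k], ord[-1L])])
}

# Decorate-sort-undecorate multi-key ordering oracle: builds sortable
# string keys per row and sorts them with base order() on a single pasted
# key per level, missing-last encoded in the decoration.
oracle_order_samples <- function(table, keys) {
  n <- table$n_rows
  decs <- list()
  for (key in keys) {
    col <- key[[1]]
    dir <- if (length(key) > 1) key[[2]] else "asc"
    cs <- NULL
    for (c in table$columns) if (c$name == col) cs <- c
    v <- table$values[[col]]
    num <- switch(cs$role,
      numeric = as.numeric(v),
      categorical = match(v, cs$levels),
      boolean = match(as.character(v), cs$levels),
      xtfrm(v))
    if (dir == "desc") num <- -num
    miss <- is.na(v)
    num[miss] <- Inf  # missing last, both directions
    decs <- c(decs, list(miss), list(num))
  }
  do.call(order, decs)
}

# Plug-in mutual information of a contingency table, spelled out term by
# term in bits.
oracle_mi_from_table <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0)
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  total
}

# Random mixed-type fixture: numeric, categorical and boolean columns with
# scattered missing cells, returned as a typed_table.
random_mixed_table <- function(n = 30L, seed = 1L) {
  set.seed(seed)
  n_num <- sample(2:4, 1)
  n_cat <- sample(1:2, 1)
  df <- list()
  for (j in seq_len(n_num)) {
    v <- round(rnorm(n), 3)
    v[runif(n) < 0.1] <- NA
    df[[sprintf("num%d", j)]] <- v
  }
  for (j in seq_len(n_cat)) {
    v <- sample(c("red", "green", "blue"), n, replace = TRUE)
    v[runif(n) < 0.1] <- NA
    df[[sprintf("cat%d", j)]] <- v
  }
  bl <- sample(c(TRUE, FALSE), n, replace = TRUE)
  bl[runif(n) < 0.1] <- NA
  df[["flag"]] <- bl
  as_typed_table(as.data.frame(df, stringsAsFactors = FALSE),
                 overrides = stats::setNames(
                   as.list(rep("numeric", n_num)),
                   sprintf("num%d", seq_len(n_num))))
}

n_matches <- function(text, pattern) {
  m <- gregexpr(pattern, text)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) 0L else length(m)
}
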