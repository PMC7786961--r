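# Independent brute-force oracles used to validate the package's graph
# computations. Deliberately written from first principles (loops over the
# edge list / all-pairs recursions), not via the code paths they check.

# all-pairs shortest paths by Floyd-Warshall on lengths 1/w
bf_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_nodal_efficiency <- function(w) {
  d <- bf_shortest_paths(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  })
}

bf_degree <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) sum(w[i, -i]))
}

# Newman-Girvan modularity with resolution gamma, from the double sum
bf_modularity <- function(w, labels, gamma = 1) {
  n <- nrow(w)
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (labels[i] == labels[j])
      q <- q + w[i, j] - gamma * k[i] * k[j] / two_m
  q / two_m
}

bf_within_module_z <- function(a, labels) {
  n <- nrow(a)
  k_in <- sapply(seq_len(n), function(i)
    sum(a[i, setdiff(which(labels == labels[i]), i)] > 0))
  z <- numeric(n)
  for (cid in unique(labels)) {
    idx <- which(labels == cid)
    s <- sd(k_in[idx])
    z[idx] <- if (length(idx) < 2 || is.na(s) || s == 0) 0
              else (k_in[idx] - mean(k_in[idx])) / s
  }
  z
}

bf_participation <- function(a, labels) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    k_i <- sum(a[i, -i] > 0)
    if (k_i == 0) return(0)
    1 - sum(sapply(unique(labels), function(cid) {
      k_m <- sum(a[i, setdiff(which(labels == cid), i)] > 0)
      (k_m / k_i)^2
    }))
  })
}

# enumerate all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, max_used) {
    pos <- length(labels) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(max_used + 1L))
      recurse(c(labels, v), max(max_used, v))
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive best-modularity partition (feasible for n <= 9)
bf_best_partition <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) bf_modularity(w, p, gamma), numeric(1))
  list(labels = parts[[which.max(qs)]], q = max(qs))
}

# small fixture graphs (weighted, symmetric, zero diagonal), n <= 12
fixture_graphs <- function() {
  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 0; m }
  path5 <- matrix(0, 5, 5)
  for (i in 1:4) path5[i, i + 1] <- path5[i + 1, i] <- 0.5
  star6 <- matrix(0, 6, 6)
  star6[1, 2:6] <- star6[2:6, 1] <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  cliques8 <- matrix(0, 8, 8)
  cliques8[1:4, 1:4] <- 1; cliques8[5:8, 5:8] <- 1
  cliques8[4, 5] <- cliques8[5, 4] <- 1
  diag(cliques8) <- 0
  set.seed(404)
  rand10 <- sym(matrix(round(runif(100), 3) * (runif(100) < 0.5), 10, 10))
  rand12 <- sym(matrix(round(runif(144), 3) * (runif(144) < 0.4), 12, 12))
  list(path5 = path5, star6 = star6, cliques8 = cliques8,
       rand10 = rand10, rand12 = rand12)
}

fixture_partition <- function(w) {
  n <- nrow(w)
  rep(seq_len(ceiling(n / 4)), each = 4, length.out = n)
}

# small ready-made subject_ts for scrub tests
toy_ts <- function(fd, dvars, n_nodes = 3, tr = 2, id = "toy") {
  n <- length(fd)
  structure(list(subject_id = id,
                 data = matrix(seq_len(n * n_nodes) + 0.5, n, n_nodes),
                 tr_seconds = tr, fd = fd, dvars = dvars),
            class = "subject_ts")
}
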