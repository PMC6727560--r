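# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (triple loops, exhaustive enumeration) so it can serve
# as an oracle for the vectorised implementations.

tiny_matrix <- function(values, sex = NULL, stage = "ES") {
  samples <- data.frame(sample_id = colnames(values),
                        sex = if (is.null(sex)) "unknown" else sex,
                        stage = stage, batch = "b", cross = "c",
                        stringsAsFactors = FALSE)
  expression_matrix(values, samples = samples)
}

# brute-force topological overlap, straight from the definition
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  T <- diag(n)
  for (m in seq_len(n)) for (q in seq_len(n)) {
    if (m == q) next
    l <- 0
    for (u in seq_len(n)) if (u != m && u != q) l <- l + A[m, u] * A[u, q]
    T[m, q] <- (l + A[m, q]) / (min(k[m], k[q]) + 1 - A[m, q])
  }
  T
}

# exhaustive null score distribution of a PWM on the same discretised grid
# as the dynamic program
threshold_oracle <- function(pwm, p_cutoff, grain = 1e-3) {
  S <- round(pwm$scores / grain)
  w <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words)); pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    sc[i] <- sum(S[cbind(words[i, ], seq_len(w))])
    pr[i] <- prod(pwm$background[words[i, ]])
  }
  agg <- tapply(pr, sc, sum)
  grid <- as.numeric(names(agg))
  o <- order(grid)
  grid <- grid[o]; prob <- as.numeric(agg)[o]
  tail <- rev(cumsum(rev(prob)))
  ok <- which(tail <= p_cutoff)
  if (length(ok) == 0) max(grid) * grain else grid[ok[1L]] * grain
}

# betweenness by explicit shortest-path enumeration (adjacency matrix input)
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    # BFS distance
    dist <- rep(Inf, n); dist[s] <- 0; frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (u in which(adj[v, ] > 0))
        if (dist[u] == Inf) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    # enumerate all shortest paths recursively
    out <- list()
    recurse <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (u in which(adj[v, ] > 0))
        if (dist[u] == dist[v] + 1) recurse(c(path, u))
    }
    recurse(s)
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    for (p in ps) {
      mid <- setdiff(p, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(ps)
    }
  }
  btw
}

# modularity of a partition, from the definition (unweighted)
modularity_oracle <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    lc <- sum(adj[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + lc / m - (dc / (2 * m))^2
  }
  q
}

# maximum modularity by exhaustive search over all set partitions
best_partition_oracle <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  assign_next <- function(membership, i, k) {
    if (i > n) {
      q <- modularity_oracle(adj, membership)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(k + 1)) {
      membership[i] <- c
      assign_next(membership, i + 1, max(k, c))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# the two-triangle graph: 1-2-3 and 4-5-6 triangles joined by edge 3-4
two_triangles <- function() {
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  adj <- matrix(0, 6, 6)
  adj[e] <- 1
  adj + t(adj)
}

fixture_path <- function() {
  system.file("extdata", "tables_2_3_transcription.tsv",
              package = "cardiosex")
}

# split the combined fixture into the female and male tables
read_fixture_tables <- function() {
  bt <- read_bias_table_tsv(fixture_path())
  sub_bt <- function(g) structure(
    list(codes = bt$codes[g, , drop = FALSE],
         genes = bt$genes[match(g, bt$genes$gene_id), , drop = FALSE]),
    class = "bias_table")
  list(all = bt,
       female = sub_bt(rownames(bt$codes)[bt$extra$table == "female"]),
       male = sub_bt(rownames(bt$codes)[bt$extra$table == "male"]))
}
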