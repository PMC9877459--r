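# Independent brute-force oracles used to pin down expected values.
# Each is deliberately written by a different route than the implementation
# it checks (enumeration / direct tabulation / closed form).

# Two-sided rank-sum p by full enumeration of rank assignments.
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Step-up BH by direct definition (no p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  running <- sorted * m / seq_len(m)
  # cumulative min from the largest rank down
  for (i in rev(seq_len(max(m - 1, 0)))) {
    running[i] <- min(running[i], running[i + 1])
  }
  adj[ord] <- pmin(running, 1)
  adj
}

# AUC by explicit pair counting.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# All maximal cliques by subset growth over an adjacency matrix, then MCC.
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  cliques <- lapply(seq_len(n), function(v) v)
  frontier <- cliques
  while (length(frontier) > 0) {
    nxt <- list()
    for (cl in frontier) {
      last <- max(cl)
      if (last < n) for (v in (last + 1):n) {
        if (all(adj[cl, v] == 1)) nxt[[length(nxt) + 1]] <- c(cl, v)
      }
    }
    cliques <- c(cliques, nxt)
    frontier <- nxt
  }
  is_maximal <- vapply(cliques, function(cl) {
    outside <- setdiff(seq_len(n), cl)
    !any(vapply(outside, function(v) all(adj[cl, v] == 1), TRUE))
  }, TRUE)
  score <- numeric(n)
  for (cl in cliques[is_maximal]) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  score
}

# Log-rank chi-square by direct O/E/V tabulation over event times.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g)
    nj <- sum(at_risk)
    d1 <- sum(time == t & event == 1 & g)
    dj <- sum(time == t & event == 1)
    O <- O + d1
    E <- E + dj * n1 / nj
    if (nj > 1) V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  (O - E)^2 / V
}

# ssGSEA running sum written out step by step for one sample.
oracle_ssgsea <- function(expr, in_set, alpha = 0.25) {
  p <- length(expr)
  r <- rank(expr)
  ord <- order(-r, names(expr))
  es <- 0
  cum_in <- 0
  cum_out <- 0
  w_total <- sum((r[ord]^alpha)[in_set[ord]])
  m <- sum(in_set)
  for (i in seq_len(p)) {
    idx <- ord[i]
    if (in_set[idx]) cum_in <- cum_in + r[idx]^alpha / w_total
    else cum_out <- cum_out + 1 / (p - m)
    es <- es + (cum_in - cum_out)
  }
  unname(es)
}

# Named adjacency matrix from an igraph for the MCC oracle.
adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# Small random graph with letter names.
random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# A small deterministic toy expression dataset (two subtypes + normal).
toy_dataset <- function(seed = 42, n_genes = 50, n_per_group = 6) {
  set.seed(seed)
  groups <- rep(c("MTC", "ATC", "normal"), each = n_per_group)
  ids <- sprintf("S%02d", seq_along(groups))
  X <- matrix(rnorm(n_genes * length(groups), 7, 0.5), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), ids))
  # genes 1-5 up in MTC, 6-8 down in MTC, 9-10 up in both tumors
  X[1:5, groups == "MTC"] <- X[1:5, groups == "MTC"] + 2
  X[6:8, groups == "MTC"] <- X[6:8, groups == "MTC"] - 2
  X[9:10, groups != "normal"] <- X[9:10, groups != "normal"] + 2
  expression_dataset(X, tibble::tibble(sample_id = ids, subtype = groups))
}
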