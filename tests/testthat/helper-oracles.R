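# Brute-force oracles for nodal graph measures, written independently of
# the package implementation: distances by exhaustive simple-path
# enumeration, clustering by triple loops, betweenness by enumerating all
# shortest paths. Only usable on small graphs (<= 8 nodes).

rand_weighted_graph <- function(n, p = 0.5, wmin = 0.1, wmax = 0.9) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) w[i, j] <- w[j, i] <- runif(1, wmin, wmax)
    }
  }
  w
}

# all simple paths from s to t as lists of node sequences
all_simple_paths_bf <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path, used) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (!used[v] && w[u, v] > 0) {
        used[v] <- TRUE
        walk(c(path, v), used)
        used[v] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n)
  used[s] <- TRUE
  walk(s, used)
  paths
}

path_length_bf <- function(w, path, to_length = function(x) 1 / x) {
  if (length(path) < 2) return(0)
  sum(to_length(w[cbind(path[-length(path)], path[-1])]))
}

# exhaustive shortest-path distance between two nodes
dist_bf <- function(w, s, t, to_length = function(x) 1 / x) {
  if (s == t) return(0)
  paths <- all_simple_paths_bf(w, s, t)
  if (!length(paths)) return(Inf)
  min(vapply(paths, function(p) path_length_bf(w, p, to_length), numeric(1)))
}

dist_matrix_bf <- function(w) {
  n <- nrow(w)
  D <- matrix(0, n, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) D[s, t] <- D[t, s] <- dist_bf(w, s, t)
  }
  D
}

strength_bf <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

degree_bf <- function(w) {
  n <- nrow(w)
  d <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (w[i, j] > 0) d[i] <- d[i] + 1L
  }
  d
}

local_efficiency_bf <- function(w) {
  n <- nrow(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    tot <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a == b) next
        d <- dist_bf(sub, a, b)
        tot <- tot + if (is.finite(d)) 1 / d else 0
      }
    }
    eff[i] <- tot / (k * (k - 1))
  }
  eff
}

clustering_bf <- function(w) {
  n <- nrow(w)
  C <- numeric(n)
  for (i in seq_len(n)) {
    d <- sum(w[i, ] > 0)
    if (d < 2) next
    num <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (w[i, j] > 0 && w[i, k] > 0 && w[j, k] > 0 && j != k) {
          num <- num + (w[i, j] + w[i, k]) / 2
        }
      }
    }
    C[i] <- num / (sum(w[i, ]) * (d - 1))
  }
  C
}

betweenness_bf <- function(w, normalized = TRUE, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_bf(w, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(p) path_length_bf(w, p), numeric(1))
      dmin <- min(lens)
      shortest <- paths[lens <= dmin * (1 + tol)]
      nsp <- length(shortest)
      through <- numeric(n)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        through[interior] <- through[interior] + 1
      }
      bc <- bc + through / nsp
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}
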