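# Independent oracles and fixture builders used across the test files.

make_net <- function(W, ids = NULL, camp = "camp01", ages = NULL) {
  n <- nrow(W)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, W = W, camp_id = camp,
                 ages = if (is.null(ages)) rep(30, n) else ages),
            class = "proximity_network")
}

# random connected weighted undirected graph; weights either continuous
# (generic, no geodesic ties) or integer-valued (forces exact ties so
# fractional crediting is exercised)
random_connected_graph <- function(n, p = 0.5, integer_weights = FALSE) {
  repeat {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (runif(1) < p) {
          w <- if (integer_weights) sample(1:2, 1) else runif(1, 0.5, 3)
          W[i, j] <- W[j, i] <- w
        }
      }
    }
    # connectivity by reachability of node 1
    reach <- rep(FALSE, n)
    reach[1] <- TRUE
    repeat {
      new <- reach | colSums(W[reach, , drop = FALSE] > 0) > 0
      if (all(new == reach)) break
      reach <- new
    }
    if (all(reach)) return(W)
  }
}

# Floyd-Warshall all-pairs shortest distances on edge lengths 1/w
fw_distances <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  D <- L
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Betweenness oracle: Floyd-Warshall distances plus combinatorial geodesic
# counting (predecessor DP), an algorithmic route independent of the
# Dijkstra/Brandes implementation.
oracle_geodesics <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  D <- fw_distances(W)
  tol <- 1e-10
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(is.finite(L[, t]) &
                      abs(D[s, ] + L[, t] - D[s, t]) <= tol * (1 + D[s, t]))
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            abs(D[s, v] + D[v, t] - D[s, t]) <= tol * (1 + D[s, t])) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  list(D = D, betweenness = btw)
}

# closeness from the Floyd-Warshall matrix
oracle_closeness <- function(W) {
  D <- fw_distances(W)
  n <- nrow(W)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) && sum(d) > 0) 1 / sum(d) else 0
  }, 0)
}

# Exhaustive all-simple-paths betweenness (tiny graphs only): enumerate
# every simple path per pair, keep the shortest, credit interior nodes.
enum_betweenness <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- list()
      best <- Inf
      rec <- function(v, visited, len) {
        if (len > best + 1e-9) return()
        if (v == t) {
          paths[[length(paths) + 1L]] <<- list(nodes = visited, len = len)
          if (len < best) best <<- len
          return()
        }
        for (u in which(is.finite(L[v, ]))) {
          if (!(u %in% visited)) rec(u, c(visited, u), len + L[v, u])
        }
      }
      rec(s, s, 0)
      if (!length(paths)) next
      lens <- vapply(paths, function(p) p$len, 0)
      keep <- lens <= min(lens) + 1e-10 * (1 + min(lens))
      geo <- paths[keep]
      for (p in geo) {
        inner <- setdiff(p$nodes, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(geo)
      }
    }
  }
  btw
}

# minute-grid enumeration oracle for daytime overlap hours
overlap_hours_oracle <- function(enter1, exit1, enter2, exit2, window = c(5, 20)) {
  m0 <- floor(as.numeric(min(enter1, enter2)) / 60)
  m1 <- ceiling(as.numeric(max(exit1, exit2)) / 60)
  if (m1 <= m0) return(0)
  mins <- seq(m0, m1 - 1)
  t <- mins * 60
  mod <- mins %% 1440
  ok <- t >= as.numeric(enter1) & t < as.numeric(exit1) &
    t >= as.numeric(enter2) & t < as.numeric(exit2) &
    mod >= window[1] * 60 & mod < window[2] * 60
  sum(ok) / 60
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

# small configs used in several files
tiny_config <- function(...) {
  sim_config(n_camps = 1, camp_size_range = c(15, 15), study_days = 2,
             seed = 7, ...)
}
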