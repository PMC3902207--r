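# Graph-theoretic analysis of the translation-invariant connection set.

# Numeric key for an edge template (j -> k at offset dx, dy); `span` must
# exceed the largest absolute offset that can occur (differences of two
# offsets reach twice the sampling range).
edge_key <- function(j, k, dx, dy, K, span) {
  ((j - 1) * K + (k - 1)) * (2 * span + 1)^2 +
    (dx + span) * (2 * span + 1) + (dy + span)
}

# Neighbor set of the generic-column neuron coding feature `f`: outbound
# targets and inbound sources, deduplicated. Returns a data frame
# (feature, dx, dy).
neighbor_set <- function(records, f) {
  out <- records[records$j == f, c("k", "dx", "dy")]
  names(out) <- c("feature", "dx", "dy")
  inb <- records[records$k == f, c("j", "dx", "dy")]
  inb$dx <- -inb$dx
  inb$dy <- -inb$dy
  names(inb) <- c("feature", "dx", "dy")
  nb <- rbind(out, inb)
  nb[!duplicated(nb), , drop = FALSE]
}

clustering_by_feature <- function(records, K, span) {
  keys <- sort(edge_key(records$j, records$k, records$dx, records$dy,
                        K, span))
  vapply(seq_len(K), function(f) {
    nb <- neighbor_set(records, f)
    n <- nrow(nb)
    if (n < 2L) return(NA_real_)
    ia <- rep(seq_len(n), times = n)
    ib <- rep(seq_len(n), each = n)
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
    pair_keys <- edge_key(nb$feature[ia], nb$feature[ib],
                          nb$dx[ib] - nb$dx[ia], nb$dy[ib] - nb$dy[ia],
                          K, span)
    n_edges <- sum(!is.na(match(pair_keys, keys)))
    n_edges / (n * (n - 1))
  }, numeric(1L))
}

path_lengths_column <- function(records, K, bound, max_hops) {
  dists <- matrix(NA_real_, K, K)
  for (s in seq_len(K)) {
    d <- cpp_bfs_column(as.integer(records$dx), as.integer(records$dy),
                        as.integer(records$j), as.integer(records$k),
                        K, as.integer(bound), s, as.integer(max_hops))
    d[d < 0L] <- NA_integer_
    dists[s, ] <- d
  }
  diag(dists) <- NA_real_  # ordered pairs of distinct features
  dists
}

# Length-preserving randomization: every template keeps its Euclidean
# length but is rotated by a random angle and rewired to random features.
randomize_records <- function(records, K) {
  n <- nrow(records)
  len <- sqrt(records$dx^2 + records$dy^2)
  repeat {
    ang <- runif(n, 0, 2 * pi)
    out <- data.frame(dx = round(len * cos(ang)),
                      dy = round(len * sin(ang)),
                      j = sample.int(K, n, replace = TRUE),
                      k = sample.int(K, n, replace = TRUE),
                      w = records$w)
    bad <- out$dx == 0 & out$dy == 0 & out$j == out$k
    if (!any(bad)) return(out)
    records_bad <- records[bad, , drop = FALSE]
    keep <- out[!bad, , drop = FALSE]
    # resample only the offending rows
    n <- nrow(records_bad)
    len <- sqrt(records_bad$dx^2 + records_bad$dy^2)
    records <- records_bad
    acc <- keep
    repeat {
      ang <- runif(n, 0, 2 * pi)
      trial <- data.frame(dx = round(len * cos(ang)),
                          dy = round(len * sin(ang)),
                          j = sample.int(K, n, replace = TRUE),
                          k = sample.int(K, n, replace = TRUE),
                          w = records$w)
      bad2 <- trial$dx == 0 & trial$dy == 0 & trial$j == trial$k
      acc <- rbind(acc, trial[!bad2, , drop = FALSE])
      if (!any(bad2)) return(acc)
      records <- records[bad2, , drop = FALSE]
      len <- len[bad2]
      n <- nrow(records)
    }
  }
}

#' Graph metrics of a sampled connection set
#'
#' Analyzes the translation-invariant connection graph (or its
#' synchronizing / desynchronizing subgraph): the intra-feature
#' connection fraction, the clustering coefficient of the generic
#' feature column, the mean shortest directed path length between all
#' ordered pairs of features within one column (breadth-first search over
#' (feature, offset) states, bounded spatially), and the small-world
#' index against a random baseline with the same connection lengths but
#' random orientations and random features.
#'
#' @param conns A [connection_set()].
#' @param subgraph `"all"`, `"sync"` or `"desync"`.
#' @param seed Seed for the random baseline.
#' @param n_random Number of baseline randomizations (>= 10 recommended).
#' @param bound Spatial search bound for paths; defaults to three times
#'   the largest sampled offset.
#' @param max_hops Hop cap for the search (default 8).
#' @return A `graph_metrics` list: `mu` (intra-feature %), `gamma`,
#'   `gamma_random`, `lambda_path`, `lambda_random`, `sigma_sw`,
#'   `n_unreachable`, and the subgraph tag.
#' @export
graph_metrics <- function(conns, subgraph = c("all", "sync", "desync"),
                          seed = 1L, n_random = 10L, bound = NULL,
                          max_hops = 8L) {
  subgraph <- match.arg(subgraph)
  K <- attr(conns, "n_features")
  records <- as.data.frame(conns)
  records <- switch(subgraph,
    all = records,
    sync = records[records$w > 0, , drop = FALSE],
    desync = records[records$w < 0, , drop = FALSE])
  if (nrow(records) == 0L) stop("empty ", subgraph, " subgraph")
  n_intra <- sum(records$j == records$k)
  n_inter <- sum(records$j != records$k)
  mu <- if (n_inter > 0L) n_intra / n_inter * 100 else Inf
  span <- 2L * max(abs(records$dx), abs(records$dy), 1L)
  if (is.null(bound)) bound <- 3L * max(abs(records$dx), abs(records$dy), 1L)
  gam <- clustering_by_feature(records, K, span)
  gamma <- mean(gam, na.rm = TRUE)
  dists <- path_lengths_column(records, K, bound, max_hops)
  n_unreach <- sum(is.na(dists)) - K  # diagonal not counted
  if (n_unreach > 0L)
    warning(n_unreach, " ordered feature pairs unreachable within the ",
            "search bound; excluded from the mean path length")
  lambda <- mean(dists, na.rm = TRUE)
  g_rand <- numeric(n_random)
  l_rand <- numeric(n_random)
  with_seed(seed, {
    for (i in seq_len(n_random)) {
      rr <- randomize_records(records, K)
      g_rand[i] <- mean(clustering_by_feature(rr, K, span), na.rm = TRUE)
      dr <- path_lengths_column(rr, K, bound, max_hops)
      l_rand[i] <- mean(dr, na.rm = TRUE)
    }
  })
  gamma_random <- mean(g_rand)
  lambda_random <- mean(l_rand)
  structure(list(mu = mu, gamma = gamma, gamma_random = gamma_random,
                 lambda_path = lambda, lambda_random = lambda_random,
                 sigma_sw = (gamma / gamma_random) /
                            (lambda / lambda_random),
                 n_unreachable = n_unreach, subgraph = subgraph),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<graph_metrics [%s]: mu = %.2f%%, gamma = %.4g (rand %.4g), ",
    "lambda = %.3g (rand %.3g), sigma_sw = %.3g>\n"),
    x$subgraph, x$mu, x$gamma, x$gamma_random,
    x$lambda_path, x$lambda_random, x$sigma_sw))
  invisible(x)
}
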