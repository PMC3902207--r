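#' Connection set container
#'
#' Translation-invariant signed tangential connections. Each record is a
#' 5-tuple: column offset `dx`, row offset `dy`, afferent feature `j`,
#' efferent feature `k`, and sign `w` in `{+1, -1}`. A record connects
#' the source neuron at `(x, y)` coding `j` to the target at
#' `(x + dx, y + dy)` coding `k`, replicated at every grid position.
#'
#' @param records Data frame with columns `dx, dy, j, k, w`.
#' @param n_features Number of feature maps `K`.
#' @param eta_plus,eta_minus Per-feature connection counts (informative).
#' @param seed Sampling seed (informative).
#' @return A `connection_set`.
#' @export
connection_set <- function(records, n_features,
                           eta_plus = NA_integer_, eta_minus = NA_integer_,
                           seed = NA_integer_) {
  stopifnot(all(c("dx", "dy", "j", "k", "w") %in% names(records)),
            all(records$w %in% c(-1, 1)))
  if (any(records$dx == 0 & records$dy == 0 & records$j == records$k))
    stop("self-loops (dx = dy = 0, j = k) are not allowed")
  structure(records, class = c("connection_set", "data.frame"),
            n_features = as.integer(n_features),
            eta_plus = eta_plus, eta_minus = eta_minus, seed = seed)
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("<connection_set: %d records (%d sync, %d desync), K = %d>\n",
              nrow(x), sum(x$w > 0), sum(x$w < 0), attr(x, "n_features")))
  invisible(x)
}

# Systematic probability-proportional-to-size sampling without
# replacement: inclusion probability of item i is the capped proportional
# probability min(1, n' * w_i / sum(w')) after iteratively granting
# certainty to items whose proportional share exceeds one.
sample_pps <- function(w, n) {
  idx <- which(w > 0)
  if (length(idx) < n) stop("insufficient candidates: ", length(idx),
                            " positive weights for ", n, " draws")
  certain <- integer(0)
  repeat {
    n_rem <- n - length(certain)
    if (n_rem == 0L) return(certain)
    p <- n_rem * w[idx] / sum(w[idx])
    over <- idx[p >= 1]
    if (!length(over)) break
    certain <- c(certain, over)
    idx <- setdiff(idx, over)
  }
  perm <- sample(length(idx))
  cum <- cumsum(p[match(idx[perm], idx)])
  pts <- runif(1) + seq_len(n - length(certain)) - 1L
  sel <- findInterval(pts, c(0, cum), left.open = TRUE)
  c(certain, idx[perm][sel])
}

#' Sample sparse signed connections from a masked correlation tensor
#'
#' For each efferent feature `k` independently, draws `eta_plus`
#' synchronizing (+1) connections with probability proportional to
#' `max(0, rho)` and `eta_minus` desynchronizing (-1) connections with
#' probability proportional to `max(0, -rho)`, over all significant
#' candidate sources `(dx, dy, j)` (the self pair `dx = dy = 0, j = k`
#' excluded). Sampling is without replacement (systematic
#' probability-proportional sampling), so the fixed per-feature counts
#' are met exactly and each candidate's inclusion probability is the
#' capped proportional share. The identical pattern applies at every
#' grid position (shift invariance).
#'
#' @param ct A [correlation_tensor()], normally after
#'   [fdr_significance_mask()].
#' @param eta_plus,eta_minus Afferent synchronizing / desynchronizing
#'   connections per neuron.
#' @param seed Sampling seed.
#' @return A [connection_set()].
#' @export
sample_connections <- function(ct, eta_plus = 200L, eta_minus = 200L,
                               seed = 1L) {
  stopifnot(inherits(ct, "correlation_tensor"))
  if (eta_plus <= 0 || eta_minus <= 0) stop("eta counts must be positive")
  K <- dim(ct$rho)[1]
  offs <- ct$offsets
  D <- length(offs)
  # candidate table for one efferent feature: afferent j x dx x dy
  grid <- expand.grid(j = seq_len(K), ix = seq_len(D), iy = seq_len(D))
  recs <- vector("list", 2L * K)
  with_seed(seed, {
    for (k in seq_len(K)) {
      rho_k <- ct$rho[grid$j + K * (k - 1L) +
                        K * K * (grid$ix - 1L) +
                        K * K * D * (grid$iy - 1L)]
      sig_k <- ct$sig[grid$j + K * (k - 1L) +
                        K * K * (grid$ix - 1L) +
                        K * K * D * (grid$iy - 1L)]
      self <- grid$j == k & offs[grid$ix] == 0L & offs[grid$iy] == 0L
      rho_k[!sig_k | self | is.na(rho_k)] <- 0
      sp <- sample_pps(pmax(0, rho_k), eta_plus)
      sm <- sample_pps(pmax(0, -rho_k), eta_minus)
      recs[[2L * k - 1L]] <- data.frame(
        dx = offs[grid$ix[sp]], dy = offs[grid$iy[sp]],
        j = grid$j[sp], k = k, w = 1)
      recs[[2L * k]] <- data.frame(
        dx = offs[grid$ix[sm]], dy = offs[grid$iy[sm]],
        j = grid$j[sm], k = k, w = -1)
    }
  })
  connection_set(do.call(rbind, recs), n_features = K,
                 eta_plus = as.integer(eta_plus),
                 eta_minus = as.integer(eta_minus), seed = seed)
}

#' Connection sparsity relative to full signed connectivity
#'
#' Percentage of realized connections per neuron relative to all
#' possible, counting one potential synchronizing and one potential
#' desynchronizing connection per ordered neuron pair (hence the factor
#' 2 in the denominator).
#'
#' @param eta_plus,eta_minus Afferent connection counts per neuron.
#' @param X,Y,K Grid dimensions (columns, rows, features).
#' @return Percentage as a plain number.
#' @export
connection_sparsity <- function(eta_plus, eta_minus, X, Y, K) {
  stopifnot(X > 0, Y > 0, K > 0)
  (eta_plus + eta_minus) / (2 * X * Y * K) * 100
}

#' Write / read a connection set as a 5-column TSV table
#'
#' @param x A [connection_set()].
#' @param path File path.
#' @return `read_connections` returns a [connection_set()].
#' @export
write_connections <- function(x, path) {
  df <- as.data.frame(x)[, c("dx", "dy", "j", "k", "w")]
  names(df) <- c("dx", "dy", "afferent_feature", "efferent_feature",
                 "weight")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connections
#' @param n_features Feature count `K` (defaults to the maximum feature
#'   index present).
#' @export
read_connections <- function(path, n_features = NULL) {
  df <- read.delim(path)
  names(df) <- c("dx", "dy", "j", "k", "w")
  if (is.null(n_features)) n_features <- max(df$j, df$k)
  connection_set(df, n_features = n_features)
}
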