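# Independent oracles used by both the unit suites and the acceptance
# suite: direct-formula and brute-force implementations kept deliberately
# naive and separate from the package's own code paths.

# Independent brute-force wPLI oracle: loops over windows, bins and
# pairs, evaluating |E{Im}| / E{|Im|} directly on raw windowed
# cross-spectra of the analytic signal.
wpli_oracle <- function(epoch, fs, window_s = 2, overlap_s = 1,
                        band = c(1, 45)) {
  nch <- nrow(epoch)
  z <- analytic_signal(epoch)
  wlen <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  starts <- seq(1, ncol(epoch) - wlen + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  keep <- which(freqs >= band[1] & freqs <= band[2])
  out <- matrix(0, nch, nch)
  for (i in seq_len(nch)) for (j in seq_len(nch)) {
    if (i == j) next
    ims <- c()
    for (s in starts) {
      xi <- stats::fft(z[i, s:(s + wlen - 1)] * taper)[keep]
      xj <- stats::fft(z[j, s:(s + wlen - 1)] * taper)[keep]
      ims <- c(ims, Im(xi * Conj(xj)))
    }
    den <- mean(abs(ims))
    out[i, j] <- if (den > 0) abs(mean(ims)) / den else 0
  }
  out
}


# Brute-force oracles for small weighted graphs: exhaustive simple-path
# enumeration for distances and shortest-path counting, direct triple
# loops for clustering.

oracle_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf); diag(len) <- 0
  best <- matrix(Inf, n, n); diag(best) <- 0
  paths <- vector("list", n * n)
  rec <- function(node, target, visited, dist, path) {
    if (node == target) {
      k <- (path[1] - 1) * n + target
      if (dist < best[path[1], target] - 1e-12) {
        best[path[1], target] <<- dist
        paths[[k]] <<- list(path)
      } else if (abs(dist - best[path[1], target]) <= 1e-12) {
        paths[[k]] <<- c(paths[[k]], list(path))
      }
      return()
    }
    for (nxt in seq_len(n)) {
      if (visited[nxt] || is.infinite(len[node, nxt])) next
      visited[nxt] <- TRUE
      rec(nxt, target, visited, dist + len[node, nxt], c(path, nxt))
      visited[nxt] <- FALSE
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- rep(FALSE, n); v[i] <- TRUE
    rec(i, j, v, 0, i)
  }
  list(d = best, paths = paths)
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  op <- oracle_paths(w)
  b <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (h in seq_len(n)) for (j in seq_len(n)) {
      if (h == j || h == i || j == i) next
      pl <- op$paths[[(h - 1) * n + j]]
      if (is.null(pl) || is.infinite(op$d[h, j])) next
      through <- sum(vapply(pl, function(p) i %in% p[-c(1, length(p))],
                            logical(1)))
      tot <- tot + through / length(pl)
    }
    b[i] <- tot / ((n - 1) * (n - 2))
  }
  b
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  what <- if (max(w) > 0) w / max(w) else w
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      t_i <- t_i + (what[i, j] * what[i, h] * what[j, h])^(1 / 3)
    }
    ci[i] <- t_i / (k * (k - 1))   # t_i above counts ordered (j,h): /2*2
  }
  ci
}

binary_metrics_oracle <- function(a) {
  # textbook binary definitions via BFS on the unweighted graph
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; dist <- 0
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] > 0))))
      nxt <- nxt[is.infinite(d[s, nxt])]
      dist <- dist + 1
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0); k <- length(nb)
    if (k < 2) return(0)
    2 * sum(a[nb, nb][upper.tri(a[nb, nb])]) / (k * (k - 1))
  }, numeric(1))
  list(d = d, ci = ci)
}


# O(n^2) Kendall tau-b oracle with tie correction.
tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}



# Independent NMI oracle: entropies and mutual information computed from
# scratch on the contingency table (information-theoretic route).
nmi_oracle <- function(a, b) {
  N <- length(a)
  tab <- table(a, b) / N
  pa <- rowSums(tab); pb <- colSums(tab)
  H <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  I <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      I <- I + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  denom <- (H(pa) + H(pb)) / 2
  if (denom == 0) return(1)
  as.numeric(I / denom)
}
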