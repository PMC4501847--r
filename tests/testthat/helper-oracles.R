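# Independent oracles used across the suite. Each is a deliberately naive
# implementation, kept separate from the package's code paths.

# brute-force observed-data likelihood: sum over the latent true molecule
# count Q and the trinomial observation channel
oracle_loglik_one <- function(k1, k2, mu, cv, p, b, qmax = 500) {
  r <- mu / (cv^2 * mu - 1)
  tot <- 0
  for (Q in (k1 + k2):qmax) {
    tot <- tot + stats::dnbinom(Q, size = r, mu = mu) *
      stats::dmultinom(c(k1, k2, Q - k1 - k2),
                       prob = c(p * b, (1 - p) * b, 1 - b))
  }
  log(tot)
}

# single-linkage clustering over the Hamming <= 1 graph by breadth-first
# search on an explicit adjacency matrix
oracle_umi_clusters <- function(umis) {
  n <- length(umis)
  chars <- strsplit(umis, "")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- sum(chars[[i]] != chars[[j]]) <= 1
    }
  }
  label <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(label[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(label[v])) next
      label[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(label)))
    }
  }
  label
}

# literal transcription of the greedy merge: sort positions by count
# ascending (ties: smaller coordinate first); walking up from the bottom,
# eliminate a site when a surviving site within `window` bp currently holds
# a strictly higher count, adding its count to that site
oracle_greedy_merge <- function(position, count, window = 12) {
  ord <- order(count, position)
  cnt <- as.numeric(count)
  dead <- rep(FALSE, length(position))
  for (i in ord) {
    if (dead[i]) next
    cand <- which(!dead & abs(position - position[i]) <= window & cnt > cnt[i])
    cand <- setdiff(cand, i)
    if (length(cand)) {
      target <- cand[order(-cnt[cand], position[cand])][1]
      cnt[target] <- cnt[target] + cnt[i]
      dead[i] <- TRUE
    }
  }
  data.frame(position = position[!dead], molecule_count = cnt[!dead])
}

# mean silhouette width for a 1-d embedding and two known labels
silhouette_1d <- function(x, labels) {
  stopifnot(length(unique(labels)) == 2)
  d <- abs(outer(x, x, "-"))
  s <- vapply(seq_along(x), function(i) {
    same <- labels == labels[i]
    same[i] <- FALSE
    a <- mean(d[i, same])
    b <- mean(d[i, !same & seq_along(x) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# random UMIs (possibly colliding) for clustering property tests
random_umis <- function(n, len = 8) {
  replicate(n, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
}
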