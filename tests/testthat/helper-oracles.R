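# Independent oracles and small fixture builders used across the suite.

# All permutations of a vector (exhaustive; used only for tiny universes).
perms_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms_all(v[-i]), function(p) c(v[i], p))))
}

# Brute-force partial-list Canberra distance: mean over all pairs of
# completions; core drops terms of features unlisted in both lists.
brute_partial_canberra <- function(t1, t2, p, core = FALSE) {
  u <- seq_len(p)
  c1 <- lapply(perms_all(setdiff(u, t1)), function(tl) c(t1, tl))
  c2 <- lapply(perms_all(setdiff(u, t2)), function(tl) c(t2, tl))
  both_unlisted <- setdiff(u, union(t1, t2))
  tot <- 0
  for (a in c1) for (b in c2) {
    ra <- match(u, a); rb <- match(u, b)
    terms <- abs(ra - rb) / (ra + rb)
    tot <- tot + if (core && length(both_unlisted) > 0)
      sum(terms[-both_unlisted]) else sum(terms)
  }
  tot / (length(c1) * length(c2))
}

# A->B->C activating chain; gene 1 is the only regulator hub.
chain_network <- function(w = 3) {
  W <- matrix(0, 3, 3); W[2, 1] <- w; W[3, 2] <- w
  grn_network(W, evolvable = 1:3)
}

# Two-class toy with `k` informative features among `p`.
toy_dataset <- function(p = 50, n = 30, k = 1, shift = 4, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(p * n), p, n)
    rownames(x) <- paste0("g", seq_len(p))
    y <- factor(rep(c("A", "B"), each = n / 2))
    x[seq_len(k), y == "B"] <- x[seq_len(k), y == "B"] + shift
    list(x = x, y = y, informative = paste0("g", seq_len(k)))
  })
}
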