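# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# exhaustive maximum bipartite matching of two band lists under tolerance t
brute_shared <- function(a, b, t) {
  if (!length(a) || !length(b)) return(0L)
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (length(a) - i + 1) <= best) return()
    if (i > length(a)) { best <<- max(best, count); return() }
    rec(i + 1, used, count)  # leave a[i] unmatched
    for (j in seq_along(b))
      if (!used[j] && abs(a[i] - b[j]) <= t) {
        used[j] <- TRUE
        rec(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
  }
  rec(1L, logical(length(b)), 0L)
  best
}

# second, independent N50/L50 implementation
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= half) return(list(n50 = s[i], l50 = i))
  }
}

# exhaustive search for a zero-violation ordering (small n only)
exhaustive_linear <- function(nodes, edges, compat = NULL) {
  stopifnot(length(nodes) <= 8)
  m <- physmapr:::component_matrices(nodes, edges, compat)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_along(nodes)))
    if (physmapr:::order_violations(p, m$adj, m$adjc) == 0) return(TRUE)
  FALSE
}

# synthetic fingerprints from integer "slot" sets, mapped onto the encoded
# band scale so they look like real HICF values
slots_to_bands <- function(slots) sort(as.integer(1500 + 30 * slots))

# build an overlap graph directly from named slot fingerprints
slot_network <- function(slot_list, params = match_params()) {
  fps <- lapply(slot_list, slots_to_bands)
  overlap_network(fps, params)
}

# union length of a set of [start, end) intervals
interval_union <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; reach <- -Inf
  for (k in seq_along(start)) {
    s <- max(start[k], reach); e <- end[k]
    if (e > s) tot <- tot + e - s
    reach <- max(reach, e)
  }
  tot
}

# Monte-Carlo band-placement estimate of P(shared >= s) for uniform random
# fingerprints of nl and nh bands on G slots (tolerance 0)
mc_sulston_tail <- function(nl, nh, G, s, reps, seed) {
  set.seed(seed)
  a <- matrix(sample.int(G, reps * nl, replace = TRUE), nrow = reps)
  b <- matrix(sample.int(G, reps * nh, replace = TRUE), nrow = reps)
  hits <- vapply(seq_len(reps), function(r)
    shared_bands(sort(a[r, ]), sort(b[r, ]), 0L) >= s, logical(1))
  mean(hits)
}
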