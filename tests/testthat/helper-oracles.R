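# Independent brute-force oracles used to check the implementation.
# These deliberately use different algorithms/code paths than R/.

# all ungapped placements of tag on precursor with <= max_mm internal
# mismatches, by direct substring comparison
oracle_placements <- function(tag, prec, max_mm = 1L) {
  L <- nchar(tag)
  out <- list()
  for (p in 0:(nchar(prec) - L)) {
    win <- substr(prec, p + 1L, p + L)
    mm <- which(strsplit(win, "")[[1]] != strsplit(tag, "")[[1]])
    if (length(mm) <= max_mm && all(mm > 1L & mm < L)) {
      out[[length(out) + 1L]] <- list(position = p, mm = mm)
    }
  }
  out
}

# maximum stem pairs with innermost pair enclosing a loop of size in
# [min_loop, max_loop]: enumerate the innermost pair directly, then
# count the best nested matching outside it LCS-style
oracle_hairpin <- function(seq, max_loop = 60L, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  can <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  lcs_pairs <- function(left, right) {
    # right is traversed inward from the 3' end (antiparallel stem)
    nl <- length(left); nr <- length(right)
    if (!nl || !nr) return(0L)
    right <- rev(right)
    D <- matrix(0L, nl + 1L, nr + 1L)
    for (i in seq_len(nl)) {
      for (j in seq_len(nr)) {
        D[i + 1L, j + 1L] <- max(D[i, j + 1L], D[i + 1L, j],
                                 D[i, j] + can(left[i], right[j]))
      }
    }
    D[nl + 1L, nr + 1L]
  }
  best <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      gap <- b - a - 1L
      if (gap < min_loop || gap > max_loop) next
      if (!can(s[a], s[b])) next
      outer_left <- if (a > 1L) s[1:(a - 1L)] else character()
      outer_right <- if (b < n) s[(b + 1L):n] else character()
      best <- max(best, 1L + lcs_pairs(outer_left, outer_right))
    }
  }
  best
}

# two-sided Fisher p by enumerating all tables with the observed
# margins and summing those no more probable than the observed one
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct binomial-coefficient summation
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# independent duplex scorer: per-position table lookup, explicit loop
oracle_score <- function(mirna, site, seed_start = 2, seed_end = 13,
                         gu = 0.5, mm = 1, mult = 2) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    t <- s[L - i + 1L]
    pair <- paste0(m[i], t)
    pen <- if (pair %in% c("AT", "TA", "GC", "CG")) {
      0
    } else if (pair %in% c("GT", "TG")) {
      gu
    } else {
      mm
    }
    if (i >= seed_start && i <= seed_end) pen <- pen * mult
    total <- total + pen
  }
  total
}

# Venn regions by per-element membership tally
oracle_venn <- function(sets) {
  nm <- names(sets)
  u <- unique(unlist(sets))
  out <- integer(7)
  names(out) <- c(nm, paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
                  paste(nm, collapse = "&"))
  for (e in u) {
    inset <- vapply(sets, function(s) e %in% s, logical(1))
    lab <- paste(nm[inset], collapse = "&")
    out[lab] <- out[lab] + 1L
  }
  out
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) pollensmrna::revcomp(x)
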