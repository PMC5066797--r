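# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain, slow, rule-by-rule code with no shared
# machinery with the package internals.

# --- Allen-rubric brute-force scorer (ungapped, all offsets) -------------
oracle_pair_penalty <- function(mb, tb) {
  wc <- (mb == "A" && tb == "T") || (mb == "T" && tb == "A") ||
    (mb == "C" && tb == "G") || (mb == "G" && tb == "C")
  if (wc) return(0)
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return(0.5)
  1
}

oracle_allen_sites <- function(mirna, transcript, max_score = 4) {
  mv <- strsplit(mirna, "")[[1]]
  tv <- strsplit(transcript, "")[[1]]
  m <- length(mv); L <- length(tv)
  out <- list()
  if (L < m) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  for (t1 in m:L) {
    sc <- 0
    for (i in 1:m) {
      w <- if (i >= 2 && i <= 13) 2 else 1
      sc <- sc + w * oracle_pair_penalty(mv[i], tv[t1 - i + 1])
    }
    if (sc <= max_score) {
      out[[length(out) + 1]] <- data.frame(start = t1 - m + 1, end = t1,
                                           score = sc)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

# gapped variant: enumerates every offset and single-gap placement by
# explicit per-position loops (slow; small inputs only)
oracle_allen_sites_gapped <- function(mirna, transcript, max_score = 4) {
  mv <- strsplit(mirna, "")[[1]]
  tv <- strsplit(transcript, "")[[1]]
  m <- length(mv); L <- length(tv)
  w <- function(i) if (i >= 2 && i <= 13) 2 else 1
  out <- list()
  add <- function(start, end, score, type, k) {
    if (score <= max_score) {
      out[[length(out) + 1]] <<- data.frame(start = start, end = end,
                                            score = score, gap_type = type,
                                            gap_pos = k)
    }
  }
  if (L >= m) {
    for (t1 in m:L) {
      sc <- 0
      for (i in 1:m) sc <- sc + w(i) * oracle_pair_penalty(mv[i], tv[t1 - i + 1])
      add(t1 - m + 1, t1, sc, "none", NA)
    }
  }
  if (L >= m + 1) {
    for (t1 in (m + 1):L) {
      for (k in 1:(m - 1)) {  # bulged transcript base after miRNA pos k
        sc <- 2 * w(k + 1)
        for (i in 1:m) {
          ti <- if (i <= k) t1 - i + 1 else t1 - i
          sc <- sc + w(i) * oracle_pair_penalty(mv[i], tv[ti])
        }
        add(t1 - m, t1, sc, "target_bulge", k)
      }
    }
  }
  if (L >= m - 1) {
    for (t1 in (m - 1):L) {
      for (k in 2:(m - 1)) {  # unpaired miRNA base k
        sc <- 2 * w(k)
        for (i in setdiff(1:m, k)) {
          ti <- if (i < k) t1 - i + 1 else t1 - i + 2
          sc <- sc + w(i) * oracle_pair_penalty(mv[i], tv[ti])
        }
        add(t1 - m + 2, t1, sc, "mirna_bulge", k)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), gap_type = character(0),
                      gap_pos = integer(0)))
  }
  do.call(rbind, out)
}

# --- category decision tree, rule by rule --------------------------------
oracle_category <- function(profile, position) {
  count <- profile[[as.character(position)]]
  if (count == 1) return(4L)
  mx <- max(profile)
  if (count == mx && sum(profile == mx) == 1) return(0L)
  if (count == mx) return(1L)
  med <- median(as.numeric(profile))
  if (count > med) 2L else 3L
}

# --- AC test by direct tail summation of the printed formula -------------
oracle_ac_p <- function(x, y, n1, n2, ymax = NULL) {
  r <- n2 / n1
  lp <- function(yy) {
    yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log(1 + r)
  }
  if (is.null(ymax)) ymax <- max(2000, 50 * (x + y + 10))
  lower <- sum(exp(lp(0:y)))
  upper <- sum(exp(lp((y + 1):ymax)))
  min(1, 2 * min(lower, upper))
}

# --- BH step-up by the definition ----------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- adjusted Rand index --------------------------------------------------
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# --- TOM by triple loop ---------------------------------------------------
oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# random degradome profile over positions <= max_pos with counts <= max_count
random_profile <- function(max_pos = 50, max_count = 20) {
  npos <- sample(1:8, 1)
  pos <- sort(sample.int(max_pos, npos))
  setNames(sample.int(max_count, npos, replace = TRUE), as.character(pos))
}

# random variant-name description valid for a given reference length
random_variant_spec <- function(ref_len) {
  repeat {
    left <- sample(-2:2, 1)
    right <- sample(-2:2, 1)
    lo <- max(1, 1 - left) + max(0, -left)
    # surviving reference region after trims
    keep <- seq(1 + max(0, -left), ref_len - max(0, -right))
    nsub <- sample(0:2, 1)
    if (length(keep) >= nsub && length(keep) >= 15) {
      return(list(left = left, right = right, nsub = nsub,
                  sub_pos = if (nsub > 0) sort(sample(keep, nsub)) else integer(0)))
    }
  }
}
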