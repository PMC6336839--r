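# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles with
# different code paths than the package.

# --- cascade oracle: evaluate all eight predicates per candidate, one at
# a time, with plain loops ---------------------------------------------
oracle_cascade <- function(cand, targets, thr = cascade_thresholds()) {
  n <- nrow(cand)
  pass <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (t in c("neuronal", "non_neuronal", "reference")) {
      ok <- ok && cand[[paste0("mq_", t)]][i] > thr$mq
      ok <- ok && cand[[paste0("bq_", t)]][i] > thr$bq
      ok <- ok && cand[[paste0("depth_", t)]][i] > thr$dp
    }
    ok <- ok && cand$n_alleles[i] == thr$n_alleles
    ok <- ok && isTRUE(cand$is_snv[i])
    # proximity: any other candidate of the same specimen & chrom
    dmin <- Inf
    for (j in seq_len(n)) {
      if (j != i && cand$specimen_id[j] == cand$specimen_id[i] &&
          cand$chrom[j] == cand$chrom[i]) {
        dmin <- min(dmin, abs(cand$pos[j] - cand$pos[i]))
      }
    }
    ok <- ok && dmin > thr$proximity
    # distance outside nearest target
    p0 <- cand$pos[i] - 1
    dt <- Inf
    tt <- targets[targets$chrom == cand$chrom[i], , drop = FALSE]
    for (k in seq_len(nrow(tt))) {
      if (tt$start[k] <= p0 && p0 < tt$end[k]) {
        dt <- 0
      } else if (p0 < tt$start[k]) {
        dt <- min(dt, tt$start[k] - p0)
      } else {
        dt <- min(dt, p0 - tt$end[k] + 1)
      }
    }
    ok <- ok && dt < thr$target_dist
    af <- cand$pop_af[i]
    if (is.na(af)) af <- 0
    ok <- ok && af < thr$max_af
    pass[i] <- ok
  }
  pass
}

# random candidate set spanning every rule boundary
random_candidates <- function(n, targets) {
  tissues <- c("neuronal", "non_neuronal", "reference")
  cand <- data.frame(
    chrom = sample(unique(targets$chrom), n, replace = TRUE),
    pos = sample(500:12000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    specimen_id = sample(c("sp1", "sp2"), n, replace = TRUE),
    is_snv = sample(c(TRUE, TRUE, TRUE, FALSE), n, replace = TRUE),
    n_alleles = sample(c(2L, 2L, 2L, 1L, 3L), n, replace = TRUE),
    pop_af = sample(c(0, 0, 1e-5, 1e-3, 0.01), n, replace = TRUE),
    stringsAsFactors = FALSE)
  cand$alt <- vapply(cand$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  for (t in tissues) {
    cand[[paste0("depth_", t)]] <- sample(c(8L, 10L, 11L, 250L), n, TRUE)
    cand[[paste0("mq_", t)]] <- sample(c(5, 10, 10.5, 55), n, TRUE)
    cand[[paste0("bq_", t)]] <- sample(c(5, 10, 10.5, 33), n, TRUE)
  }
  cand
}

tiny_targets <- function() {
  data.frame(chrom = c("c1", "c1", "c2"),
             start = c(1000L, 5000L, 2000L),
             end = c(1150L, 5150L, 2150L), stringsAsFactors = FALSE)
}

# --- Wilcoxon oracle: full bitmask enumeration of group assignments ----
oracle_wilcoxon <- function(x, y, alternative = "two.sided") {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != nx) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    extreme <- switch(alternative,
                      greater = w >= obs - 1e-9,
                      less = w <= obs + 1e-9,
                      two.sided = abs(w - mu) >= abs(obs - mu) - 1e-9)
    if (extreme) hits <- hits + 1L
  }
  hits / total
}

# --- BH oracle: direct step-up definition ------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[o[i]] <- min(vapply(i:n, function(j) p[o[j]] * n / j, numeric(1)), 1)
  }
  adj
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
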