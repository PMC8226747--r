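# Independent oracles and fixture builders used across the suite.

# direct-loop 3x3 same-padded convolution (double precision)
naive_conv3x3 <- function(x, w, b) {
  d <- dim(x)
  co <- dim(w)[4]
  out <- array(0, c(d[1], d[2], co, d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(co)) for (h in seq_len(d[1]))
    for (wd in seq_len(d[2])) {
      s <- b[o]
      for (kh in 1:3) for (kw in 1:3) for (ci in seq_len(d[3])) {
        hh <- h + kh - 2; ww <- wd + kw - 2
        if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2])
          s <- s + x[hh, ww, ci, n] * w[kh, kw, ci, o]
      }
      out[h, wd, o, n] <- s
    }
  out
}

# pixel-set based metric oracles, written against the definitions directly
oracle_dice <- function(gt, pred) {
  g <- which(gt != 0); s <- which(pred != 0)
  if (length(g) + length(s) == 0) return(1)
  2 * length(intersect(g, s)) / (length(g) + length(s))
}

oracle_aji <- function(gt, pred) {
  K <- max(gt); L <- max(pred)
  if (K == 0 && L == 0) return(1)
  if (K == 0) return(0)
  gsets <- lapply(seq_len(K), function(k) which(gt == k))
  psets <- if (L > 0) lapply(seq_len(L), function(k) which(pred == k)) else list()
  used <- rep(FALSE, L)
  num <- 0; den <- 0
  for (i in seq_len(K)) {
    best <- 0; bestj <- 0; besti <- 0; bestu <- 0
    for (j in seq_len(L)) {
      if (used[j]) next
      inter <- length(intersect(gsets[[i]], psets[[j]]))
      uni <- length(union(gsets[[i]], psets[[j]]))
      jac <- if (uni > 0) inter / uni else 0
      if (jac > best) { best <- jac; bestj <- j; besti <- inter; bestu <- uni }
    }
    if (bestj > 0 && besti > 0) {
      num <- num + besti; den <- den + bestu; used[bestj] <- TRUE
    } else {
      den <- den + length(gsets[[i]])
    }
  }
  for (j in seq_len(L)) if (!used[j]) den <- den + length(psets[[j]])
  if (den == 0) return(1)
  num / den
}

# maximum-cardinality one-to-one matching among pairs with IoU >= threshold,
# by exhaustive assignment enumeration (small K, L only)
oracle_max_tp <- function(gt, pred, threshold = 0.5) {
  K <- max(gt); L <- max(pred)
  if (K == 0 || L == 0) return(0)
  iou <- matrix(0, K, L)
  for (i in seq_len(K)) for (j in seq_len(L)) {
    g <- which(gt == i); s <- which(pred == j)
    iou[i, j] <- length(intersect(g, s)) / length(union(g, s))
  }
  ok <- iou >= threshold
  best <- 0
  # recursively try all assignments of gt instances to preds (or none)
  rec <- function(i, usedp, count) {
    if (count + (K - i + 1) <= best) return()
    if (i > K) { best <<- max(best, count); return() }
    rec(i + 1, usedp, count)
    for (j in seq_len(L)) if (!usedp[j] && ok[i, j]) {
      usedp[j] <- TRUE
      rec(i + 1, usedp, count + 1)
      usedp[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, L), 0)
  best
}

# seeded random instance mask: up to max_inst rectangular-ish blobs on a
# small grid (brute-force-oracle friendly)
random_instance_mask <- function(h, w, max_inst) {
  m <- matrix(0L, h, w)
  n <- sample(0:max_inst, 1)
  for (k in seq_len(n)) {
    r0 <- sample(h, 1); c0 <- sample(w, 1)
    r1 <- min(h, r0 + sample(0:3, 1)); c1 <- min(w, c0 + sample(0:3, 1))
    m[r0:r1, c0:c1] <- k
  }
  # relabel contiguously (overwrites may erase an instance)
  ids <- setdiff(sort(unique(as.integer(m))), 0L)
  if (length(ids) > 0) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    m[m > 0] <- remap[m[m > 0]]
  }
  m
}

# tiny all-same-size training fixture
tiny_tiles <- function(n, hw = 64, seed = 5, rate = 3) {
  synth_tiles(n, canvas = c(hw, hw), n_nuclei = rate, n_styles = 2, seed = seed)
}
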