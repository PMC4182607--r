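# Independent oracles used across the suite. These deliberately use the
# slowest, most literal definition of each quantity and share no code with
# the implementation.

# brute-force Feret: max pairwise distance over the corner points of EVERY
# mask pixel (the implementation only uses boundary pixels + convex hull)
brute_feret <- function(mask, pixel_size_um = 1) {
  idx <- which(mask)
  nr <- nrow(mask)
  cc <- ((idx - 1) %/% nr) + 1
  rr <- ((idx - 1) %% nr) + 1
  x <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
  y <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 2) return(0)
  max(dist(pts)) * pixel_size_um
}

# random blobby mask: union of a few disks on a small grid
random_blob_mask <- function(nr = 48, nc = 48, n_disks = 3) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_disks)) {
    cx <- runif(1, 5, nc - 4); cy <- runif(1, 5, nr - 4)
    r <- runif(1, 2, 9)
    xs <- pmax(1, floor(cx - r)):pmin(nc, ceiling(cx + r))
    ys <- pmax(1, floor(cy - r)):pmin(nr, ceiling(cy + r))
    for (x in xs) for (y in ys) if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- TRUE
  }
  if (!any(m)) m[round(nr / 2), round(nc / 2)] <- TRUE
  m
}

# exact two-sided signed-rank p by FULL enumeration of all 2^n sign patterns
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# literal step-up BH definition: sort ascending, p*m/rank, enforce
# monotonicity from the largest rank down, cap at 1, restore order
brute_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  adj <- ps * m / seq_len(k)
  for (i in (k - 1):1) if (k > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

# maximum bipartite matching by brute force over all injections (tiny inputs)
brute_matching <- function(d2, radius) {
  na <- nrow(d2); nb <- ncol(d2)
  best <- 0
  assign_next <- function(i, used_b, count) {
    if (count + (na - i + 1) <= best) return()
    if (i > na) { best <<- max(best, count); return() }
    assign_next(i + 1, used_b, count) # leave i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d2[i, j] <= radius^2) {
        used_b[j] <- TRUE
        assign_next(i + 1, used_b, count + 1)
        used_b[j] <- FALSE
      }
    }
  }
  assign_next(1, logical(nb), 0)
  best
}

# default small section spec used across imaging tests
quiet_spec <- function(...) {
  section_spec(...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
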