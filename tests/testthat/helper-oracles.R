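## Brute-force reference implementations, deliberately independent of the
## package internals: recursive flood fill on small grids, direct-summation
## statistics, recursive permutation enumeration.

## flood fill from (i, j) over equal-value cells; returns a logical matrix
bruteFlood <- function(mask, i, j, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  target <- mask[i, j]
  seen <- matrix(FALSE, nr, nc)
  queue <- list(c(i, j))
  seen[i, j] <- TRUE
  nb <- if (connectivity == 4)
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  else
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in nb) {
      q <- p + d
      if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
      if (!seen[q[1], q[2]] && mask[q[1], q[2]] == target) {
        seen[q[1], q[2]] <- TRUE
        queue <- c(queue, list(q))
      }
    }
  }
  seen
}

## connected-component labels by repeated flood fill
bruteLabel <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextLab <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      nextLab <- nextLab + 1L
      comp <- bruteFlood(mask, i, j, connectivity)
      lab[comp & mask != 0] <- nextLab
    }
  }
  lab
}

## hole filling: flood the background from every border cell (dual
## connectivity); unreached background becomes foreground
bruteFill <- function(mask, connectivity = 8) {
  bgConn <- if (connectivity == 8) 4 else 8
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if ((i == 1 || i == nr || j == 1 || j == nc) &&
        mask[i, j] == 0 && !reached[i, j])
      reached <- reached | bruteFlood(mask, i, j, bgConn)
  }
  out <- mask
  out[mask == 0 & !reached] <- 1L
  out
}

## Dice by direct voxel counting
bruteDice <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

## all permutations of 1..n by recursive insertion
brutePerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- brutePerms(n - 1)
  out <- NULL
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, setdiff(seq_len(n), pos)] <- sub
    out <- rbind(out, blk)
  }
  out
}

## exhaustive two-sided Spearman p: count permutations with |rho| >= |obs|
bruteSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  P <- brutePerms(length(x))
  rhos <- apply(P, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}
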