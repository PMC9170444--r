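# Independent brute-force scalar oracles and fixture generators.
# These deliberately use plain double loops (no vectorization shared with
# the implementation) so they can serve as independent references.

oracle_cost <- function(m, B, A, l) {
  total <- 0
  for (x in seq_along(A)) {
    for (y in seq_along(m)) {
      total <- total + B[x, y]^l * (m[y] - A[x])^2
    }
  }
  total
}

oracle_centers <- function(m, B, l) {
  f <- nrow(B)
  a <- numeric(f)
  for (x in seq_len(f)) {
    num <- 0
    den <- 0
    for (y in seq_along(m)) {
      num <- num + B[x, y]^l * m[y]
      den <- den + B[x, y]^l
    }
    a[x] <- num / den
  }
  a
}

oracle_membership <- function(m, A, l) {
  f <- length(A)
  B <- matrix(0, f, length(m))
  for (y in seq_along(m)) {
    r <- abs(m[y] - A)
    if (any(r == 0)) {
      B[, y] <- (r == 0) / sum(r == 0)
    } else {
      for (x in seq_len(f)) {
        B[x, y] <- 1 / sum((r[x] / r)^(2 / (l - 1)))
      }
    }
  }
  B
}

oracle_centers_spatial <- function(m, mb, B, l, theta) {
  f <- nrow(B)
  a <- numeric(f)
  for (x in seq_len(f)) {
    num <- 0
    den <- 0
    for (y in seq_along(m)) {
      num <- num + B[x, y]^l * (m[y] + theta * mb[y])
      den <- den + (1 + theta) * B[x, y]^l
    }
    a[x] <- num / den
  }
  a
}

oracle_kdist <- function(u, v, delta) 2 * (1 - exp(-(u - v)^2 / delta^2))

oracle_membership_kernel <- function(m, mb, A, l, theta, delta) {
  f <- length(A)
  B <- matrix(0, f, length(m))
  for (y in seq_along(m)) {
    D <- numeric(f)
    for (x in seq_len(f)) {
      D[x] <- oracle_kdist(m[y], A[x], delta) +
        theta * oracle_kdist(mb[y], A[x], delta)
    }
    if (any(D == 0)) {
      B[, y] <- (D == 0) / sum(D == 0)
    } else {
      for (x in seq_len(f)) {
        B[x, y] <- D[x]^(-1 / (l - 1)) / sum(D^(-1 / (l - 1)))
      }
    }
  }
  B
}

oracle_vpc <- function(B) {
  s <- 0
  for (x in seq_len(nrow(B))) for (y in seq_len(ncol(B))) s <- s + B[x, y]^2
  s / ncol(B)
}

oracle_vpe <- function(B) {
  s <- 0
  for (x in seq_len(nrow(B))) {
    for (y in seq_len(ncol(B))) {
      if (B[x, y] > 0) s <- s - B[x, y] * log(B[x, y])
    }
  }
  s / ncol(B)
}

oracle_vxb <- function(m, B, A, l) {
  num <- oracle_cost(m, B, A, l)
  sep <- Inf
  for (x in seq_along(A)) {
    for (e in seq_along(A)) {
      if (x != e) sep <- min(sep, (A[x] - A[e])^2)
    }
  }
  num / (length(m) * sep)
}

# AUC by Mann-Whitney pair counting, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# Best Youden J by exhaustive scan over every candidate threshold.
oracle_youden <- function(scores, labels) {
  best <- -Inf
  for (t0 in c(Inf, sort(unique(scores), decreasing = TRUE))) {
    sens <- sum(scores >= t0 & labels) / sum(labels)
    spec <- sum(!(scores >= t0) & !labels) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Random valid membership matrix (unit column sums), seeded.
random_membership <- function(f, n, seed) {
  set.seed(seed)
  B <- matrix(runif(f * n), f, n)
  sweep(B, 2, colSums(B), "/")
}

# All permutations of 1..k via a recursion distinct from the package's.
oracle_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# Small standard fixtures ----------------------------------------------

two_group_image <- function(n = 50, seed = 1) {
  set.seed(seed)
  gray_image(c(rnorm(n, 0, 0.05), rnorm(n, 100, 0.05)))
}

small_phantom_2d <- function(sigma = 0, seed = 1, shape = c(48, 48)) {
  make_phantom(shape = shape, sigma = sigma, seed = seed)
}
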