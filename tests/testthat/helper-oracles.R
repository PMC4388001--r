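# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the fast implementations.

# population with explicitly supplied haplotypes (2 rows per individual)
manual_population <- function(H, map, sex = NULL, generation = 0L) {
  n <- nrow(H) / 2
  coansel:::new_population(matrix(as.integer(H), nrow = nrow(H)),
                           seq_len(n),
                           sex %||% rep(c("M", "F"), length.out = n),
                           rep(as.integer(generation), n), map)
}

random_population <- function(n, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coansel::init_base(map, n)
}

# IBS coancestry by explicit enumeration of the 4 ordered gamete pairs
bf_fG <- function(H, cols = seq_len(ncol(H))) {
  n <- nrow(H) / 2
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (m in cols) {
        for (a in 0:1) {
          for (b in 0:1) {
            s <- s + (H[2 * i - 1 + a, m] == H[2 * k - 1 + b, m])
          }
        }
      }
      f[i, k] <- s / (4 * length(cols))
    }
  }
  f
}

# ROH coancestry by direct run enumeration with rle per chromosome
bf_fR <- function(H, chr, cols = seq_len(ncol(H)), min_run = 100) {
  n <- nrow(H) / 2
  chr <- chr[cols]
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (a in 0:1) {
        for (b in 0:1) {
          g1 <- H[2 * i - 1 + a, cols]
          g2 <- H[2 * k - 1 + b, cols]
          for (c in unique(chr)) {
            r <- rle(g1[chr == c] == g2[chr == c])
            s <- s + sum(r$lengths[r$values & r$lengths >= min_run])
          }
        }
      }
      f[i, k] <- s / (4 * length(cols))
    }
  }
  f
}

# VanRaden coancestry with p fixed, explicit double loop
bf_fV <- function(H, cols = seq_len(ncol(H)), p = 0.5) {
  n <- nrow(H) / 2
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      gi <- (H[2 * i - 1, cols] + H[2 * i, cols]) / 2
      gk <- (H[2 * k - 1, cols] + H[2 * k, cols]) / 2
      f[i, k] <- mean((gi - p) * (gk - p)) / (p * (1 - p))
    }
  }
  f
}

# Path-counting additive relationship: sum over common ancestors and pairs
# of non-overlapping ancestral paths of (1/2)^(L1+L2+1) (1 + F_ancestor).
bf_A_paths <- function(ped) {
  id <- ped$id
  par <- function(i) {
    p <- c(ped$sire[match(i, id)], ped$dam[match(i, id)])
    p[!is.na(p)]
  }
  paths_up <- function(i) {
    out <- list(c(i))
    for (p in par(i)) {
      out <- c(out, lapply(paths_up(p), function(pa) c(i, pa)))
    }
    out
  }
  Fcoef <- function(i) {
    p <- c(ped$sire[match(i, id)], ped$dam[match(i, id)])
    if (anyNA(p)) return(0)
    fpair(p[1], p[2])
  }
  fpair <- function(i, j) {
    if (i == j) return(0.5 * (1 + Fcoef(i)))
    s <- 0
    for (p1 in paths_up(i)) {
      for (p2 in paths_up(j)) {
        anc <- p1[length(p1)]
        if (anc != p2[length(p2)]) next
        # paths may only share the common ancestor itself
        if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
        s <- s + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + Fcoef(anc))
      }
    }
    s
  }
  n <- length(id)
  A <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      A[a, b] <- 2 * fpair(id[a], id[b])
    }
  }
  A
}

# GLS/BLUP closed form for the animal model with X = 1, Z = I
bf_gls_blup <- function(y, K, sigma2_a, sigma2_e, ridge = 0) {
  V <- sigma2_a * K + sigma2_e * diag(length(y))
  Vi <- solve(V)
  one <- rep(1, length(y))
  mu <- drop(t(one) %*% Vi %*% y) / drop(t(one) %*% Vi %*% one)
  u <- drop(sigma2_a * K %*% Vi %*% (y - mu))
  list(mu_hat = mu, ebv = unname(u))
}

# balanced one-way ANOVA variance components (q groups of m records)
bf_anova_vc <- function(y, group) {
  m <- length(y) / length(unique(group))
  gm <- tapply(y, group, mean)
  msb <- m * sum((gm - mean(y))^2) / (length(gm) - 1)
  mse <- sum((y - gm[group])^2) / (length(y) - length(gm))
  list(sigma2_a = (msb - mse) / m, sigma2_e = mse)
}

# pedigree for two full sibs (founders 1, 2; sibs 3, 4)
full_sib_pedigree <- function() {
  tibble::tibble(id = 1:4,
                 sire = c(NA, NA, 1L, 1L),
                 dam = c(NA, NA, 2L, 2L),
                 sex = c("M", "F", "M", "F"),
                 generation = c(0L, 0L, 1L, 1L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
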