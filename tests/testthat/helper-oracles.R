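# Independent oracles used to validate the package's fast implementations.
# Each one is a deliberately naive computation of the same quantity.

# Genotype posteriors by exhaustive enumeration of all K^(2L) ordered
# copying paths of the diploid HMM (feasible for L <= 4, K <= 3).
brute_force_posterior <- function(H, obs, rho, eps) {
  K <- nrow(H)
  L <- ncol(H)
  p1 <- c(eps, 1 - eps)
  em <- array(0, c(2, 2, 3))
  for (a1 in 0:1) for (a2 in 0:1) {
    q1 <- p1[a1 + 1]; q2 <- p1[a2 + 1]
    em[a1 + 1, a2 + 1, 1] <- (1 - q1) * (1 - q2)
    em[a1 + 1, a2 + 1, 2] <- q1 * (1 - q2) + (1 - q1) * q2
    em[a1 + 1, a2 + 1, 3] <- q1 * q2
  }
  A <- lapply(rho, function(r) (1 - r) * diag(K) + r / K)
  sj <- rep(seq_len(K), times = K)   # state s -> haplotype pair (sj, sk)
  sk <- rep(seq_len(K), each = K)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(K^2)), L)))
  pr <- rep(1 / K^2, nrow(paths))
  for (m in seq_len(L)) {
    s <- paths[, m]
    if (m > 1) {
      sp <- paths[, m - 1]
      pr <- pr * A[[m - 1]][cbind(sj[sp], sj[s])] *
        A[[m - 1]][cbind(sk[sp], sk[s])]
    }
    if (obs[m] >= 0) {
      pr <- pr * em[cbind(H[sj[s], m] + 1, H[sk[s], m] + 1, obs[m] + 1)]
    }
  }
  post <- matrix(0, 3, L)
  for (m in seq_len(L)) {
    s <- paths[, m]
    for (g in 1:3) {
      post[g, m] <- sum(pr * em[cbind(H[sj[s], m] + 1, H[sk[s], m] + 1, g)])
    }
  }
  post / sum(pr)
}

# Literal, quadratic application of the thinning rule: rescan all
# within-chromosome adjacent intervals every iteration, remove the
# lower-MAF member of the globally closest pair (ties: first pair in
# (chrom, bp) order; equal MAF: right member).
brute_force_thin <- function(markers, target_count) {
  m <- markers[order(match(markers$chrom, unique(markers$chrom)), markers$bp), ]
  while (nrow(m) > target_count) {
    gaps <- data.frame(i = integer(0), gap = numeric(0))
    for (r in seq_len(nrow(m) - 1)) {
      if (m$chrom[r] == m$chrom[r + 1]) {
        gaps <- rbind(gaps, data.frame(i = r, gap = m$bp[r + 1] - m$bp[r]))
      }
    }
    i <- gaps$i[which.min(gaps$gap)]
    drop <- if (m$maf[i] < m$maf[i + 1]) i else i + 1
    m <- m[-drop, ]
  }
  m$marker_id
}

# Dense, single-block solve of the weighted SNP-BLUP normal equations.
brute_force_mme <- function(y, X, rel, lambda) {
  rel <- pmin(pmax(rel, 0.01), 0.99)
  Rinv <- diag(rel / (1 - rel), length(rel))
  one <- rep(1, length(y))
  C <- rbind(
    c(crossprod(one, Rinv %*% one), crossprod(one, Rinv %*% X)),
    cbind(crossprod(X, Rinv %*% one),
          crossprod(X, Rinv %*% X) + diag(lambda, ncol(X)))
  )
  sol <- solve(C, c(crossprod(one, Rinv %*% y), crossprod(X, Rinv %*% y)))
  list(mu = sol[1], g = sol[-1])
}

# Monte-Carlo kinship by gene dropping allele labels through the pedigree:
# the probability that one random allele from each of i and j is identical
# by descent, averaged over replicates (vectorised across replicates).
gene_drop_kinship <- function(ped, n_rep = 1e5) {
  n <- nrow(ped)
  ids <- ped$animal_id
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  a1 <- matrix(0L, n, n_rep)
  a2 <- matrix(0L, n, n_rep)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[i, ] <- lab + 1L
      a2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
      pick <- stats::runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
      (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
    est[i, j] <- est[j, i] <- mean(ibd) / 4
  }
  est
}
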