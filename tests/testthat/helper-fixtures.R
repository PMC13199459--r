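# Fixtures built in code: Gaussian blob classification sets, registry-count
# crash tables, and the convex-QP oracle for the Crammer-Singer primal.

# Three 2-D Gaussian blobs; `spread` controls class overlap.
make_blob_data <- function(n_per_class, spread = 0.9, scale = 1, seed = 42) {
  centers <- matrix(c(0, 0, 2.5, 0, 1.2, 2.2), 3, 2, byrow = TRUE) * scale
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:3, function(j) {
      cbind(rnorm(n_per_class, centers[j, 1], spread),
            rnorm(n_per_class, centers[j, 2], spread))
    }))
  })
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(1:3, each = n_per_class))
}

# Crash table reproducing the registry's marginal counts relevant to the
# descriptive checks: severity 169/448/151 and second-vehicle counts
# truck 300 / bus 11 / motorcycle 78 / none 379 (rows assigned in blocks;
# only the column counts matter for the shares under test).
registry_count_table <- function() {
  n <- 768L
  truck <- c(rep(1L, 300), rep(0L, n - 300))
  bus <- c(rep(0L, 300), rep(1L, 11), rep(0L, n - 311))
  moto <- c(rep(0L, 311), rep(1L, 78), rep(0L, n - 389))
  tibble::tibble(
    Truck_Involved = truck,
    Bus_Involved = bus,
    Motorcycle_Involved = moto,
    severity = rep(1:3, c(169L, 448L, 151L))
  )
}

# Generic convex-QP oracle for the bias-augmented Crammer-Singer primal:
#   min 1/2 sum_j ||w_j||^2 + C sum_i xi_i
#   s.t. (w_{y_i} - w_j) . x~_i + xi_i >= 1 (j != y_i), xi_i >= 0
# with x~ = (x, 1).  Solved by kernlab's interior-point QP; the tiny ridge
# on the slack block keeps the Hessian positive definite.
qp_mcsvm_oracle <- function(X, y, C) {
  Xa <- cbind(X, 1)
  n <- nrow(Xa)
  p <- ncol(Xa)
  k <- 3L
  nv <- k * p + n
  H <- diag(c(rep(1, k * p), rep(1e-8, n)))
  cvec <- c(rep(0, k * p), rep(C, n))
  rows <- list()
  for (i in seq_len(n)) {
    for (j in setdiff(1:k, y[i])) {
      a <- numeric(nv)
      a[(y[i] - 1L) * p + seq_len(p)] <- Xa[i, ]
      a[(j - 1L) * p + seq_len(p)] <- -Xa[i, ]
      a[k * p + i] <- 1
      rows[[length(rows) + 1L]] <- a
    }
  }
  A <- do.call(rbind, rows)
  sol <- kernlab::ipop(
    cvec, H, A, b = rep(1, nrow(A)),
    l = c(rep(-100, k * p), rep(0, n)),
    u = c(rep(100, k * p), rep(1e4, n)),
    r = rep(1e6, nrow(A)), sigf = 9, maxiter = 200
  )
  z <- kernlab::primal(sol)
  W <- matrix(z[seq_len(k * p)], k, p, byrow = TRUE)
  xi <- z[(k * p + 1L):nv]
  list(W = W, xi = xi, objective = 0.5 * sum(W^2) + C * sum(xi))
}

# Brute-force pairwise AUC: probability that a positive outscores a
# negative, counting ties as one half.
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}
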