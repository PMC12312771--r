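# Brute-force oracles, deliberately simpler than (and sharing no code with)
# the production implementations.

# Covariance of a recursive linear system by explicit substitution: express
# each variable as a linear combination of the residuals, equation by
# equation, then apply the residual covariance.
oracle_recursive_cov <- function(B, Psi) {
  p <- nrow(B)
  A <- matrix(0, p, p)     # y = A %*% zeta, filled in topological order
  remaining <- seq_len(p)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(m)
      all(which(B[m, ] != 0) %in% setdiff(seq_len(p), remaining)), logical(1))]
    stopifnot(length(ready) > 0)   # acyclic input assumed
    for (m in ready) {
      A[m, ] <- B[m, , drop = FALSE] %*% A
      A[m, m] <- A[m, m] + 1
    }
    remaining <- setdiff(remaining, ready)
  }
  A %*% Psi %*% t(A)
}

# Dense multivariate-normal log-likelihood of a two-level dataset: build each
# cluster's full (n_j * p) covariance matrix explicitly and evaluate the
# normal density.
oracle_dense_loglik <- function(ds, sigma_w, sigma_b, mu) {
  v <- ds$variables
  names(mu) <- v
  ll <- 0
  for (s in ds$studies) {
    vs <- colnames(s$Y)
    stopifnot(s$n * length(vs) <= 200)  # memory guard: oracle stays tiny
    SW <- sigma_w[vs, vs]; SB <- sigma_b[vs, vs]
    n <- s$n
    Omega <- kronecker(diag(n), SW) + kronecker(matrix(1, n, n), SB)
    y <- as.vector(t(s$Y[, vs])) - rep(mu[vs], n)
    R <- chol(Omega)
    z <- backsolve(R, y, transpose = TRUE)
    ll <- ll - 0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(z^2))
  }
  ll
}

# Dense-likelihood optimizer for the saturated two-level model on a tiny
# balanced dataset: direct search over Cholesky factors of both covariance
# matrices and the mean vector.
oracle_saturated_fit <- function(ds) {
  p <- length(ds$variables)
  nlt <- p * (p + 1) / 2
  unpack <- function(x, off) {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- x[off + seq_len(nlt)]
    diag(L) <- exp(diag(L))
    M <- L %*% t(L)
    dimnames(M) <- list(ds$variables, ds$variables)
    M
  }
  Y <- do.call(rbind, lapply(ds$studies, function(s) s$Y[, ds$variables]))
  S0 <- cov(Y) / 2
  pack <- function(S) { L <- t(chol(S)); diag(L) <- log(diag(L))
                        L[lower.tri(L, diag = TRUE)] }
  x0 <- c(pack(S0), pack(S0), colMeans(Y))
  neg <- function(x)
    tryCatch(-oracle_dense_loglik(ds, unpack(x, 0), unpack(x, nlt),
                                  x[2 * nlt + seq_len(p)]),
             error = function(e) 1e10)
  opt <- optim(x0, neg, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(loglik = -opt$value, sigma_w = unpack(opt$par, 0),
       sigma_b = unpack(opt$par, nlt))
}

# Path coefficients by ordered regressions computed directly from a
# covariance matrix (normal equations per outcome).
oracle_regression_paths <- function(S, outcomes) {
  # outcomes: named list outcome -> predictor vector
  out <- list()
  for (y in names(outcomes)) {
    x <- outcomes[[y]]
    out[[y]] <- drop(solve(S[x, x, drop = FALSE]) %*% S[x, y])
    names(out[[y]]) <- x
  }
  out
}

tpb_outcomes <- function() list(INT = c("ATT", "SN", "PBC"),
                                BEH = c("PBC", "INT"))

# Toy fixture: 6 small studies from the equal-structure scenario, optionally
# with the behavior variable masked in half of them.
make_toy_dataset <- function(seed = 1, masked = FALSE) {
  set.seed(seed)
  ds <- simulate_meta_dataset(get_scenario("S4"), k = 6, n_min = 8, n_max = 12)
  if (masked) ds <- apply_missingness(ds)
  ds
}

random_pd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}
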