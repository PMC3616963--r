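#' GTR+Gamma model parameters
#'
#' Container for a general time-reversible nucleotide model with optional
#' discrete-Gamma rate variation across sites. Exchangeabilities are given in
#' the order AC, AG, AT, CG, CT, GT (the GT rate is conventionally the one
#' fixed to 1 during optimization). The rate matrix is rescaled so that one
#' unit of branch length equals one expected substitution per site.
#'
#' @param rates Six positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param freqs Four stationary base frequencies (A, C, G, T) summing to 1.
#' @param gamma_shape Positive shape of the Gamma rate distribution, or
#'   `NULL` for rate homogeneity across sites.
#' @param n_categories Number of discrete Gamma categories (default 4).
#' @return An object of class `gtr_params`.
#' @export
gtr_params <- function(rates = c(1, 1, 1, 1, 1, 1),
                       freqs = rep(0.25, 4),
                       gamma_shape = NULL,
                       n_categories = 4L) {
  rates <- as.numeric(rates)
  freqs <- as.numeric(freqs)
  stopifnot(length(rates) == 6L, length(freqs) == 4L)
  if (any(rates <= 0)) stop("GTR exchangeabilities must be positive")
  if (any(freqs <= 0)) stop("base frequencies must be positive")
  if (abs(sum(freqs) - 1) > 1e-12) stop("base frequencies must sum to 1")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  structure(list(rates = rates, freqs = freqs,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "gtr_params")
}

# Instantaneous GTR rate matrix, scaled to one expected substitution
# per unit branch length. Rows/cols ordered A, C, G, T.
gtr_rate_matrix <- function(p) {
  r <- p$rates
  pi <- p$freqs
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  Q[1, 2] <- r[1] * pi[2]; Q[1, 3] <- r[2] * pi[3]; Q[1, 4] <- r[3] * pi[4]
  Q[2, 1] <- r[1] * pi[1]; Q[2, 3] <- r[4] * pi[3]; Q[2, 4] <- r[5] * pi[4]
  Q[3, 1] <- r[2] * pi[1]; Q[3, 2] <- r[4] * pi[2]; Q[3, 4] <- r[6] * pi[4]
  Q[4, 1] <- r[3] * pi[1]; Q[4, 2] <- r[5] * pi[2]; Q[4, 3] <- r[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigen-decomposition of the (reversible) GTR generator via similarity
# transform with diag(sqrt(pi)); numerically stable because the transformed
# matrix is symmetric. Returns U, Uinv, values with Q = U diag(v) Uinv.
gtr_eigen <- function(p) {
  Q <- gtr_rate_matrix(p)
  pi <- p$freqs
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- diag(1 / s) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(s)
  list(values = e$values, U = U, Uinv = Uinv)
}

# Transition probability matrix P(t) = exp(Qt).
gtr_prob_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Mean relative rates of the n discrete Gamma(shape, shape) categories,
# computed as the exact mean of each quantile bin.
discrete_gamma_rates <- function(shape, n_categories = 4L) {
  if (is.null(shape)) return(1)
  k <- n_categories
  q <- qgamma(seq_len(k - 1) / k, shape = shape, rate = shape)
  bounds <- c(0, q, Inf)
  # E[X; a<X<b] for X~Gamma(shape,shape) equals P(a < Y < b) with
  # Y~Gamma(shape+1, shape); each bin has mass 1/k.
  upper <- pgamma(bounds[-1], shape = shape + 1, rate = shape)
  lower <- pgamma(bounds[-(k + 1)], shape = shape + 1, rate = shape)
  r <- k * (upper - lower)
  r / mean(r) * 1  # guard against tiny numerical drift; mean must be 1
}
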