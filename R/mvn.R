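# Vectorised low-dimensional multivariate normal CDFs.
#
# The selection-bias integrals evaluate a (K-1)-dimensional normal orthant
# probability at every quadrature node, with a correlation matrix that is
# fixed across nodes and only the integration limits varying.  For K-1 = 2, 3
# the CDF has classical one-dimensional integral representations (tetrachoric
# series / Plackett's identity) that vectorise over a whole batch of limits,
# which is what makes the Stallard-Todd fixed-point iteration affordable.
# mvtnorm::pmvnorm (deterministic Miwa algorithm) handles dimension >= 4 and
# serves as the reference implementation in the tests.

gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  gl_cache[[key]]
}

# standard bivariate normal density at (x, y) with correlation r (vectorised)
dbvn <- function(x, y, r) {
  omr2 <- 1 - r^2
  exp(-(x^2 - 2 * r * x * y + y^2) / (2 * omr2)) / (2 * pi * sqrt(omr2))
}

# P(X1 <= b1, X2 <= b2) for standard bivariate normal with correlation rho,
# vectorised over the limits.  Plackett/Drezner-Wesolowsky: the CDF equals the
# independent case plus the integral of the bivariate density along the
# correlation path 0 -> rho.
pbvnorm <- function(b1, b2, rho, nodes = 48L) {
  n <- max(length(b1), length(b2))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n)
  if (abs(rho) < .Machine$double.eps) return(pnorm(b1) * pnorm(b2))
  if (abs(rho) > 0.925) {
    # near-singular correlation: defer to mvtnorm elementwise
    R <- matrix(c(1, rho, rho, 1), 2)
    return(vapply(seq_len(n), function(i) {
      as.numeric(mvtnorm::pmvnorm(upper = c(b1[i], b2[i]), corr = R,
                                  algorithm = mvtnorm::Miwa(steps = 512)))
    }, double(1)))
  }
  gl <- gl_rule(nodes)
  r <- rho * (gl$x + 1) / 2            # nodes on (0, rho)
  w <- gl$w * rho / 2
  omr2 <- 1 - r^2
  # bivariate density at (b1, b2) for every (limit, node) pair, as outer ops
  dens <- exp(-outer(b1^2 + b2^2, 1 / (2 * omr2)) +
                outer(b1 * b2, r / omr2))
  pnorm(b1) * pnorm(b2) + drop(dens %*% (w / (2 * pi * sqrt(omr2))))
}

# P(X <= b) for standard trivariate normal, vectorised over rows of the n x 3
# limit matrix B; rho = (r21, r31, r32).  Plackett's identity along the linear
# correlation path from (0, 0, r32) to (r21, r31, r32): the derivative in t is
# a bivariate density at the two pivot limits times the conditional normal CDF
# of the remaining coordinate.
ptvnorm <- function(B, rho, nodes = 48L) {
  B <- matrix(B, ncol = 3)
  r21 <- rho[1]; r31 <- rho[2]; r32 <- rho[3]
  b1 <- B[, 1]; b2 <- B[, 2]; b3 <- B[, 3]
  if (max(abs(c(r21, r31))) < .Machine$double.eps) {
    return(pnorm(b1) * pbvnorm(b2, b3, r32, nodes))
  }
  if (max(abs(rho)) > 0.925) {
    R <- diag(3)
    R[2, 1] <- R[1, 2] <- r21; R[3, 1] <- R[1, 3] <- r31
    R[3, 2] <- R[2, 3] <- r32
    return(vapply(seq_len(nrow(B)), function(i) {
      as.numeric(mvtnorm::pmvnorm(upper = B[i, ], corr = R,
                                  algorithm = mvtnorm::Miwa(steps = 512)))
    }, double(1)))
  }
  gl <- gl_rule(nodes)
  t <- (gl$x + 1) / 2                  # path parameter on (0, 1)
  w <- gl$w / 2

  # contribution of one moving pair (limits bi, bj, rate r_move), with the
  # remaining coordinate bl conditioned on (Xi, Xj) = (bi, bj); all node-level
  # quantities are scalars per node, so everything reduces to outer products
  pair_contrib <- function(bi, bj, bl, r_move, r_other) {
    q <- t * r_move                    # correlation of the moving pair
    c1 <- t * r_other                  # corr(Xl, Xi) along the path
    c2 <- r32                          # corr(Xl, Xj), fixed
    omq2 <- 1 - q^2
    s <- sqrt(pmax(1 - (c1^2 - 2 * q * c1 * c2 + c2^2) / omq2, 1e-300))
    dens <- exp(-outer(bi^2 + bj^2, 1 / (2 * omq2)) +
                  outer(bi * bj, q / omq2)) /
      matrix(2 * pi * sqrt(omq2), length(bi), length(t), byrow = TRUE)
    mu <- outer(bi, (c1 - c2 * q) / omq2) + outer(bj, (c2 - c1 * q) / omq2)
    z <- (bl - mu) / matrix(s, length(bi), length(t), byrow = TRUE)
    drop((dens * pnorm(z)) %*% (w * r_move))
  }

  pnorm(b1) * pbvnorm(b2, b3, r32, nodes) +
    pair_contrib(b1, b2, b3, r21, r31) +
    pair_contrib(b1, b3, b2, r31, r21)
}

# P(X <= b) for a standard MVN with correlation matrix R, batched over rows
# of B; dispatches on dimension.
pmvn_batch <- function(B, R) {
  d <- ncol(B)
  if (d == 1) return(pnorm(B[, 1]))
  if (d == 2) return(pbvnorm(B[, 1], B[, 2], R[2, 1]))
  if (d == 3) return(ptvnorm(B, c(R[2, 1], R[3, 1], R[3, 2])))
  alg <- mvtnorm::Miwa(steps = 512)
  vapply(seq_len(nrow(B)), function(i) {
    as.numeric(mvtnorm::pmvnorm(upper = B[i, ], corr = R, algorithm = alg))
  }, double(1))
}
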