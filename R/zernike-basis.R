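# Construction of the Zernike-Canterakis basis functions Z_nlm as complex
# polynomials in Cartesian coordinates.  Each basis function is the product of
# a radial polynomial R_nl(r) (even powers of r above r^l) and a solid
# harmonic r^l Y_lm(theta, phi), both of which expand into finite sums of
# monomials x^a y^b z^c.  Working with the monomial expansion lets moments be
# assembled from geometric moments of the voxel grid in a single pass.

# A polynomial in (x, y, z) of maximum total degree `deg` is stored as a
# complex array coef[a+1, b+1, c+1] = coefficient of x^a y^b z^c.

.poly_zero <- function(deg) {
  array(complex(real = 0), dim = rep(deg + 1L, 3L))
}

.poly_mult <- function(p, q, deg) {
  out <- .poly_zero(deg)
  nz <- which(p != 0, arr.ind = TRUE)
  qz <- which(q != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L || nrow(qz) == 0L) return(out)
  for (i in seq_len(nrow(nz))) {
    ia <- nz[i, ]
    pv <- p[ia[1L], ia[2L], ia[3L]]
    idx <- sweep(qz, 2L, ia - 1L, "+")
    keep <- rowSums(idx - 1L) <= deg
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) next
    vals <- q[qz[keep, , drop = FALSE]] * pv
    out[idx] <- out[idx] + vals
  }
  out
}

# coefficients of the Legendre polynomial P_l(u) in the monomial basis
.legendre_coef <- function(l) {
  # coefficient vectors padded to fixed length l + 1
  pad <- function(v) c(v, numeric(l + 1L - length(v)))
  if (l == 0L) return(1)
  pm1 <- pad(1)                # P_0
  p <- pad(c(0, 1))            # P_1
  if (l == 1L) return(p)
  for (k in 1L:(l - 1L)) {
    up <- c(0, p)[seq_len(l + 1L)]              # u * P_k, truncated pad
    nxt <- ((2 * k + 1) * up - k * pm1) / (k + 1)
    pm1 <- p
    p <- nxt
  }
  p
}

# m-th derivative of a polynomial given by its coefficient vector
.poly_deriv <- function(coef, m) {
  for (i in seq_len(m)) {
    if (length(coef) <= 1L) return(0)
    coef <- coef[-1L] * seq_len(length(coef) - 1L)
  }
  coef
}

# r^2 = x^2 + y^2 + z^2 raised to the e-th power, as a monomial array
.poly_r2_pow <- function(e, deg) {
  out <- .poly_zero(deg)
  if (e == 0L) {
    out[1L, 1L, 1L] <- 1
    return(out)
  }
  for (i in 0:e) for (j in 0:(e - i)) {
    k <- e - i - j
    out[2L * i + 1L, 2L * j + 1L, 2L * k + 1L] <-
      factorial(e) / (factorial(i) * factorial(j) * factorial(k))
  }
  out
}

# (x + iy)^m as a monomial array
.poly_xiy_pow <- function(m, deg) {
  out <- .poly_zero(deg)
  for (j in 0:m) {
    out[m - j + 1L, j + 1L, 1L] <- choose(m, j) * (1i)^j
  }
  out
}

# Solid harmonic r^l Y_lm scaled by sqrt(4*pi), i.e. normalized so that the
# integral of |e_lm|^2 over the unit sphere is 4*pi.  Uses the associated
# Legendre function with the Condon-Shortley phase.
.solid_harmonic_poly <- function(l, m, deg) {
  stopifnot(m >= 0L, m <= l)
  dm <- .poly_deriv(.legendre_coef(l), m)       # d^m/du^m P_l(u)
  norm <- sqrt((2 * l + 1) * exp(lfactorial(l - m) - lfactorial(l + m)))
  phase <- (-1)^m
  xiy <- .poly_xiy_pow(m, deg)
  out <- .poly_zero(deg)
  for (j in seq_along(dm)) {
    bj <- dm[j]
    if (bj == 0) next
    jz <- j - 1L                                # power of z
    e <- (l - m - jz) / 2L                      # power of r^2
    term <- .poly_r2_pow(e, deg)
    zsh <- .poly_zero(deg)
    zsh[1L, 1L, jz + 1L] <- bj
    term <- .poly_mult(term, zsh, deg)
    out <- out + term
  }
  .poly_mult(out, xiy, deg) * (norm * phase)
}

# Radial expansion coefficients q_klv of R_nl(r) = sum_v q_klv r^(2v + l),
# normalized so that (3/4pi) * Int_{|x|<=1} |Z_nlm|^2 dx = 1.
.radial_coef <- function(n, l) {
  k <- (n - l) %/% 2L
  v <- 0:k
  (-1)^k / 4^k * sqrt((2 * n + 3) / 3) * choose(2 * k, k) *
    (-1)^v * choose(k, v) * choose(2 * (k + l + v) + 1, 2 * k) /
    choose(k + l + v, k)
}

# All valid (n, l) pairs up to `order`: 0 <= l <= n, (n - l) even,
# in (n ascending, l ascending) order.
.nl_pairs <- function(order) {
  out <- NULL
  for (n in 0:order) {
    l <- seq.int(n %% 2L, n, by = 2L)
    out <- rbind(out, cbind(n = n, l = l))
  }
  out
}

# Sparse monomial table for Z_nlm (m >= 0): data.frame of exponents and
# complex coefficients.  Moments for m < 0 follow from conjugate symmetry.
.zernike_basis_table <- function(order) {
  pairs <- .nl_pairs(order)
  basis <- vector("list", 0L)
  for (row in seq_len(nrow(pairs))) {
    n <- pairs[row, "n"]; l <- pairs[row, "l"]
    q <- .radial_coef(n, l)
    for (m in 0:l) {
      harm <- .solid_harmonic_poly(l, m, order)
      poly <- .poly_zero(order)
      for (v in seq_along(q)) {
        poly <- poly + .poly_mult(.poly_r2_pow(v - 1L, order), harm, order) * q[v]
      }
      nz <- which(poly != 0, arr.ind = TRUE)
      basis[[length(basis) + 1L]] <- list(
        n = n, l = l, m = m,
        a = nz[, 1L] - 1L, b = nz[, 2L] - 1L, c = nz[, 3L] - 1L,
        coef = poly[nz]
      )
    }
  }
  basis
}

# Basis tables are expensive to build at high order; memoize per order.
.basis_cache <- new.env(parent = emptyenv())

.zernike_basis <- function(order) {
  key <- as.character(order)
  if (is.null(.basis_cache[[key]])) {
    .basis_cache[[key]] <- .zernike_basis_table(order)
  }
  .basis_cache[[key]]
}

# Dense conversion operator: moments (m >= 0) = C %*% geometric-moment
# vector.  Rows follow the basis list order; columns are monomials indexed
# linearly as a + b*(order+1) + c*(order+1)^2 + 1.  Coefficients are
# pre-conjugated and carry the 3/(4 pi) prefactor of the moment integral.
.zernike_operator <- function(order) {
  key <- paste0("op", order)
  if (is.null(.basis_cache[[key]])) {
    basis <- .zernike_basis(order)
    k <- order + 1L
    C <- matrix(complex(real = 0), nrow = length(basis), ncol = k^3)
    for (i in seq_along(basis)) {
      b <- basis[[i]]
      lin <- b$a + b$b * k + b$c * k * k + 1L
      C[i, lin] <- 3 / (4 * pi) * Conj(b$coef)
    }
    triples <- cbind(n = vapply(basis, function(b) as.integer(b$n), 1L),
                     l = vapply(basis, function(b) as.integer(b$l), 1L),
                     m = vapply(basis, function(b) as.integer(b$m), 1L))
    .basis_cache[[key]] <- list(C = C, triples = triples)
  }
  .basis_cache[[key]]
}

# Direct (non-polynomial) evaluation of Z_nlm at Cartesian points, through
# spherical coordinates and an associated-Legendre recurrence.  This is an
# independent route used to cross-check the monomial expansion.
.zernike_eval_spherical <- function(n, l, m, pts) {
  r <- sqrt(rowSums(pts^2))
  ct <- ifelse(r > 0, pts[, 3L] / r, 1)
  phi <- atan2(pts[, 2L], pts[, 1L])
  am <- abs(m)
  # associated Legendre P_l^am(ct) by recurrence, Condon-Shortley phase
  if (am == 0L) {
    pmm <- rep(1, length(ct))
  } else {
    dfact <- prod(seq.int(1L, 2L * am - 1L, by = 2L))
    pmm <- (-1)^am * dfact * (sqrt(pmax(1 - ct^2, 0)))^am
  }
  if (l == am) {
    plm <- pmm
  } else {
    pm1 <- pmm
    p <- (2 * am + 1) * ct * pmm
    if (l > am + 1L) {
      for (ll in (am + 2L):l) {
        nxt <- ((2 * ll - 1) * ct * p - (ll + am - 1) * pm1) / (ll - am)
        pm1 <- p
        p <- nxt
      }
    }
    plm <- p
  }
  ylm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lfactorial(l - am) - lfactorial(l + am))) *
    plm * exp(1i * am * phi)
  if (m < 0) ylm <- (-1)^am * Conj(ylm)
  q <- .radial_coef(n, l)
  rad <- numeric(length(r))
  for (v in seq_along(q)) rad <- rad + q[v] * r^(2 * (v - 1L) + l)
  sqrt(4 * pi) * rad * ylm
}
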