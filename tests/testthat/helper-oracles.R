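# Independent oracles used across the suite. None of these share code with
# the package implementation paths they check.

# closed-form simple linear regression (textbook normal equations)
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

# minimised RMSD by direct optimisation over Euler angles (multi-start
# Nelder-Mead); independent of the SVD-based superposition
rmsd_oracle <- function(mobile, reference) {
  rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) {
    r <- rot_z(p[1]) %*% rot_y(p[2]) %*% rot_z(p[3])
    sqrt(mean(rowSums((mc %*% t(r) - rc)^2)))
  }
  starts <- list(
    c(0, 0, 0), c(pi / 2, pi / 4, 0), c(pi, pi / 2, pi), c(-pi / 2, 1, 2),
    c(2.5, 2.5, -2.5), c(1, 3, 1), c(-2, 0.5, 3), c(0.3, 1.8, -1.1)
  )
  best <- Inf
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
    best <- min(best, o$value)
  }
  best
}

# all-pairs double-loop contact count with optional minimum image
contacts_oracle <- function(a, b, cutoff, box = NULL) {
  cnt <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# exhaustive scan for the first max-then-min pattern on a smoothed profile
first_min_oracle <- function(r, g, window) {
  half <- (window - 1) / 2
  n <- length(g)
  gs <- vapply(seq_len(n), function(i) {
    mean(g[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  imax <- NA
  for (i in 2:(n - 1)) {
    if (gs[i] > gs[i - 1] && gs[i] >= gs[i + 1]) { imax <- i; break }
  }
  if (is.na(imax)) return(NA_real_)
  for (i in seq(imax + 1, n - 1)) {
    if (gs[i] < gs[i - 1] && gs[i] <= gs[i + 1]) return(r[i])
  }
  NA_real_
}

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# assemble an RDF-profile-shaped object without running rdf()
make_profile <- function(r, g, rho, dr, count = rep(0, length(r))) {
  structure(
    tibble::tibble(r = r, g = g, count = count),
    bulk_density = rho, dr = dr, r_max = max(r) + dr / 2,
    n_frames = 1L, n_centers = 1L,
    class = c("hg_rdf", class(tibble::tibble()))
  )
}
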