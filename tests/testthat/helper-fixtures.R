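# Shared fixtures, built once per test run.

toy <- make_hinged_toy_protein()
toy_closed <- make_hinged_toy_protein(closure = 1)

# a random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# independent brute-force coordination number (plain double loop)
brute_coordination <- function(a, b, params) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt(sum((a[i, ] - b[j, ])^2))
      x <- (r - params$d0) / params$r0
      x <- max(x, 0)
      s <- if (abs(x - 1) < 1e-9) params$n / params$m else
        (1 - x^params$n) / (1 - x^params$m)
      total <- total + min(max(s, 0), 1)
    }
  }
  total
}

# independent brute-force cluster-count allocation, a literal
# transcription of the stated rule: allocate proportionally with
# half-away rounding, clip to the slice size, exempt sub-2-frame
# slices, inflate the total by the increment until every populated
# slice holds at least two clusters
brute_allocate <- function(sizes, base = 100, increment = 10) {
  n_tot <- sum(sizes)
  n_c <- base
  repeat {
    x <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
      xi <- floor(sizes[i] / n_tot * n_c + 0.5)
      x[i] <- min(xi, sizes[i])
      if (sizes[i] < 2) x[i] <- sizes[i]
    }
    ok <- TRUE
    for (i in seq_along(sizes)) {
      if (sizes[i] >= 2 && x[i] < 2) ok <- FALSE
    }
    if (ok) return(list(x = x, n_c = n_c))
    n_c <- n_c + increment
  }
}
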