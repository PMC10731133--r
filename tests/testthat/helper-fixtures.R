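# Shared fixtures and independent oracles used across test files.

# brute-force moving-window slope oracle: least-squares slope of every
# contiguous strain window, via lm() directly (independent of the
# cumulative-sum implementation in the package)
brute_force_max_slope <- function(strain, stress, window, min_points = 10) {
  n <- length(strain)
  best <- -Inf
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_points) next
      if (strain[j] - strain[i] > window * 1.5) break
      if (j - i + 1 >= min_points && strain[j] - strain[i] >= window ||
          j == n) {
        sl <- unname(coef(lm(stress[i:j] ~ strain[i:j]))[2])
        if (is.finite(sl) && sl > best) best <- sl
      }
    }
  }
  best
}

# manual Holm step-down oracle (definition, not p.adjust)
holm_oracle <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (k - seq_len(k) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

# random isotropic constants for contact oracles
random_isotropic <- function() {
  E <- runif(1, 5, 40)
  nu <- runif(1, 0.05, 0.45)
  list(E = E, nu = nu,
       constants = elastic_constants(E11 = E, E33 = E, nu12 = nu,
                                     nu31 = nu, G31 = E / (2 * (1 + nu))))
}

# small single-group cohort spec used by distribution tests
one_group_spec <- function(n_sites, group = "healthy") {
  g <- reference_cohort_params()
  g <- g[g$group == group, ]
  g$n_sites <- as.integer(n_sites)
  g
}

# synthetic band-fit stubs with prescribed areas (for ratio-level tests)
fake_fits <- function(a1, a3, apo) {
  lapply(seq_along(a1), function(i) {
    list(amide1 = list(area = a1[i]),
         amide3 = list(area = a3[i]),
         v1po4 = list(area = apo[i]))
  })
}
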