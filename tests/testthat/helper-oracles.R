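# Independent brute-force oracles used across the test files.  These stay
# deliberately naive: they check the package's optimized implementations
# against direct definitions.

# All images of a state under the group, by explicit permutation.
oracle_orbit <- function(state, group = dioxin_symmetry_group()) {
  unique(lapply(group, function(p) state[p]))
}

# Orbit-minimum by enumerating the orbit and sorting the collapsed strings
# under the rank alphabet H < Cl < Br.
oracle_canonical <- function(state, group = dioxin_symmetry_group()) {
  orb <- oracle_orbit(state, group)
  keys <- vapply(orb, function(s) {
    paste(match(s, c("H", "Cl", "Br")), collapse = "")
  }, character(1))
  orb[[order(keys)[1L]]]
}

# All k^8 raw states over an alphabet, as a list.
oracle_all_states <- function(alphabet) {
  grid <- do.call(expand.grid, c(rep(list(alphabet), 8),
                                 stringsAsFactors = FALSE))
  # expand.grid varies the FIRST factor fastest; orientation is irrelevant
  # for counting orbits
  lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
}

# Exhaustive reference Kennard-Stone: same maximin rule, naive O(n^2 k)
# recomputation at every step, ties to the lowest index (pairs scanned in
# column-major order of the upper triangle, matching the package rule).
oracle_kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  best <- NULL
  bestd <- -Inf
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (d[i, j] > bestd) {
        bestd <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mind <- sapply(cand, function(i) min(d[i, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# Ordinary least squares via the normal equations, with the same autoscaling
# convention as fit_pls, returning predictions on the original scale.
oracle_ols_predict <- function(X, y, Xnew) {
  sx <- nanoqspr::autoscale(as.matrix(X))
  ym <- mean(y)
  ysd <- sd(y)
  b <- solve(crossprod(sx$x), crossprod(sx$x, (y - ym) / ysd))
  xs <- nanoqspr::apply_scaling(as.matrix(Xnew), sx$center, sx$scale)
  ym + ysd * as.vector(xs %*% b)
}

# A small random congener state under a fixed RNG stream.
random_state <- function() {
  sample(c("H", "Cl", "Br"), 8, replace = TRUE)
}

# Shared small synthetic scenario: full congener set, descriptors and
# energies at a given noise level.
make_scenario <- function(noise_sd = 0, seed = 7L, nuisance_cor = 0) {
  params <- generator_params(noise_sd = noise_sd, seed = seed,
                             nuisance_cor = nuisance_cor)
  tab <- congener_table()
  desc <- generate_descriptor_table(tab, params)
  en <- generate_adsorption_energies(desc, params)
  list(params = params, congeners = tab, descriptors = desc,
       energies = en)
}
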