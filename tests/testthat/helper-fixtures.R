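# Small in-code fixture builders shared across test files.

# A valid boundary set with random smooth-ish interfaces on an nb x na
# grid: random positive layer thicknesses on top of a random base.
random_boundary_set <- function(nb = 6, nc = 5, depth = 200) {
  base <- matrix(runif(nb * nc, 5, 20), nb, nc)
  depths <- array(0, dim = c(7, nb, nc))
  depths[1, , ] <- base
  for (k in 1:6)
    depths[k + 1, , ] <- depths[k, , ] + matrix(runif(nb * nc, 0.5, 20), nb, nc)
  boundary_set(depths)
}

# Flat interfaces at depths 10, 20, ..., 70 on a grid.
flat_boundary_set <- function(nb = 4, nc = 4) {
  boundary_set(array(rep(seq(10, 70, by = 10), times = nb * nc),
                     dim = c(7, nb, nc)))
}

# Long cohort table for one measure from per-group generator functions.
make_stats_table <- function(n = 20, weeks = c(0, 8),
                             gen = function(g, w, base) base + rnorm(n),
                             measure = "m", layer = "IPL") {
  ids <- sprintf("a%02d", seq_len(2 * n))
  groups <- rep(c("control", "T2D"), each = n)
  base <- rnorm(2 * n, 10, 1)
  rows <- lapply(weeks, function(w) {
    v <- if (w == 0) base else gen(groups, w, base)
    data.frame(animal_id = ids, group = groups, week = w, layer = layer,
               measure = measure, value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
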