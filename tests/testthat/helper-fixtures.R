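# small in-code fixture builders shared across test files

make_foci <- function(positions, cell = "c1", biv = "chr09",
                      channel = "bright") {
  n <- length(positions)
  data.frame(cell_id = rep(cell, n), bivalent_id = rep(biv, n),
             channel = rep(channel, n), position_frac = positions,
             stringsAsFactors = FALSE)
}

make_cell_records <- function(shapes, cell = "c1") {
  data.frame(cell_id = rep(cell, length(shapes)), shape_class = shapes,
             stringsAsFactors = FALSE)
}

# rescale a sample to exact target mean and SD (for summary-stat oracles)
with_moments <- function(x, mean_target, sd_target) {
  (x - mean(x)) / sd(x) * sd_target + mean_target
}

# closed-form mean and variance of the capped per-cell chiasma score for a
# class-II-only genotype: per bivalent, score = min(Poisson(rate * L), 2)
capped_poisson_moments <- function(rate, sc_lengths) {
  lam <- rate * sc_lengths
  p0 <- exp(-lam); p1 <- lam * exp(-lam); p2 <- 1 - p0 - p1
  m <- p1 + 2 * p2
  v <- (p1 + 4 * p2) - m^2
  list(mean = sum(m), var = sum(v))
}
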