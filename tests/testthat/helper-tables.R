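# case-control example table used throughout: chi2 = 0.01020304
table2_counts <- function() matrix(c(25, 20, 30, 25), 2, 2)

table2 <- function() contingency_table(table2_counts())

# random table with positive margins, for property-style loops
random_table <- function(max_dim = 4L, max_cell = 30L) {
  repeat {
    I <- sample(2:max_dim, 1L)
    J <- sample(2:max_dim, 1L)
    counts <- matrix(sample(0:max_cell, I * J, replace = TRUE), I, J)
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) {
      return(contingency_table(counts))
    }
  }
}

# Laplace CDF, for goodness-of-fit checks of the sampler
plaplace <- function(q, scale) {
  ifelse(q < 0, 0.5 * exp(q / scale), 1 - 0.5 * exp(-q / scale))
}
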