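# Shared fixtures for the test suite. All webs are generated in code.

# Random simple digraph (may contain mutual links and be trophic-invalid):
# exercises the full 13-class census, unlike the DAG generator.
random_digraph <- function(n, p = 0.25) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  diag(m) <- FALSE
  idx <- which(m, arr.ind = TRUE)
  labels <- sprintf("r%02d", seq_len(n))
  food_web(cbind(labels[idx[, 1]], labels[idx[, 2]]), nodes = labels)
}

expect_web_equal <- function(a, b) {
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
}

# Write an edge list for ad-hoc parser tests.
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
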