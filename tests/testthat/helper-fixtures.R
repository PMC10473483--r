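# Shared fixtures: grids shaped like the two study designs and a default
# three-viewpoint synthetic dataset.

# 19 statements, 7 columns, anchors -3..+3, max 5 per column
grid19 <- function() gridSpec(-3:3, c(1, 2, 4, 5, 4, 2, 1))

# 42 statements, 11 columns, anchors -5..+5, max 8 per column
grid42 <- function() gridSpec(-5:5, c(1, 2, 3, 5, 6, 8, 6, 5, 3, 2, 1))

synth3 <- function(seed = 11, noiseSd = 0.5) {
  generateSynthetic(S = 42, kTrue = 3, groupSizes = c(11, 11, 11),
                    noiseSd = noiseSd, grid = grid42(), seed = seed)
}

# independent direct evaluation of the orthomax objective (kept separate
# from the package's own implementation on purpose)
refOrthomax <- function(L, gamma) {
  P <- nrow(L)
  acc <- 0
  for (j in seq_len(ncol(L))) {
    acc <- acc + sum(L[, j]^4) - (gamma / P) * sum(L[, j]^2)^2
  }
  acc
}
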