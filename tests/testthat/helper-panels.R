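# Small deterministic panels built in code for the I/O and stability tests.

make_panel_df <- function() {
  tibble::tibble(
    dataset_id = "demo",
    source = rep(c("observed", "predicted"), each = 6),
    treatment_id = rep(rep(c("A", "B", "C"), each = 2), 2),
    environment_id = rep(c("2015", "2016"), 6),
    replicate = "r1",
    grain_yield = c(2, 4, 3, 5, 4, 6, 2.1, 3.9, 3.2, 4.8, 4.1, 5.9)
  )
}

# complete treatment x environment matrix with known F-W structure
make_fw_matrix <- function(slopes, intercepts, omega) {
  mat <- outer(slopes, omega) + intercepts
  dimnames(mat) <- list(sprintf("T%02d", seq_along(slopes)),
                        sprintf("E%02d", seq_along(omega)))
  mat
}

# population-moment CCC by brute-force loops (independent oracle)
ccc_bruteforce <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Willmott index by an explicit elementwise loop (independent oracle)
wi_bruteforce <- function(o, e) {
  ob <- mean(o)
  num <- 0; den <- 0
  for (i in seq_along(o)) {
    num <- num + (e[i] - o[i])^2
    den <- den + (abs(e[i] - ob) + abs(o[i] - ob))^2
  }
  1 - num / den
}
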