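# Brute-force re-implementations of the spatial-adjustment quantities,
# written as plain loops over the plot table so they share no code with the
# package internals.

oracle_method1 <- function(table) {
  c1 <- table[table$role == "check1", ]
  mu <- mean(c1$value)
  adj <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    in_row <- c1$value[c1$block_row == table$block_row[i]]
    in_col <- c1$value[c1$block_col == table$block_col[i]]
    r <- if (length(in_row) > 0) mean(in_row) else mu
    c <- if (length(in_col) > 0) mean(in_col) else mu
    adj[i] <- table$value[i] - r - c + 2 * mu
  }
  adj
}

oracle_method3 <- function(table, reference = "grand") {
  blocks <- sort(unique(table$block))
  c1 <- c2 <- rep(NA_real_, length(blocks))
  for (b in seq_along(blocks)) {
    rows <- table[table$block == blocks[b], ]
    c1[b] <- mean(rows$value[rows$role == "check1"])
    c2[b] <- mean(rows$value[startsWith(rows$role, "check2")])
  }
  beta <- sum((c2 - mean(c2)) * (c1 - mean(c1))) / sum((c2 - mean(c2))^2)
  alpha <- mean(c1) - beta * mean(c2)
  adj <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    b <- match(table$block[i], blocks)
    ref <- if (reference == "grand") mean(c2) else c2[b]
    adj[i] <- table$value[i] - beta * (c1[b] - ref) + alpha
  }
  list(beta = beta, alpha = alpha, adjusted = adj)
}

oracle_iwp <- function(table, col = "value") {
  roles <- sort(unique(table$role[startsWith(table$role, "check2")]))
  ss_total <- 0
  n_total <- 0
  for (r in roles) {
    rows <- table[table$role == r, ]
    x <- tapply(rows[[col]], rows$block, mean)
    ss_total <- ss_total + sum((x - mean(x))^2)
    n_total <- n_total + length(x)
  }
  ss_total / (length(roles) * (n_total - length(roles)))
}

# A small random MAD trial on a complete block grid.
random_small_trial <- function(seed, n_blocks = 6, field_cols = 3,
                               block_shape = c(3, 3),
                               gradient_sd = 1, noise_sd = 0.5) {
  lay <- generate_layout(n_blocks, block_shape = block_shape,
                         field_cols = field_cols, seed = seed)
  truth <- random_trial_truth(lay, grand_mean = 10, genotype_sd = 1,
                              gradient_sd = gradient_sd, noise_sd = noise_sd,
                              seed = seed + 1000)
  simulate_trial(lay, truth, seed = seed + 2000)
}

# Fabricate a canopy_fit directly from a dense curve, bypassing the model
# fitting, to test the extraction operators in isolation.
fake_fit <- function(day, fitted) {
  structure(
    list(model = "fake", grid = tibble::tibble(day = day, fitted = fitted),
         converged = TRUE),
    class = "canopy_fit"
  )
}
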