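# Shared fixtures and independent oracles used across test files.

tiny_ct <- function(values = c(20, 22, 24, 21, 23, 25),
                    features = c("mmu-miR-1", "mmu-miR-2", "mmu-miR-3"),
                    samples = c("s1", "s2"), ...) {
  m <- matrix(values, nrow = length(features),
              dimnames = list(features, samples))
  ct_matrix(m, ...)
}

tiny_sheet <- function() {
  sample_sheet(
    sample_id = sprintf("%s_%d", rep(c("wt.vehicle", "wt.KA",
                                       "ko.vehicle", "ko.KA"), each = 3),
                        1:3),
    genotype = rep(c("wt", "wt", "ko", "ko"), each = 3),
    treatment = rep(c("vehicle", "KA", "vehicle", "KA"), each = 3))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate all C(N, n) draws from a universe with K marked elements and
# count draws with >= k marked.
hyper_tail_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(marked >= k)
}

# Textbook BH step-up oracle: adj_(i) = min over j >= i of p_(j) * m / j,
# capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force per-element Venn cell classifier.
venn_oracle <- function(A_up, A_down, B_up, B_down) {
  all <- unique(c(A_up, A_down, B_up, B_down))
  cell_of <- vapply(all, function(f) {
    a <- if (f %in% A_up) "up" else if (f %in% A_down) "down" else "none"
    b <- if (f %in% B_up) "up" else if (f %in% B_down) "down" else "none"
    switch(paste(a, b),
           "up up" = "common_up", "down down" = "common_down",
           "up none" = "unique_A_up", "down none" = "unique_A_down",
           "none up" = "unique_B_up", "none down" = "unique_B_down",
           "up down" = "discordant_A_up_B_down",
           "down up" = "discordant_A_down_B_up")
  }, character(1))
  split(all, factor(cell_of, levels = c(
    "common_up", "unique_A_up", "unique_B_up", "common_down",
    "unique_A_down", "unique_B_down", "discordant_A_up_B_down",
    "discordant_A_down_B_up")))
}

sort_chr <- function(x) sort(as.character(x))
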