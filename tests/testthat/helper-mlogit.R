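# Known-truth 3-class multinomial-logit simulator used by the association
# and acceptance suites for parameter-recovery checks.
simulate_mlogit_truth <- function(n, seed) {
  set.seed(seed)
  X <- cbind(b1 = rbinom(n, 1, 0.3), b2 = rbinom(n, 1, 0.5),
             b3 = rbinom(n, 1, 0.2), c1 = rnorm(n), c2 = rnorm(n),
             c3 = rnorm(n))
  B <- list(B = c(0.8, -0.5, 0.4, 0.3, -0.6, 0.2),
            C = c(-0.4, 0.6, 1.0, -0.3, 0.2, 0.5))
  a <- c(B = -0.5, C = -1.0)
  eta <- cbind(0, a["B"] + X %*% B$B, a["C"] + X %*% B$C)
  pr <- exp(eta) / rowSums(exp(eta))
  u <- runif(n)
  cls <- c("A", "B", "C")[1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])]
  ft <- data.table::data.table(member_id = as.character(seq_len(n)),
                               outcome = factor(cls, levels = c("A", "B", "C")),
                               X)
  data.table::setattr(ft, "continuous", c("c1", "c2", "c3"))
  data.table::setattr(ft, "reference", "A")
  list(features = ft, truth = B)
}
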