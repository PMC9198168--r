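`%||%` <- function(a, b) if (is.null(a)) b else a

# Split ";"-delimited token strings into a list of character vectors.
split_tokens <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  out[!nzchar(x)] <- list(character(0))
  out
}

# TRUE where the token string contains at least one of `tokens`.
has_any_token <- function(x, tokens) {
  pat <- paste0("(^|;)(", paste(tokens, collapse = "|"), ")(;|$)")
  grepl(pat, x)
}

# Number of tokens in each ";"-delimited string ("" counts as zero).
count_tokens <- function(x) {
  n <- nchar(x)
  k <- n - nchar(gsub(";", "", x, fixed = TRUE))
  ifelse(n == 0L, 0L, k + 1L)
}

# Collapse a logical membership matrix (rows = records, columns = named
# categories) into ";"-delimited token strings, preserving column order.
tokens_from_matrix <- function(mat, names) {
  out <- character(nrow(mat))
  idx <- which(mat, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  dt <- data.table(row = idx[, 1L], col = idx[, 2L])
  setorder(dt, row, col)
  agg <- dt[, .(s = paste(names[col], collapse = ";")), by = row]
  out[agg$row] <- agg$s
  out
}

# Draw one categorical label per row given an n x K matrix of probabilities.
sample_categorical <- function(prob, labels) {
  K <- ncol(prob)
  cp <- prob
  for (k in seq_len(K)[-1L]) cp[, k] <- cp[, k - 1L] + cp[, k]
  u <- runif(nrow(prob)) * cp[, K]  # tolerate rows summing to != 1 exactly
  idx <- rowSums(u > cp) + 1L
  labels[pmin(idx, K)]
}

# Canonical ";"-joined month strings "1;...;m" for m = 1..12.
month_prefix_strings <- function() {
  vapply(1:12, function(m) paste(seq_len(m), collapse = ";"), character(1))
}
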