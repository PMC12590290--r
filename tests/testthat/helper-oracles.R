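# shared oracles and fixture builders, all built in code at test time

# exhaustive assignment minimum over all permutations (independent of the
# LSAP solver); rows = queries, cols = targets, nt <= nq
brute_force_assignment <- function(cost) {
  nq <- nrow(cost); nt <- ncol(cost)
  stopifnot(nt <= nq)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- Inf; best_q <- NULL
  for (p in perms(seq_len(nq))) {
    sel <- p[seq_len(nt)]
    total <- sum(cost[cbind(sel, seq_len(nt))])
    if (total < best) { best <- total; best_q <- sel }
  }
  list(total = best, pairs = cbind(query = best_q, target = seq_len(nt)))
}

# minimal STAR loop parser, independent of the package reader
parse_star_independently <- function(path) {
  lines <- readLines(path)
  labels <- grep("^_rln", lines, value = TRUE)
  labels <- sub("^_([A-Za-z]+).*", "\\1", labels)
  data_lines <- lines[!grepl("^(_|data_|loop_)", lines) & nzchar(trimws(lines))]
  rows <- strsplit(trimws(data_lines), "[[:space:]]+")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(df)) names(df) <- labels
  df
}

# independent binary cross-entropy (for the focal-loss reduction check)
binary_cross_entropy <- function(p, fg) {
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  sum(ifelse(fg, -log(p), -log(1 - p)))
}

# central finite difference of f at x
numeric_gradient <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# random valid normalized boxes
random_norm_boxes <- function(n) {
  cbind(cx = runif(n, 0.2, 0.8), cy = runif(n, 0.2, 0.8),
        w = runif(n, 0.05, 0.3), h = runif(n, 0.05, 0.3))
}

# a very small detector used where training speed matters
micro_model_config <- function(...) {
  tiny_config(hidden_dim = 32L, n_heads = 2L, n_encoder_layers = 1L,
              n_decoder_layers = 1L, groups = 2L, queries_per_group = 5L,
              ffn_dim = 64L, ...)
}
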