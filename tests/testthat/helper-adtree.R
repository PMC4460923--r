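# Exhaustive-search oracle for confidence-rated ADTree boosting: scores
# every (precondition node, attribute, midpoint threshold) candidate by
# direct weight sums, with no sorting or incremental tricks, and grows
# the tree iteration by iteration. Tie-breaks mirror the documented
# contract: lowest precondition node id, alphabetically first
# attribute, smallest threshold (strict improvement scan).

oracle_train_adtree <- function(X, y, n_iterations, epsilon = 1) {
  feats <- sort(colnames(X), method = "radix")
  n <- nrow(X)
  w <- rep(1, n)
  root <- 0.5 * log(sum(w[y > 0]) / sum(w[y < 0]))
  w <- w * exp(-y * root)
  total_weight <- sum(w)

  reach <- list(rep(TRUE, n))     # prediction node 0
  rules <- list()

  for (it in seq_len(n_iterations)) {
    best <- NULL
    for (node_id in seq_along(reach) - 1L) {
      inc <- reach[[node_id + 1L]]
      if (sum(inc) < 2) next
      w_notc <- sum(w[!inc])
      for (f in feats) {
        vals <- sort(unique(X[inc, f]))
        if (length(vals) < 2) next
        mids <- (utils::head(vals, -1) + utils::tail(vals, -1)) / 2
        for (thr in mids) {
          r <- X[, f] >= thr
          wp_t <- sum(w[inc & r & y > 0])
          wn_t <- sum(w[inc & r & y < 0])
          wp_f <- sum(w[inc & !r & y > 0])
          wn_f <- sum(w[inc & !r & y < 0])
          z <- 2 * (sqrt(wp_t * wn_t) + sqrt(wp_f * wn_f)) + w_notc
          if (is.null(best) || z < best$z) {
            best <- list(z = z, node = node_id, attribute = f,
                         threshold = thr,
                         a_true = 0.5 * log((wp_t + epsilon) /
                                              (wn_t + epsilon)),
                         a_false = 0.5 * log((wp_f + epsilon) /
                                               (wn_f + epsilon)))
          }
        }
      }
    }
    if (is.null(best)) break
    inc <- reach[[best$node + 1L]]
    r <- X[, best$attribute] >= best$threshold
    contrib <- ifelse(r, best$a_true, best$a_false)
    w[inc] <- w[inc] * exp(-y[inc] * contrib[inc])
    reach[[length(reach) + 1L]] <- inc & r
    reach[[length(reach) + 1L]] <- inc & !r
    rules[[it]] <- best
    total_weight <- c(total_weight, sum(w))
  }
  list(root_value = root, rules = rules, total_weight = total_weight)
}

# independent scorer: walks every root-to-node path recursively instead
# of tracking reach sets
oracle_score_one <- function(model, x) {
  reaches <- function(node) {
    if (node == 0) return(TRUE)
    j <- (node + 1) %/% 2
    r <- model$rules[j, ]
    takes_true <- x[[r$attribute]] >= r$threshold
    ok <- if (node %% 2 == 1) takes_true else !takes_true
    ok && reaches(r$precondition)
  }
  s <- model$root_value
  for (j in seq_len(nrow(model$rules))) {
    r <- model$rules[j, ]
    if (reaches(r$precondition)) {
      s <- s + if (x[[r$attribute]] >= r$threshold) r$a_true else r$a_false
    }
  }
  s
}

# small labeled data frame usable by train_adtree
toy_dataset <- function(n_pos, n_neg, p = 1, seed = 1, shift = 1.5) {
  set.seed(seed)
  n <- n_pos + n_neg
  d <- data.frame(protein = sprintf("T%03d", seq_len(n)))
  for (j in seq_len(p)) {
    d[[paste0("f", j)]] <- c(rnorm(n_pos, shift * (j == 1)), rnorm(n_neg))
  }
  d$label <- rep(c("positive", "negative"), c(n_pos, n_neg))
  d
}
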