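#' Train an alternating decision tree
#'
#' Confidence-rated boosting of an alternating decision tree (ADTree).
#' The model is a root prediction value plus an ordered list of decision
#' rules; an instance's confidence score is the sum of the root value
#' and the prediction values of every branch it reaches, and it is
#' classified positive exactly when that additive score exceeds 0.
#'
#' Training starts from unit instance weights. The root value is
#' `0.5 * log(W+ / W-)`, the log class-weight ratio (the class bias of
#' the data), after which weights are multiplied by `exp(-y * root)`.
#' Each boosting iteration exhaustively scores every combination of an
#' existing prediction node (precondition `c`), an attribute and a
#' candidate threshold (midpoints between consecutive distinct attribute
#' values among the instances satisfying `c`; the decision is
#' "attribute >= threshold goes to the true branch") with the criterion
#' \deqn{Z = 2(\sqrt{W_+(c \wedge r) W_-(c \wedge r)} +
#'            \sqrt{W_+(c \wedge \neg r) W_-(c \wedge \neg r)}) +
#'            W(\neg c)}
#' and adds the minimizer. Branch prediction values are
#' `0.5 * log((W+ + eps) / (W- + eps))` on the matching instances, and
#' weights update as `w <- w * exp(-y * value reached)`. Z-minimization
#' contracts the total weight, so the total instance weight is
#' non-increasing across iterations. Ties in `Z` are broken toward the
#' lowest precondition node id, then the alphabetically first attribute,
#' then the smallest threshold, so builds are deterministic.
#'
#' @param dataset A `labeled_dataset` (rows labeled `excluded` are
#'   ignored) with both classes present.
#' @param n_iterations Number of boosting iterations (decision rules);
#'   20 by default. 0 gives a root-only model.
#' @param epsilon Smoothing constant added to the class weights inside
#'   branch prediction values; default 1.
#' @param seed Optional integer recorded in the model metadata; training
#'   itself is deterministic.
#' @param features Feature columns to train on (default the canonical
#'   ten present in the dataset).
#' @return An object of class `adtree`: list with `root_value`, `rules`
#'   (data frame: `index`, `precondition`, `attribute`, `threshold`,
#'   `a_true`, `a_false`), `n_iterations`, `epsilon`, `features`,
#'   `total_weight` (trajectory after the root and after each
#'   iteration) and `seed`. Prediction node ids: 0 is the root and rule
#'   `j` creates nodes `2j - 1` (true branch) and `2j` (false branch);
#'   `precondition` refers to these ids.
#' @export
train_adtree <- function(dataset, n_iterations = 20, epsilon = 1,
                         seed = NULL, features = NULL) {
  stopifnot(n_iterations >= 0, epsilon >= 0)
  rows <- training_rows(dataset)
  if (is.null(features)) {
    features <- intersect(adnet_features(), names(rows))
    if (length(features) == 0) {
      # not a canonical feature table: train on every numeric column
      # that is not bookkeeping
      reserved <- c("protein", "label", "n_diseases", "y", "fold",
                    "score")
      numeric_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
      features <- setdiff(numeric_cols, reserved)
    }
  }
  stopifnot(length(features) >= 1)
  features_scan <- sort(features, method = "radix")
  if (length(unique(rows$y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }

  X <- as.matrix(rows[, features_scan, drop = FALSE])
  y <- rows$y
  ypos <- y > 0
  n <- nrow(X)
  w <- rep(1, n)

  root <- 0.5 * log(sum(w[ypos]) / sum(w[!ypos]))
  w <- w * exp(-y * root)
  total_weight <- sum(w)

  reach <- matrix(TRUE, n, 1)  # column k holds prediction node k - 1
  rules <- vector("list", n_iterations)
  n_rules <- 0L

  for (t in seq_len(n_iterations)) {
    tot_w <- sum(w)
    best <- NULL
    for (node in seq_len(ncol(reach)) - 1L) {
      idx <- which(reach[, node + 1L])
      if (length(idx) < 2) next
      w_notc <- tot_w - sum(w[idx])
      for (f in features_scan) {
        res <- .cpp_best_cut(X[idx, f], w[idx], ypos[idx])
        if (!res$ok) next
        z <- res$z_split + w_notc
        if (is.null(best) || z < best$z) {
          best <- list(z = z, node = node, attribute = f,
                       threshold = res$threshold,
                       wp_true = res$wp_true, wn_true = res$wn_true,
                       wp_false = res$wp_false, wn_false = res$wn_false)
        }
      }
    }
    if (is.null(best)) {
      warning("no further split available; stopping after ",
              n_rules, " rules")
      break
    }
    a_true <- 0.5 * log((best$wp_true + epsilon) / (best$wn_true + epsilon))
    a_false <- 0.5 * log((best$wp_false + epsilon) / (best$wn_false + epsilon))

    cond <- X[, best$attribute] >= best$threshold
    in_node <- reach[, best$node + 1L]
    contrib <- ifelse(cond, a_true, a_false)
    upd <- which(in_node)
    w[upd] <- w[upd] * exp(-y[upd] * contrib[upd])

    reach <- cbind(reach, in_node & cond, in_node & !cond)
    n_rules <- n_rules + 1L
    rules[[n_rules]] <- data.frame(
      index = n_rules, precondition = best$node,
      attribute = best$attribute, threshold = best$threshold,
      a_true = a_true, a_false = a_false, stringsAsFactors = FALSE)
    total_weight <- c(total_weight, sum(w))
  }

  rules <- if (n_rules > 0) do.call(rbind, rules[seq_len(n_rules)]) else
    data.frame(index = integer(0), precondition = integer(0),
               attribute = character(0), threshold = numeric(0),
               a_true = numeric(0), a_false = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(root_value = root, rules = rules,
                 n_iterations = n_iterations, epsilon = epsilon,
                 features = features_scan, total_weight = total_weight,
                 seed = seed),
            class = "adtree")
}

#' @exportS3Method base::print
print.adtree <- function(x, ...) {
  cat("adtree: root ", signif(x$root_value, 4), ", ",
      nrow(x$rules), " rules over ", length(x$features),
      " features\n", sep = "")
  if (nrow(x$rules) > 0) {
    hdr <- utils::head(x$rules, 5)
    cat(paste0("  (", hdr$index, ") ", hdr$attribute, " >= ",
               signif(hdr$threshold, 4), " @node ", hdr$precondition,
               ": ", sprintf("%+.3g", hdr$a_true), " / ",
               sprintf("%+.3g", hdr$a_false), collapse = "\n"), "\n")
    if (nrow(x$rules) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Additive confidence scores from an ADTree
#'
#' Evaluates the tree on new instances: each instance accumulates the
#' root value plus the prediction value of every branch whose
#' precondition path it satisfies (the attribute comparison is
#' inclusive: `value >= threshold` follows the true branch). The sign
#' of the score is the predicted class (positive iff score > 0) and
#' its magnitude the confidence.
#'
#' @param model An `adtree`.
#' @param newdata Data frame containing every feature column the model
#'   uses; a missing column is an error naming the attribute.
#' @return Numeric vector of confidence scores, one per row.
#' @export
adtree_score <- function(model, newdata) {
  miss <- setdiff(unique(c(model$features, model$rules$attribute)),
                  names(newdata))
  if (length(miss) > 0) {
    stop("newdata is missing attribute(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(newdata)
  score <- rep(model$root_value, n)
  n_rules <- nrow(model$rules)
  reach <- matrix(FALSE, n, 2 * n_rules + 1)
  reach[, 1] <- TRUE
  for (j in seq_len(n_rules)) {
    r <- model$rules[j, ]
    at_node <- reach[, r$precondition + 1L]
    cond <- newdata[[r$attribute]] >= r$threshold
    score <- score + ifelse(at_node, ifelse(cond, r$a_true, r$a_false), 0)
    reach[, 2L * j] <- at_node & cond        # node 2j - 1
    reach[, 2L * j + 1L] <- at_node & !cond  # node 2j
  }
  score
}

#' Predict classes or scores from an ADTree
#'
#' @param object An `adtree`.
#' @param newdata Data frame of instances.
#' @param type `"score"` for the additive confidence score, `"class"`
#'   for the `positive`/`negative` decision (positive iff score > 0).
#' @param ... Unused.
#' @return Numeric scores or a character vector of class labels.
#' @export
predict.adtree <- function(object, newdata, type = c("score", "class"),
                           ...) {
  type <- match.arg(type)
  s <- adtree_score(object, newdata)
  if (type == "score") s else ifelse(s > 0, "positive", "negative")
}

#' Serialize an ADTree to JSON
#'
#' @param model An `adtree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
serialize_adtree <- function(model, path = NULL) {
  doc <- list(format = "adnet/adtree", version = 1L,
              root_value = model$root_value,
              n_iterations = model$n_iterations,
              epsilon = model$epsilon,
              features = model$features,
              seed = model$seed,
              total_weight = model$total_weight,
              rules = model$rules)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Deserialize an ADTree from JSON
#'
#' Validates the schema: rules must be indexed 1..T in order and every
#' rule's precondition must reference the root (0) or a prediction node
#' created by an earlier rule; a dangling precondition is rejected.
#'
#' @param json JSON string, or path to a JSON file.
#' @return An `adtree`.
#' @export
deserialize_adtree <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json)
  if (is.null(doc$format) || doc$format != "adnet/adtree") {
    stop("not an adnet ADTree document", call. = FALSE)
  }
  rules <- as.data.frame(doc$rules)
  if (nrow(rules) == 0) {
    rules <- data.frame(index = integer(0), precondition = integer(0),
                        attribute = character(0), threshold = numeric(0),
                        a_true = numeric(0), a_false = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    needed <- c("index", "precondition", "attribute", "threshold",
                "a_true", "a_false")
    if (!all(needed %in% names(rules))) {
      stop("rule table lacks mandatory fields", call. = FALSE)
    }
    if (!identical(as.integer(rules$index), seq_len(nrow(rules)))) {
      stop("rule indices must be 1..n in discovery order", call. = FALSE)
    }
    if (any(!is.finite(rules$threshold))) {
      stop("rule thresholds must be finite", call. = FALSE)
    }
    bad <- rules$precondition < 0 |
      rules$precondition > 2L * (rules$index - 1L)
    if (any(bad)) {
      stop("dangling precondition in rule(s): ",
           paste(rules$index[bad], collapse = ", "), call. = FALSE)
    }
    rules$index <- as.integer(rules$index)
    rules$precondition <- as.integer(rules$precondition)
    rules$threshold <- as.numeric(rules$threshold)
    rules$a_true <- as.numeric(rules$a_true)
    rules$a_false <- as.numeric(rules$a_false)
  }
  structure(list(root_value = as.numeric(doc$root_value), rules = rules,
                 n_iterations = as.integer(doc$n_iterations),
                 epsilon = as.numeric(doc$epsilon),
                 features = doc$features,
                 total_weight = as.numeric(doc$total_weight),
                 seed = doc$seed),
            class = "adtree")
}
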