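# Relevance filtering: a linear classifier over masked citation text,
# trained by stochastic gradient descent on the modified Huber loss, with a
# confidence threshold applied when filtering mentions.

#' The packaged English stop-word list
#'
#' A fixed, versioned list shipped with the package so that featurization is
#' reproducible across installations.
#'
#' @return Character vector of lower-cased stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "pathomine",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Training configuration for the relevance filter
#'
#' The learning rate follows the inverse-scaling schedule
#' `eta_t = 1 / (lambda * (t + t0))` with `t0 = 1 / (lambda * eta0)`, i.e.
#' the first step uses `eta0` and the rate decays hyperbolically. All fields
#' are serialized with the model.
#'
#' @param epochs Passes over the shuffled training set.
#' @param lambda L2 regularization strength.
#' @param eta0 Initial learning rate.
#' @param seed Seed fixing the example shuffling (and hence the weights).
#' @param ngram_order 1 for unigrams, 2 for unigrams + bigrams.
#' @param threshold Default confidence threshold for filtering, in [0, 1].
#' @param stopwords Stop-word list; defaults to the packaged list.
#' @return A `pm_train_config` list.
#' @export
train_config <- function(epochs = 10L, lambda = 1e-4, eta0 = 0.1, seed = 42L,
                         ngram_order = 1L, threshold = 0.5,
                         stopwords = default_stopwords()) {
  stopifnot(epochs >= 1, lambda > 0, eta0 > 0, ngram_order %in% c(1L, 2L),
            threshold >= 0, threshold <= 1)
  structure(list(epochs = as.integer(epochs), lambda = lambda, eta0 = eta0,
                 seed = as.integer(seed), ngram_order = as.integer(ngram_order),
                 threshold = threshold, stopwords = stopwords,
                 stopword_list = "pathomine-en-1"),
            class = "pm_train_config")
}

#' Turn text into binary n-gram features
#'
#' Lower-cases, tokenizes (keeping the mask token `@PATHOGEN$` intact as one
#' token), removes stop words, and emits the set of distinct n-grams up to
#' `ngram_order` (bigram parts joined by a single space). Feature values are
#' binary presence indicators, not counts.
#'
#' @param text A string.
#' @param config A [train_config()].
#' @return Character vector of distinct feature strings (empty for empty
#'   text).
#' @export
featurize <- function(text, config) {
  stopifnot(inherits(config, "pm_train_config"))
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character())
  toks <- regmatches(tolower(text),
                     gregexpr("[a-z0-9@$-]+", tolower(text), perl = TRUE))[[1]]
  toks <- toks[!toks %in% config$stopwords]
  if (!length(toks)) return(character())
  feats <- toks
  if (config$ngram_order >= 2L && length(toks) >= 2L) {
    feats <- c(feats, paste(toks[-length(toks)], toks[-1]))
  }
  unique(feats)
}

#' Modified Huber loss
#'
#' For margin `m = y * score` (labels coded +1/-1): `max(0, 1 - m)^2` when
#' `m >= -1`, and `-4 m` otherwise. Quadratic near the decision boundary,
#' linear for badly misclassified points, which bounds the influence of the
#' majority class under imbalance; continuous (both branches give 4 at
#' `m = -1`), continuously differentiable, and convex.
#'
#' @param margin Numeric vector of margins.
#' @return Loss values.
#' @export
modified_huber_loss <- function(margin) {
  ifelse(margin >= -1, pmax(0, 1 - margin)^2, -4 * margin)
}

# derivative of the loss w.r.t. the raw score, times nothing else:
# dL/ds = y * dL/dm
modified_huber_dscore <- function(margin, y) {
  ifelse(margin >= 1, 0, ifelse(margin >= -1, -2 * (1 - margin) * y, -4 * y))
}

#' Train the relevance filter
#'
#' Linear model minimizing mean modified-Huber loss plus an L2 penalty by
#' stochastic gradient descent: examples are shuffled each epoch under the
#' configured seed, the learning rate decays as `1 / (lambda * (t + t0))`,
#' and the regularization shrink is applied via the usual weight-scale trick
#' so each step costs only the active features. Training is deterministic
#' given the configuration; the global RNG state is left untouched.
#'
#' @param examples Data frame with columns `text` and `label`
#'   (`relevant`/`irrelevant`), as from [build_training_set()]. Both labels
#'   must be present.
#' @param config A [train_config()].
#' @return A `pm_filter_model`: vocabulary, weights, bias, config, and the
#'   per-epoch mean training loss.
#' @export
train_filter <- function(examples, config = train_config()) {
  stopifnot(inherits(config, "pm_train_config"), nrow(examples) >= 2)
  y <- ifelse(examples$label == "relevant", 1, -1)
  for (cls in c("relevant", "irrelevant")) {
    if (!cls %in% examples$label) {
      stop("training set has no '", cls, "' examples", call. = FALSE)
    }
  }
  feats <- lapply(examples$text, featurize, config = config)
  vocab <- sort(unique(unlist(feats)))
  vmap <- new.env(parent = emptyenv())
  for (i in seq_along(vocab)) assign(vocab[i], i, envir = vmap)
  xidx <- lapply(feats, function(f) {
    vapply(f, function(g) get(g, envir = vmap), integer(1), USE.NAMES = FALSE)
  })

  w <- numeric(length(vocab))
  wscale <- 1
  b <- 0
  t0 <- 1 / (config$lambda * config$eta0)
  t <- 0L
  n <- nrow(examples)
  epoch_loss <- numeric(config$epochs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    for (i in ord) {
      t <- t + 1L
      eta <- 1 / (config$lambda * (t + t0))
      idx <- xidx[[i]]
      s <- wscale * sum(w[idx]) + b
      m <- y[i] * s
      losses[i] <- modified_huber_loss(m)
      # L2 shrink on the weights (not the bias)
      wscale <- wscale * (1 - eta * config$lambda)
      g <- modified_huber_dscore(m, y[i])
      if (g != 0 && length(idx)) w[idx] <- w[idx] - eta * g / wscale
      if (g != 0) b <- b - eta * g
      if (wscale < 1e-9) {  # renormalize to keep the trick stable
        w <- w * wscale
        wscale <- 1
      }
    }
    epoch_loss[ep] <- mean(losses)
  }
  structure(
    list(vocab = vocab, weights = w * wscale, bias = b, config = config,
         epoch_loss = epoch_loss),
    class = "pm_filter_model"
  )
}

#' @export
print.pm_filter_model <- function(x, ...) {
  cat(sprintf("<pm_filter_model> %d features, ngram order %d, final epoch loss %.4f\n",
              length(x$vocab), x$config$ngram_order,
              x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

raw_score <- function(model, text) {
  feats <- featurize(text, model$config)
  idx <- match(feats, model$vocab)
  idx <- idx[!is.na(idx)]  # out-of-vocabulary n-grams are ignored
  sum(model$weights[idx]) + model$bias
}

#' Predict relevance for a text
#'
#' Confidence maps the raw linear score to [0, 1] by the clipped link
#' `(1 + min(1, max(-1, score))) / 2` (the standard probability map for
#' modified-Huber scores); a raw score of 0 gives confidence 0.5. The label
#' is `relevant` iff confidence is at or above the threshold.
#'
#' @param model A `pm_filter_model`.
#' @param text A string (typically masked citation text).
#' @param threshold Confidence threshold; defaults to the trained config's.
#' @return List with `label` and `confidence`.
#' @export
predict_filter <- function(model, text, threshold = model$config$threshold) {
  stopifnot(inherits(model, "pm_filter_model"))
  s <- raw_score(model, text)
  conf <- (1 + pmin(1, pmax(-1, s))) / 2
  list(label = if (conf >= threshold) "relevant" else "irrelevant",
       confidence = conf)
}

#' Filter mentions by predicted relevance
#'
#' For each (citation, pathogen) pair in the mentions, masks the pair's
#' mentions, predicts relevance, and drops all of that pathogen's mentions in
#' that citation when the pair is predicted irrelevant. Raising the threshold
#' never increases the number of retained mentions.
#'
#' @param mentions Mention data frame over `x`.
#' @param model A `pm_filter_model`.
#' @param x The `pm_corpus` the mentions were found in.
#' @param threshold Confidence threshold; defaults to the trained config's.
#' @return The retained subset of `mentions`.
#' @export
filter_mentions <- function(mentions, model, x, threshold = model$config$threshold) {
  stopifnot(inherits(model, "pm_filter_model"), inherits(x, "pm_corpus"))
  if (!nrow(mentions)) return(mentions)
  unknown <- setdiff(unique(mentions$pmid), names(x$citations))
  if (length(unknown)) {
    stop("mentions reference unknown PMIDs: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(mentions$pmid, mentions$pathogen_id)
  keep <- logical(nrow(mentions))
  for (k in unique(key)) {
    rows <- key == k
    cit <- get_citation(x, mentions$pmid[rows][1])
    masked <- mask_citation(cit, mentions[rows, , drop = FALSE])
    pred <- predict_filter(model, masked, threshold = threshold)
    keep[rows] <- pred$label == "relevant"
  }
  mentions[keep, , drop = FALSE]
}

#' Save and load a filter model as JSON
#'
#' Serializes vocabulary, weights, bias and the full training configuration;
#' the reloaded model reproduces the original's predictions.
#'
#' @param model A `pm_filter_model`.
#' @param path File path.
#' @export
write_filter_model <- function(model, path) {
  stopifnot(inherits(model, "pm_filter_model"))
  payload <- list(vocab = model$vocab, weights = model$weights, bias = model$bias,
                  config = unclass(model$config), epoch_loss = model$epoch_loss)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- train_config(epochs = cfg$epochs, lambda = cfg$lambda, eta0 = cfg$eta0,
                         seed = cfg$seed, ngram_order = cfg$ngram_order,
                         threshold = cfg$threshold, stopwords = cfg$stopwords)
  structure(list(vocab = payload$vocab, weights = payload$weights,
                 bias = payload$bias, config = config,
                 epoch_loss = payload$epoch_loss),
            class = "pm_filter_model")
}
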