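#' Tokenize plain text for n-gram counting
#'
#' Whitespace tokenization with punctuation stripped; lowercasing is
#' configurable. Returns one character vector per sentence (sentences split
#' on `.`, `!`, `?`).
#'
#' @param text character vector of raw text.
#' @param lowercase logical.
#' @return list of character vectors (sentences of tokens).
#' @export
tokenize_corpus <- function(text, lowercase = TRUE) {
  text <- paste(text, collapse = " ")
  if (lowercase) text <- tolower(text)
  sents <- strsplit(text, "[.!?]+")[[1]]
  out <- lapply(sents, function(s) {
    s <- gsub("[^[:alnum:]'[:space:]-]", " ", s)
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    toks[nzchar(toks)]
  })
  out[vapply(out, length, integer(1)) > 0]
}

BOS <- "<s>"
UNK <- "<unk>"

#' Count n-grams of order 1..max_order
#'
#' Builds the count tables behind the surprisal predictors. Sentence starts
#' are padded with `<s>` context tokens for orders above 1; unigram counts
#' cover real tokens only, so the unigram total equals the corpus token
#' count. Deterministic.
#'
#' @param tokens a character vector (treated as one sentence) or a list of
#'   character vectors (one per sentence), e.g. from [tokenize_corpus()].
#' @param max_order integer in 1..3.
#' @return object of class `corpus_counts`: per-order named count vectors
#'   (n-gram tokens joined by single spaces), per-context totals and
#'   distinct-continuation counts for orders > 1, the total token count,
#'   and the vocabulary (with the reserved unknown symbol `<unk>`).
#' @examples
#' cc <- count_ngrams(c("a", "a", "b"), max_order = 1)
#' unigram_surprisal(cc, "a")   # -log(2/3)
#' @export
count_ngrams <- function(tokens, max_order = 1L) {
  if (!is.list(tokens)) tokens <- list(tokens)
  tokens <- lapply(tokens, as.character)
  if (!length(tokens) || !sum(lengths(tokens)))
    stop("empty corpus")
  if (max_order < 1L || max_order > 3L)
    stop("max_order must be 1, 2, or 3")
  if (any(unlist(tokens) %in% c(BOS, UNK)))
    stop("corpus contains reserved symbols <s>/<unk>")

  orders <- vector("list", max_order)
  names(orders) <- as.character(seq_len(max_order))
  for (k in seq_len(max_order)) {
    grams <- unlist(lapply(tokens, function(s) {
      padded <- c(rep(BOS, k - 1L), s)
      n <- length(padded)
      if (n < k) return(character(0))
      starts <- seq_len(n - k + 1L)
      vapply(starts, function(i)
        paste(padded[i:(i + k - 1L)], collapse = " "), character(1))
    }))
    tab <- table(grams)
    orders[[k]] <- stats::setNames(as.numeric(tab), names(tab))
  }

  ctx_totals <- ctx_types <- vector("list", max_order)
  for (k in seq_len(max_order)) {
    if (k == 1L) next
    keys <- names(orders[[k]])
    ctx <- sub(" [^ ]+$", "", keys)
    ctx_totals[[k]] <- tapply(orders[[k]], ctx, sum)
    ctx_types[[k]] <- tapply(orders[[k]], ctx, length)
  }

  out <- list(orders = orders,
              context_totals = ctx_totals,
              context_types = ctx_types,
              total = sum(orders[[1]]),
              vocab = names(orders[[1]]),
              unk = UNK,
              max_order = max_order)
  class(out) <- "corpus_counts"
  out
}

#' @export
print.corpus_counts <- function(x, ...) {
  cat(sprintf("n-gram counts: %d tokens, %d types, orders 1..%d\n",
              x$total, length(x$vocab), x$max_order))
  invisible(x)
}

# Base (unigram) probability used by the smoothed conditionals: proper over
# vocabulary plus <unk>, with one unit of mass reserved for <unk>.
base_unigram_prob <- function(counts, words) {
  c1 <- counts$orders[["1"]]
  p <- unname(c1[words]) / (counts$total + 1)
  p[is.na(p)] <- 1 / (counts$total + 1)
  p
}

#' Unigram surprisal (negative log prior probability)
#'
#' `-log p(word)` in nats under the maximum-likelihood unigram distribution;
#' equals the negated log relative frequency, i.e. the standard frequency
#' predictor up to an additive constant. Words outside the vocabulary map to
#' the reserved unknown symbol, which receives one extra unit of probability
#' mass (`1/(N+1)`), so out-of-vocabulary queries stay finite and rank below
#' every seen word.
#'
#' @param counts a [count_ngrams()] object.
#' @param words character vector of query words.
#' @return numeric vector of surprisals (nats, >= 0).
#' @export
unigram_surprisal <- function(counts, words) {
  stopifnot(inherits(counts, "corpus_counts"))
  c1 <- counts$orders[["1"]]
  p <- unname(c1[words]) / counts$total
  p[is.na(p)] <- 1 / (counts$total + 1)
  -log(p)
}

#' Smoothed bigram/trigram surprisal
#'
#' `-log P(word | context)` in nats under interpolated absolute discounting
#' with a fixed discount: the highest order uses raw counts discounted by
#' `D`, and the held-out mass `D * N1plus(context) / c(context)` is spread
#' over the lower-order distribution, recursing down to the count-based
#' unigram base (with `<unk>` mass `1/(N+1)`). An unseen context backs off
#' entirely to the lower-order estimate, so the conditional reduces toward
#' the unigram estimate as context counts vanish. Conditional probabilities
#' over the vocabulary plus `<unk>` sum to exactly 1 for any context.
#'
#' @param counts a [count_ngrams()] object built to at least `order`.
#' @param context character vector of context tokens (length `order - 1`);
#'   the last element is the most recent word.
#' @param words character vector of query words.
#' @param order 2 or 3.
#' @param discount absolute discount `D` in (0, 1); default 0.75.
#' @return numeric vector of surprisals (nats, >= 0).
#' @export
ngram_surprisal <- function(counts, context, words, order = 2L,
                            discount = 0.75) {
  stopifnot(inherits(counts, "corpus_counts"))
  if (!order %in% c(2L, 3L)) stop("order must be 2 or 3")
  if (counts$max_order < order)
    stop("counts were not built to order ", order)
  if (length(context) < order - 1L)
    stop("context must supply at least order - 1 tokens")
  context <- utils::tail(as.character(context), order - 1L)
  context[!context %in% c(counts$vocab, BOS)] <- counts$unk
  unname(-log(cond_prob(counts, context, words, order, discount)))
}

cond_prob <- function(counts, context, words, order, discount) {
  if (order == 1L) return(base_unigram_prob(counts, words))
  k <- as.character(order)
  ctx_key <- paste(context, collapse = " ")
  c_ctx <- counts$context_totals[[order]][ctx_key]
  lower <- cond_prob(counts, context[-1L], words, order - 1L, discount)
  if (is.na(c_ctx)) return(lower)
  keys <- paste(ctx_key, words)
  c_full <- counts$orders[[k]][keys]
  c_full[is.na(c_full)] <- 0
  n1p <- counts$context_types[[order]][ctx_key]
  pmax(c_full - discount, 0) / c_ctx + discount * n1p / c_ctx * lower
}

#' Word surprisal from precomputed subtoken log-probabilities
#'
#' Language models that operate on subtokens assign each word one or more
#' log-probabilities; the chain rule recovers the word-level surprisal as
#' the sum of subtoken surprisals. The package consumes these values from a
#' file (it never runs a language model itself).
#'
#' @param logprobs numeric vector of subtoken log-probabilities for one
#'   word, each finite and `<= 0`.
#' @return the word surprisal (nats, >= 0).
#' @examples
#' word_surprisal_from_subtokens(c(-2.0, -1.5))  # 3.5
#' @export
word_surprisal_from_subtokens <- function(logprobs) {
  logprobs <- as.numeric(logprobs)
  if (!length(logprobs)) stop("empty subtoken list")
  if (any(!is.finite(logprobs))) stop("subtoken log-probabilities must be finite")
  if (any(logprobs > 0)) stop("subtoken log-probabilities must be <= 0")
  -sum(logprobs)
}

#' Read subtoken log-probabilities and aggregate per word
#'
#' @param path TSV with columns `word_index`, `subtoken`, `logprob`.
#' @return data.frame with `word_index` and `surprisal` (nats), one row per
#'   word, ordered by `word_index`.
#' @export
read_subtoken_surprisals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("word_index", "subtoken", "logprob") %in% names(df)))
  agg <- tapply(df$logprob, df$word_index, word_surprisal_from_subtokens)
  data.frame(word_index = as.integer(names(agg)),
             surprisal = as.numeric(agg))[order(as.integer(names(agg))), ]
}

#' Attach standardized predictor columns to an event table
#'
#' Adds named predictor vectors as columns and z-scores them using training
#' statistics, which are recorded in the `"standardization"` attribute for
#' reuse on held-out data.
#'
#' @param events event data.frame.
#' @param columns named list of numeric vectors, one value per event.
#' @param train_mask logical vector selecting the rows whose mean/SD define
#'   the standardization (default: all rows).
#' @param standardize logical; if `FALSE`, attach raw values.
#' @return the event table with new columns; attribute `"standardization"`
#'   is a data.frame of `name`, `mean`, `sd`.
#' @export
attach_predictors <- function(events, columns, train_mask = NULL,
                              standardize = TRUE) {
  stopifnot(is.list(columns), !is.null(names(columns)))
  if (is.null(train_mask)) train_mask <- rep(TRUE, nrow(events))
  stats_df <- data.frame(name = character(0), mean = numeric(0),
                         sd = numeric(0))
  for (nm in names(columns)) {
    v <- columns[[nm]]
    if (length(v) != nrow(events))
      stop(sprintf("column '%s' has %d values for %d events",
                   nm, length(v), nrow(events)))
    if (standardize) {
      m <- mean(v[train_mask])
      s <- stats::sd(v[train_mask])
      if (!is.finite(s) || s == 0)
        stop(sprintf("column '%s' is constant (zero SD) on the training set",
                     nm))
      v <- (v - m) / s
      stats_df <- rbind(stats_df, data.frame(name = nm, mean = m, sd = s))
    }
    events[[nm]] <- v
  }
  old <- attr(events, "standardization")
  attr(events, "standardization") <- rbind(old, stats_df)
  events
}

#' @rdname attach_predictors
#' @param names predictor columns to remove.
#' @export
detach_predictors <- function(events, names) {
  events[names] <- NULL
  st <- attr(events, "standardization")
  if (!is.null(st)) {
    st <- st[!st$name %in% names, , drop = FALSE]
    attr(events, "standardization") <- if (nrow(st)) st else NULL
  }
  events
}

#' Serialize / load n-gram counts as sorted plain text
#'
#' One file per order, lines of `ngram<TAB>count`, sorted by n-gram.
#'
#' @param counts a [count_ngrams()] object.
#' @param prefix file prefix; order `k` is written to `<prefix>.<k>.tsv`.
#' @return `write_ngram_counts` the written paths; `read_ngram_counts` a
#'   reconstructed `corpus_counts` object.
#' @export
write_ngram_counts <- function(counts, prefix) {
  stopifnot(inherits(counts, "corpus_counts"))
  paths <- character(0)
  for (k in seq_len(counts$max_order)) {
    v <- counts$orders[[as.character(k)]]
    v <- v[order(names(v))]
    path <- sprintf("%s.%d.tsv", prefix, k)
    utils::write.table(
      data.frame(ngram = names(v), count = as.integer(v)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_ngram_counts
#' @export
read_ngram_counts <- function(prefix) {
  orders <- list()
  k <- 1L
  repeat {
    path <- sprintf("%s.%d.tsv", prefix, k)
    if (!file.exists(path) || k > 3L) break
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
    orders[[as.character(k)]] <- stats::setNames(as.numeric(df$count),
                                                 df$ngram)
    k <- k + 1L
  }
  if (!length(orders)) stop("no count files found at prefix ", prefix)
  max_order <- length(orders)
  ctx_totals <- ctx_types <- vector("list", max_order)
  for (k in seq_len(max_order)) {
    if (k == 1L) next
    keys <- names(orders[[k]])
    ctx <- sub(" [^ ]+$", "", keys)
    ctx_totals[[k]] <- tapply(orders[[k]], ctx, sum)
    ctx_types[[k]] <- tapply(orders[[k]], ctx, length)
  }
  out <- list(orders = orders, context_totals = ctx_totals,
              context_types = ctx_types, total = sum(orders[[1]]),
              vocab = names(orders[[1]]), unk = UNK, max_order = max_order)
  class(out) <- "corpus_counts"
  out
}
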