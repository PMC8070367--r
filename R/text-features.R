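#' Minimal text preprocessing for structure names
#'
#' Physician-given names carry signal in their abbreviations and symbols, so
#' preprocessing is deliberately minimal: lowercase only, no stripping, no
#' re-tokenization. Vectorized.
#'
#' @param raw character vector of verbatim names.
#' @return Lowercased names.
#' @examples
#' preprocessName("Fem hdneck Lt")
#' @export
preprocessName <- function(raw) tolower(raw)

#' Character n-grams of a name
#'
#' Splits on whitespace, wraps each token in boundary markers `<` and `>`,
#' and returns all contiguous character n-grams of the wrapped token for
#' each n in `nMin:nMax`, plus the whole wrapped token itself (when it is
#' not already among the n-grams, i.e. when it is longer than `nMax`).
#'
#' @param name a single string.
#' @param nMin,nMax n-gram range, `1 <= nMin <= nMax`.
#' @return Character vector of n-grams (empty for the empty string).
#' @examples
#' extractCharNgrams("ptv", 2, 2)
#' @export
extractCharNgrams <- function(name, nMin = 2L, nMax = 5L) {
  if (nMin < 1 || nMin > nMax) stop("need 1 <= nMin <= nMax")
  toks <- strsplit(trimws(name), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  out <- character(0)
  for (tok in toks) {
    w <- paste0("<", tok, ">")
    L <- nchar(w)
    for (n in nMin:nMax) {
      if (L < n) next
      out <- c(out, substring(w, 1:(L - n + 1), n:L))
    }
    if (L > nMax) out <- c(out, w)
  }
  out
}

# hash every n-gram of a (already preprocessed) name into bucket ids
.nameBuckets <- function(name, nMin, nMax, buckets) {
  g <- extractCharNgrams(name, nMin, nMax)
  if (!length(g)) return(integer(0))
  vapply(g, .strHash, integer(1), mod = buckets, USE.NAMES = FALSE)
}

#' Train the supervised character n-gram text classifier
#'
#' A self-contained supervised embedding classifier in the fastText mould:
#' each name is a bag of hashed character n-grams, the document vector is
#' the mean of its n-gram embedding rows, and a linear softmax layer maps it
#' to class probabilities. Training is plain SGD on cross-entropy with a
#' linearly decaying learning rate; all randomness (initialization, epoch
#' shuffles) is governed by `seed`, so training is bitwise reproducible.
#'
#' Names are expected to be preprocessed already (see [preprocessName()]).
#'
#' @param names character vector of (preprocessed) structure names.
#' @param labels class name per structure; at least 2 distinct values.
#' @param labelSet optional [LabelSet-class] fixing the class order;
#'   defaults to the sorted unique labels.
#' @param dim embedding dimension (default 200).
#' @param nMin,nMax character n-gram range (default 2-5).
#' @param buckets hash-bucket space (default 2^20); only occupied buckets
#'   are stored.
#' @param epochs SGD epochs (default 25).
#' @param lr initial learning rate (default 0.5), decaying linearly to 0.
#' @param seed integer RNG seed.
#' @return A [TextModel-class].
#' @export
trainTextModel <- function(names, labels, labelSet = NULL, dim = 200L,
                           nMin = 2L, nMax = 5L, buckets = 2^20,
                           epochs = 25L, lr = 0.5, seed = 1L) {
  stopifnot(length(names) == length(labels), length(names) >= 1)
  classNames <- if (is.null(labelSet)) sort(unique(labels))
                else classNames(labelSet)
  if (length(unique(labels)) < 2) stop("degenerate task: single-class input")
  if (!all(labels %in% classNames)) stop("labels outside the label set")
  y <- match(labels, classNames)
  nC <- length(classNames)

  docIds <- lapply(names, .nameBuckets, nMin = nMin, nMax = nMax,
                   buckets = buckets)
  vocab <- sort(unique(unlist(docIds)))
  docRows <- lapply(docIds, function(ids) match(ids, vocab))

  nDoc <- length(names)
  total <- epochs * nDoc
  E <- NULL
  W <- matrix(0, nC, dim)
  withr::with_seed(seed, {
    E <- matrix(runif(length(vocab) * dim, -1 / dim, 1 / dim),
                nrow = length(vocab), ncol = dim)
    step <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nDoc)) {
        step <- step + 1
        ids <- docRows[[i]]
        if (!length(ids)) next
        lrt <- lr * (1 - (step - 1) / total)
        h <- colMeans(E[ids, , drop = FALSE])
        s <- drop(W %*% h)
        s <- s - max(s)
        p <- exp(s)
        p <- p / sum(p)
        g <- p
        g[y[i]] <- g[y[i]] - 1
        gh <- drop(crossprod(W, g))
        W <- W - lrt * tcrossprod(g, h)
        E[ids, ] <- E[ids, , drop = FALSE] -
          (lrt / length(ids)) * matrix(gh, nrow = length(ids), ncol = dim,
                                       byrow = TRUE)
      }
    }
  })
  new("TextModel", embeddings = E, vocabIds = as.integer(vocab),
      outputWeights = W, classNames = classNames,
      config = list(nMin = nMin, nMax = nMax, buckets = buckets, dim = dim,
                    epochs = epochs, lr = lr, seed = seed))
}

# mean-pooled document vectors for a character vector of names (rows)
.docMatrix <- function(model, names) {
  cfg <- model@config
  out <- matrix(0, length(names), ncol(model@embeddings))
  for (i in seq_along(names)) {
    ids <- .nameBuckets(names[i], cfg$nMin, cfg$nMax, cfg$buckets)
    rows <- match(ids, model@vocabIds)
    rows <- rows[!is.na(rows)]
    if (length(rows))
      out[i, ] <- colMeans(model@embeddings[rows, , drop = FALSE])
  }
  out
}

#' Embed a name as a document vector
#'
#' Mean of the name's in-vocabulary n-gram embedding rows; the zero vector
#' when no n-gram is known. Deterministic.
#'
#' @param model a trained [TextModel-class].
#' @param name character vector of (preprocessed) names.
#' @return numeric matrix, one row per name, `dim` columns (a plain vector
#'   for a single name).
#' @export
embedName <- function(model, name) {
  m <- .docMatrix(model, name)
  if (length(name) == 1) drop(m) else m
}

#' Class probabilities from the text view
#'
#' Softmax over the linear class scores of the document vector, ordered by
#' the model's class names. A fully out-of-vocabulary name yields the
#' uniform distribution (zero document vector, equal scores).
#'
#' @param model a trained [TextModel-class].
#' @param name character vector of (preprocessed) names.
#' @return Probability matrix (rows sum to 1), columns named by class; a
#'   plain named vector for a single name.
#' @export
predictTextProba <- function(model, name) {
  H <- .docMatrix(model, name)
  S <- H %*% t(model@outputWeights)
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P <- P / rowSums(P)
  colnames(P) <- model@classNames
  if (length(name) == 1) P[1, ] else P
}
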