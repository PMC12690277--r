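#' Create a sentence embedder
#'
#' Returns an embedder object implementing the backend contract used
#' throughout the package: a fixed output dimension, deterministic
#' embeddings, optional L2 normalization (on by default, so cosine
#' similarity reduces to a dot product), and an in-memory cache so each
#' distinct sentence is embedded once.
#'
#' Backends:
#' * `"hashed_ngram"` (default): signed hashing of character n-grams
#'   (n = 3..5 over the lowercased, space-padded sentence) into `dimension`
#'   buckets, then L2 normalization. Purely lexical, dependency-free and
#'   fully deterministic; the default dimension of 1024 mirrors the large
#'   pretrained sentence encoders typically used for this analysis.
#' * `"transformer"`: a pretrained sentence encoder supplied by the caller
#'   through `embed_fun` (a `function(texts) matrix`). No model ships with
#'   the package; requesting this backend without `embed_fun` raises a
#'   capability error pointing at `hashed_ngram`.
#'
#' @param backend `"hashed_ngram"` or `"transformer"`.
#' @param dimension Output dimension (default 1024).
#' @param normalize L2-normalize each vector (default `TRUE`).
#' @param model_name Label for the transformer model (metadata only).
#' @param embed_fun For `backend = "transformer"`: function taking a
#'   character vector and returning a numeric matrix with one row per text.
#' @param ngram Integer range of character n-gram lengths for
#'   `hashed_ngram` (default `3:5`).
#' @return An object of class `pain_embedder`.
#' @export
#' @examples
#' emb <- hashed_embedder(dimension = 256)
#' v <- embed_sentences(c("My pain is throbbing", "I slept well"), emb)
#' dim(v)
embedder <- function(backend = c("hashed_ngram", "transformer"),
                     dimension = 1024L, normalize = TRUE,
                     model_name = NULL, embed_fun = NULL, ngram = 3:5) {
  backend <- match.arg(backend)
  if (dimension < 1) abort("dimension must be positive")
  if (backend == "transformer" && is.null(embed_fun)) {
    abort(paste(
      "transformer backend requested but no model is available:",
      "supply `embed_fun` wrapping an installed sentence encoder,",
      "or use embedder(backend = \"hashed_ngram\")."
    ))
  }
  obj <- list(
    backend = backend,
    dimension = as.integer(dimension),
    normalize = isTRUE(normalize),
    model_name = model_name,
    embed_fun = embed_fun,
    ngram = as.integer(ngram),
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "pain_embedder"
  obj
}

#' @rdname embedder
#' @export
hashed_embedder <- function(dimension = 1024L, normalize = TRUE, ngram = 3:5) {
  embedder("hashed_ngram", dimension = dimension, normalize = normalize,
           ngram = ngram)
}

#' @export
print.pain_embedder <- function(x, ...) {
  cat(sprintf("<pain_embedder: %s, dimension %d, normalize %s, %d cached>\n",
              x$backend, x$dimension, x$normalize, length(ls(x$cache))))
  invisible(x)
}

#' Embed sentences
#'
#' One vector per input sentence, order preserved. Deterministic: the same
#' (text, embedder spec) always yields the same vector; results are cached
#' per embedder object.
#'
#' @param texts Character vector of non-empty sentences.
#' @param emb A [embedder()] object.
#' @return Numeric matrix, `length(texts)` rows by `emb$dimension` columns,
#'   rows unit-normalized when `emb$normalize` is on.
#' @export
embed_sentences <- function(texts, emb) {
  stopifnot(inherits(emb, "pain_embedder"))
  texts <- as.character(texts)
  if (length(texts) == 0) abort("no texts to embed")
  if (any(is.na(texts)) || any(!nzchar(trimws(texts)))) {
    abort("cannot embed empty or missing sentences")
  }
  out <- matrix(NA_real_, nrow = length(texts), ncol = emb$dimension)
  uniq <- unique(texts)
  todo <- uniq[!vapply(uniq, exists, logical(1), envir = emb$cache)]
  if (length(todo) > 0) {
    vecs <- if (emb$backend == "hashed_ngram") {
      t(vapply(todo, hashed_ngram_vector, numeric(emb$dimension),
               dimension = emb$dimension, ngram = emb$ngram))
    } else {
      m <- emb$embed_fun(todo)
      if (!is.matrix(m) || nrow(m) != length(todo) || ncol(m) != emb$dimension) {
        abort(sprintf("embed_fun must return a %d x %d matrix",
                      length(todo), emb$dimension))
      }
      m
    }
    if (emb$normalize) {
      nrm <- sqrt(rowSums(vecs^2))
      if (any(nrm == 0)) abort("embedding produced a zero vector; cannot normalize")
      vecs <- vecs / nrm
    }
    for (i in seq_along(todo)) assign(todo[[i]], vecs[i, ], envir = emb$cache)
  }
  for (i in seq_along(texts)) out[i, ] <- get(texts[[i]], envir = emb$cache)
  rownames(out) <- NULL
  out
}

# Character n-grams of the lowercased, single-space-squished sentence,
# padded with one leading and trailing space.
char_ngrams <- function(text, ngram) {
  x <- paste0(" ", stringr::str_squish(tolower(text)), " ")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- character(0)
  for (n in ngram) {
    if (L >= n) {
      starts <- seq_len(L - n + 1L)
      out <- c(out, vapply(starts, function(s) {
        paste(chars[s:(s + n - 1L)], collapse = "")
      }, character(1)))
    }
  }
  out
}

# Two independent polynomial rolling hashes over the n-gram's code points,
# kept below 2^26 so all double-precision arithmetic stays exact.
ngram_hashes <- function(grams) {
  p <- 67108859 # largest prime < 2^26
  h1 <- vapply(grams, function(g) {
    h <- 0
    for (cp in utf8ToInt(g)) h <- (h * 31 + cp) %% p
    h
  }, numeric(1))
  h2 <- vapply(grams, function(g) {
    h <- 7
    for (cp in utf8ToInt(g)) h <- (h * 131 + cp) %% p
    h
  }, numeric(1))
  list(h1 = h1, h2 = h2)
}

hashed_ngram_vector <- function(text, dimension, ngram) {
  grams <- char_ngrams(text, ngram)
  v <- numeric(dimension)
  if (length(grams) == 0) return(v)
  h <- ngram_hashes(grams)
  bucket <- (h$h1 %% dimension) + 1L
  sign <- ifelse(h$h2 %% 2 == 0, 1, -1)
  for (i in seq_along(bucket)) v[bucket[[i]]] <- v[bucket[[i]]] + sign[[i]]
  v
}

#' Embed an anchor registry
#'
#' Embeds every anchor and antithesis sentence once with the same backend
#' used for interview sentences.
#'
#' @param registry An [anchor_registry()].
#' @param emb A [embedder()].
#' @return Tibble with columns `pair_id`, `side` (`"anchor"`/
#'   `"antithesis"`), `probe_id` (`"<pair_id>__<side>"`), `text`, and a
#'   matrix column `vector`.
#' @export
embed_registry <- function(registry, emb) {
  stopifnot(inherits(registry, "anchor_registry"))
  long <- tidyr::pivot_longer(
    as_tibble(registry)[, c("pair_id", "anchor_text", "antithesis_text")],
    cols = c("anchor_text", "antithesis_text"),
    names_to = "side", values_to = "text"
  ) |>
    mutate(side = sub("_text$", "", .data$side),
           probe_id = paste0(.data$pair_id, "__", .data$side))
  long$vector <- embed_sentences(long$text, emb)
  long[, c("pair_id", "side", "probe_id", "text", "vector")]
}
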