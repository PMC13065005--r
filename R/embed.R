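#' Deterministic seeded hash embedder
#'
#' A fixture embedding backend satisfying the embedder contract: every
#' token maps to a fixed unit vector derived from a seeded hash of its
#' lowercase surface, so the same token always gets the same vector and two
#' unrelated tokens are nearly orthogonal in expectation (cosine
#' concentrates around 0 with sd about `1/sqrt(dim)`). Declared synonym
#' pairs are forced close by interpolation
#' (`v_syn = normalize(0.95 * v_base + 0.05 * v_own)`), giving cosine
#' `>= 0.9` by construction. If `known_tokens` is supplied, tokens outside
#' it map to the zero-vector out-of-vocabulary sentinel.
#'
#' The global RNG state is saved and restored around every embedding call.
#'
#' @param dim embedding dimension, `>= 8` (default 64)
#' @param seed integer seed mixed into every token hash
#' @param synonym_table optional two-column data.frame / matrix of
#'   (variant, base) pairs to force together
#' @param known_tokens optional character vector; tokens outside it embed
#'   to the zero vector
#' @return an object of class `hash_embedder` with elements `embed`
#'   (function `token -> numeric[dim]`) and `dim`
#' @export
#' @examples
#' emb <- hash_embedder(dim = 32, seed = 1)
#' v <- emb$embed("nausea")
#' sum(v^2)
hash_embedder <- function(dim = 64L, seed = 0L, synonym_table = NULL,
                          known_tokens = NULL) {
  stopifnot(dim >= 8L)
  dim <- as.integer(dim)
  syn <- NULL
  if (!is.null(synonym_table)) {
    syn <- as.data.frame(synonym_table, stringsAsFactors = FALSE)
    stopifnot(ncol(syn) >= 2L)
    names(syn)[1:2] <- c("variant", "base")
    syn$variant <- tolower(syn$variant)
    syn$base <- tolower(syn$base)
  }
  known <- if (is.null(known_tokens)) NULL else tolower(known_tokens)

  raw_vec <- function(tok) {
    v <- with_local_seed(string_seed(tok, salt = seed),
                         function() stats::rnorm(dim))
    v / sqrt(sum(v^2))
  }
  embed_one <- function(token) {
    tok <- tolower(trimws(token))
    if (!nzchar(tok)) return(numeric(dim))
    if (!is.null(known) && !(tok %in% known)) return(numeric(dim))
    if (!is.null(syn) && tok %in% syn$variant) {
      base <- syn$base[match(tok, syn$variant)]
      v <- 0.95 * raw_vec(base) + 0.05 * raw_vec(tok)
      return(v / sqrt(sum(v^2)))
    }
    raw_vec(tok)
  }
  structure(list(embed = embed_one, dim = dim), class = "hash_embedder")
}

# mean-of-token-vectors representation of a possibly multi-word term;
# zero vector if every token is out of vocabulary
embed_term <- function(term, embedder) {
  toks <- strsplit(trimws(tolower(term)), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(numeric(embedder$dim))
  vs <- vapply(toks, embedder$embed, numeric(embedder$dim))
  rowMeans(matrix(vs, nrow = embedder$dim))
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Similarity of a term to a medical vocabulary
#'
#' Embeds the term (multi-word terms as the arithmetic mean of their token
#' vectors) and every vocabulary entry, and returns the maximum cosine
#' similarity over entries. A zero-vector on either side contributes
#' similarity 0, so out-of-vocabulary terms score 0 against everything.
#'
#' @param term non-empty character scalar
#' @param vocab a [medical_vocabulary()]
#' @param embedder an embedder (e.g. [hash_embedder()])
#' @return numeric scalar in `[-1, 1]`
#' @export
term_similarity <- function(term, vocab, embedder) {
  stopifnot(nzchar(trimws(term)))
  v <- embed_term(term, embedder)
  if (sqrt(sum(v^2)) == 0) return(0)
  sims <- vapply(vocab$terms,
                 function(entry) cosine(v, embed_term(entry, embedder)),
                 numeric(1))
  max(sims)
}
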