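# shared fixtures built in code

ext_path <- function(...) {
  system.file("extdata", ..., package = "aspectrx", mustWork = TRUE)
}

fx_tagger <- fixture_tagger()
fx_modlex <- default_modifier_lexicon()
fx_sentlex <- sentiment_lexicon()
fx_th <- thresholds()

r1_text <- "so far im feeling quite positive and free of depressive feelings"
r2_text <- "however that's only if we get a good nights sleep"
actemra_text <- paste(
  "i have been truly lucky as i have not experienced any side affects",
  "in the years i have been on actemra"
)
review_p <- paste(
  "Contrave combines drugs that were used for alcohol, smoking, and opioid",
  "cessation. People lose weight on it because it also helps control",
  "over-eating. I have no doubt that most obesity is caused from sugar/carb",
  "addiction, which is just as powerful as any drug. I have been taking it",
  "for five days, and the good news is, it seems to go to work immediately."
)

# an embedder with hand-chosen vectors: distinct tokens are exactly
# orthogonal unit basis vectors; unknown tokens map to the zero sentinel
basis_embedder <- function(tokens, dim = max(8, length(tokens))) {
  stopifnot(length(tokens) <= dim)
  structure(list(
    embed = function(token) {
      v <- numeric(dim)
      i <- match(tolower(token), tolower(tokens))
      if (!is.na(i)) v[i] <- 1
      v
    },
    dim = dim
  ), class = "hash_embedder")
}

tmp_reviews_csv <- function(rows) {
  p <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  utils::write.csv(rows, p, row.names = FALSE)
  p
}
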