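# A compact deterministic contextual encoder satisfying the encoder
# contract: tokenization with character offsets (see tokenize_words),
# per-row contextual vectors, custom shared position indices, and a
# pairwise visibility mask.  Token and position embeddings are frozen
# pseudo-random vectors derived from a seed, so the encoder is fully
# deterministic and needs no fitted weights; only the classification
# heads on top of it are trained.
#
# Architecture: input = token embedding + position embedding; two layers
# of masked scaled dot-product self-attention with residual connections;
# the output concatenates the attended representation with a sum-pooled
# context channel over the visible text block (so cue words elsewhere in
# the sentence remain linearly accessible from marker rows, with a
# contribution independent of sentence length).

#' Construct a frozen deterministic encoder
#'
#' @param dim Embedding dimension per channel (output width is `2 * dim`).
#' @param seed Integer seed freezing all embeddings.
#' @param n_layers Number of masked self-attention layers.
#' @param sharpness Attention temperature multiplier; higher values make
#'   the position-keyed attention more sharply peaked at shared position
#'   indices.
#' @return An object of class `frozen_encoder`.
#' @export
frozen_encoder <- function(dim = 64L, seed = 1L, n_layers = 2L,
                           sharpness = 3) {
  structure(
    list(dim = as.integer(dim), seed = as.integer(seed),
         n_layers = as.integer(n_layers), width = 2L * as.integer(dim),
         sharpness = sharpness,
         cache = new.env(parent = emptyenv())),
    class = "frozen_encoder"
  )
}

#' @export
print.frozen_encoder <- function(x, ...) {
  cat(sprintf("<frozen_encoder dim=%d layers=%d width=%d seed=%d>\n",
              x$dim, x$n_layers, x$width, x$seed))
  invisible(x)
}

# Deterministic 32-bit hash of a string (FNV-1a style, kept in double to
# avoid integer overflow warnings).
.string_hash <- function(s) {
  h <- 2166136261
  for (cp in utf8ToInt(s)) {
    h <- ((h %% 65536) * 16777619 + (h %/% 65536) * 16777619 %% 65536 * 65536 + cp) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

.hashed_vector <- function(enc, key) {
  hit <- enc$cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- .Random.seed_get()
  set.seed((.string_hash(key) + enc$seed * 7919L) %% 2147483647L)
  v <- stats::rnorm(enc$dim)
  .Random.seed_set(old)
  enc$cache[[key]] <- v
  v
}

# Save/restore the global RNG state so encoding never perturbs user code.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

token_embedding <- function(enc, token) .hashed_vector(enc, paste0("tok\r", tolower(token)))
position_embedding <- function(enc, pos) .hashed_vector(enc, paste0("pos\r", pos))

#' Encode a marker pack
#'
#' Runs the frozen encoder over a pack: token plus shared position
#' embeddings, `n_layers` of visibility-masked self-attention with
#' residual connections, then concatenation with the visible-text sum
#' pool.  Deterministic for fixed encoder seed and input.
#'
#' @param enc A [frozen_encoder()].
#' @param pack A marker pack (see [pack_neighborhood()]).
#' @return Numeric matrix, one row per pack row, `enc$width` columns.
#' @export
encode_pack <- function(enc, pack) {
  rows <- pack$rows
  m <- length(rows$token)
  Tm <- matrix(0, m, enc$dim) # token-content stream
  P <- matrix(0, m, enc$dim)  # shared position embeddings
  for (i in seq_len(m)) {
    Tm[i, ] <- token_embedding(enc, rows$token[i])
    P[i, ] <- position_embedding(enc, rows$position[i])
  }
  mask <- build_visibility_mask(pack)
  # disentangled attention: scores from position embeddings (sharply
  # peaked at shared position indices), values from token content, so
  # marker representations aggregate the content of the tokens whose
  # positions they share without absorbing position noise
  S <- P %*% t(P) * enc$sharpness / sqrt(enc$dim)
  S[!mask] <- -Inf
  S <- S - apply(S, 1L, max) # numerical stability
  A <- exp(S)
  A <- A / rowSums(A)
  H <- Tm
  for (l in seq_len(enc$n_layers)) {
    H <- H + A %*% H
  }
  textish <- rows$kind %in% c("text", "solid")
  ctx_pool <- colSums(H[textish, , drop = FALSE])
  C <- matrix(ctx_pool, m, enc$dim, byrow = TRUE)
  cbind(H, C)
}
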