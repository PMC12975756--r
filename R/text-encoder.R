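#' Configure the clinical-text transformer encoder
#'
#' Defaults mirror a BERT-base clinical encoder: 12 layers, hidden size
#' 768, 12 attention heads, WordPiece-style vocabulary. Small
#' configurations (2 layers, hidden 32) are used for desk-scale training;
#' the default configuration is used for parameter accounting. Pretrained
#' weights can be loaded from disk when available; otherwise
#' initialization is seeded random.
#'
#' @param layers transformer layers (>= 1).
#' @param hidden hidden size d (divisible by heads).
#' @param heads attention heads.
#' @param vocabSize vocabulary size.
#' @param maxLen maximum sequence length.
#' @param intermediate feed-forward inner width (default 4*hidden).
#' @param pretrainedPath optional RDS path with a saved weight list.
#' @return an "encoderConfig" list.
#' @export
encoderConfig <- function(layers = 12L, hidden = 768L, heads = 12L,
                          vocabSize = 30522L, maxLen = 128L,
                          intermediate = 4L * hidden,
                          pretrainedPath = NULL) {
  stopifnot(layers >= 1L, hidden %% heads == 0L)
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads),
                 vocabSize = as.integer(vocabSize),
                 maxLen = as.integer(maxLen),
                 intermediate = as.integer(intermediate),
                 pretrainedPath = pretrainedPath),
            class = "encoderConfig")
}

#' Configure low-rank (LoRA) adapters
#'
#' Each targeted attention projection W0 is augmented as
#' W' = W0 + (alpha/r) A B with A (d x r) small random, B (r x d) zero, so
#' outputs are bit-identical to the unadapted encoder at injection. Only A
#' and B train; W0 stays frozen.
#'
#' @param r adapter rank (default 8).
#' @param alpha scaling (default 16).
#' @param targets attention matrices to adapt, subset of
#'   c("query", "key", "value", "output").
#' @return a "loraConfig" list.
#' @export
loraConfig <- function(r = 8L, alpha = 16, targets = c("query", "value")) {
  stopifnot(r >= 1L, length(targets) >= 1L,
            all(targets %in% c("query", "key", "value", "output")))
  structure(list(r = as.integer(r), alpha = alpha, targets = targets),
            class = "loraConfig")
}

# --- tokenizer ------------------------------------------------------------

#' Default WordPiece-style vocabulary for serialized clinical records
#'
#' Digits are tokenized individually so unseen numeric values never fall
#' out of vocabulary.
#' @return character vector of tokens (position = id).
#' @export
defaultVocab <- function() {
  c("[PAD]", "[UNK]", "[CLS]", "[SEP]",
    as.character(0:9), ".", "-",
    "updrs", "total", "score", "is", "age", "years", "moca", "impairment",
    "hoehn", "and", "yahr", "stage", "weight", "kilograms", "years,",
    "gene", "carrier", "status", "positive", "negative", "male", "female",
    "duration", "bmi", "education")
}

#' Load a vocabulary file (one token per line, WordPiece layout)
#' @param path file path.
#' @export
loadVocab <- function(path) readLines(path, warn = FALSE)

#' Tokenize text for the clinical encoder
#'
#' Lower-cases, splits on whitespace and punctuation (keeping "." as its
#' own token), splits numerals into digit tokens, and wraps the sequence in
#' [CLS]/[SEP]. Unknown tokens map to [UNK]. An empty string encodes the
#' special-token-only sequence.
#'
#' @param text input string.
#' @param vocab vocabulary (character vector).
#' @param maxLen truncation length.
#' @return integer token ids.
#' @export
tokenize <- function(text, vocab = defaultVocab(), maxLen = 128L) {
  s <- tolower(text)
  s <- gsub("([.,;:!?()])", " \\1 ", s)
  s <- gsub("([0-9])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- match("[UNK]", vocab)
  ids <- c(match("[CLS]", vocab), ids, match("[SEP]", vocab))
  head(ids, maxLen)
}

# --- parameters -----------------------------------------------------------

#' Analytic parameter count of an encoder configuration
#'
#' @param cfg an \code{\link{encoderConfig}}.
#' @return named per-module counts (embeddings, per-layer attention and
#'   feed-forward, layer norms).
#' @export
countTextEncoderParams <- function(cfg) {
  d <- cfg$hidden; i <- cfg$intermediate
  emb <- cfg$vocabSize * d + cfg$maxLen * d + 2 * d
  perLayer <- 4 * (d * d + d) +      # Q, K, V, O projections
    2 * d +                          # attention layer norm
    d * i + i + i * d + d +          # feed-forward
    2 * d                            # output layer norm
  c(embeddings = emb, transformer_layers = cfg$layers * perLayer)
}

#' Closed-form LoRA trainable-parameter count
#'
#' @param cfg an \code{\link{encoderConfig}}.
#' @param lora a \code{\link{loraConfig}}.
#' @return trainable adapter parameters: layers x targets x 2 d r.
#' @export
countLoraParams <- function(cfg, lora) {
  cfg$layers * length(lora$targets) * 2L * cfg$hidden * lora$r
}

#' Build a transformer text encoder
#'
#' @param cfg an \code{\link{encoderConfig}}.
#' @param seed weight-initialization seed (ignored when pretrained weights
#'   are loaded from \code{cfg$pretrainedPath}).
#' @return a "textEncoder" list with weights, config, and (initially
#'   absent) adapters.
#' @export
buildTextEncoder <- function(cfg, seed = 1L) {
  w <- if (!is.null(cfg$pretrainedPath)) {
    readRDS(cfg$pretrainedPath)
  } else {
    with_seed(seed, init_encoder_weights(cfg))
  }
  structure(list(cfg = cfg, w = w, lora = NULL), class = "textEncoder")
}

init_encoder_weights <- function(cfg) {
  d <- cfg$hidden; i <- cfg$intermediate
  s <- 0.02
  mk <- function(nr, nc) matrix(rnorm(nr * nc, 0, s), nr, nc)
  layers <- lapply(seq_len(cfg$layers), function(l) list(
    Wq = mk(d, d), bq = rep(0, d), Wk = mk(d, d), bk = rep(0, d),
    Wv = mk(d, d), bv = rep(0, d), Wo = mk(d, d), bo = rep(0, d),
    ln1g = rep(1, d), ln1b = rep(0, d),
    W1 = mk(d, i), b1 = rep(0, i), W2 = mk(i, d), b2 = rep(0, d),
    ln2g = rep(1, d), ln2b = rep(0, d)))
  list(tok = mk(cfg$vocabSize, d), pos = mk(cfg$maxLen, d),
       lnEg = rep(1, d), lnEb = rep(0, d), layers = layers)
}

#' Inject LoRA adapters into an encoder
#'
#' @param encoder a \code{\link{buildTextEncoder}} result.
#' @param lora a \code{\link{loraConfig}}.
#' @param seed adapter initialization seed (A random small, B zero).
#' @return list with the adapted \code{encoder} and a
#'   \code{\linkS4class{ParamReport}} itemizing trainable vs frozen.
#' @export
injectLora <- function(encoder, lora, seed = 1L) {
  d <- encoder$cfg$hidden
  if (lora$r >= d) stopf("LoRA rank must be below the hidden size")
  adapters <- with_seed(seed, lapply(seq_len(encoder$cfg$layers),
    function(l) {
      setNames(lapply(lora$targets, function(tg) list(
        A = matrix(rnorm(d * lora$r, 0, 0.02), d, lora$r),
        B = matrix(0, lora$r, d))), lora$targets)
    }))
  encoder$lora <- list(cfg = lora, adapters = adapters)
  frozenMods <- countTextEncoderParams(encoder$cfg)
  trainable <- countLoraParams(encoder$cfg, lora)
  mods <- c(frozenMods, lora_adapters = trainable)
  report <- new("ParamReport", modules = mods, total = sum(mods),
                totalM = round_half_up(sum(mods) / 1e6, 1),
                trainable = trainable, frozen = sum(frozenMods),
                macs = NA_real_, inputSize = "per token")
  list(encoder = encoder, report = report)
}

#' Merge LoRA adapters into the base weights
#'
#' Materializes W' = W0 + (alpha/r) A B for every adapted matrix and drops
#' the adapters; the merged encoder's outputs equal the adapted encoder's.
#'
#' @param encoder a LoRA-adapted encoder.
#' @return plain encoder with merged weights.
#' @export
mergeLora <- function(encoder) {
  if (is.null(encoder$lora)) return(encoder)
  sc <- encoder$lora$cfg$alpha / encoder$lora$cfg$r
  key <- c(query = "Wq", key = "Wk", value = "Wv", output = "Wo")
  for (l in seq_along(encoder$w$layers)) {
    for (tg in names(encoder$lora$adapters[[l]])) {
      ad <- encoder$lora$adapters[[l]][[tg]]
      encoder$w$layers[[l]][[key[tg]]] <-
        encoder$w$layers[[l]][[key[tg]]] + sc * (ad$A %*% ad$B)
    }
  }
  encoder$lora <- NULL
  encoder
}

# Forward pass on an autodiff tape. `p` maps every weight to a tape node
# (const for frozen, param for trainable); built by encoder_nodes().
encoder_forward <- function(tape, encoder, ids, p) {
  cfg <- encoder$cfg
  d <- cfg$hidden
  H <- cfg$heads
  dh <- d %/% H
  n <- length(ids)
  X <- adAdd(tape, adRows(tape, p$tok, ids),
             adRows(tape, p$pos, seq_len(n)))
  X <- adLayerNorm(tape, X, p$lnEg, p$lnEb)
  key <- c(query = "Wq", key = "Wk", value = "Wv", output = "Wo")
  for (l in seq_len(cfg$layers)) {
    lp <- p$layers[[l]]
    proj <- function(tg) {
      base <- adAdd(tape, adMatmul(tape, X, lp[[key[tg]]]),
                    lp[[sub("W", "b", key[tg])]])
      ad <- p$adapters[[l]][[tg]]
      if (is.null(ad)) return(base)
      sc <- encoder$lora$cfg$alpha / encoder$lora$cfg$r
      adAdd(tape, base,
            adScale(tape, adMatmul(tape, adMatmul(tape, X, ad$A), ad$B),
                    sc))
    }
    Q <- proj("query"); K <- proj("key"); V <- proj("value")
    headsOut <- vector("list", H)
    for (h in seq_len(H)) {
      cidx <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- adCols(tape, Q, cidx)
      Kh <- adCols(tape, K, cidx)
      Vh <- adCols(tape, V, cidx)
      A <- adSoftmaxRows(tape, adScale(tape,
            adMatmul(tape, Qh, adTranspose(tape, Kh)), 1 / sqrt(dh)))
      headsOut[[h]] <- adMatmul(tape, A, Vh)
    }
    att <- headsOut[[1L]]
    if (H > 1L) for (h in 2:H) att <- adCbind(tape, att, headsOut[[h]])
    O <- proj_out(tape, att, lp, p$adapters[[l]], encoder)
    X <- adLayerNorm(tape, adAdd(tape, X, O), lp$ln1g, lp$ln1b)
    FF <- adAdd(tape, adMatmul(tape,
            adRelu(tape, adAdd(tape, adMatmul(tape, X, lp$W1), lp$b1)),
            lp$W2), lp$b2)
    X <- adLayerNorm(tape, adAdd(tape, X, FF), lp$ln2g, lp$ln2b)
  }
  list(tokens = X, pooled = adRows(tape, X, 1L))
}

proj_out <- function(tape, att, lp, adapters, encoder) {
  base <- adAdd(tape, adMatmul(tape, att, lp$Wo), lp$bo)
  ad <- adapters[["output"]]
  if (is.null(ad)) return(base)
  sc <- encoder$lora$cfg$alpha / encoder$lora$cfg$r
  adAdd(tape, base,
        adScale(tape, adMatmul(tape, adMatmul(tape, att, ad$A), ad$B), sc))
}

# Create tape nodes for all encoder weights. trainLora = TRUE makes the
# adapters adParam (trainable) and everything else adConst (frozen).
encoder_nodes <- function(tape, encoder, trainLora = TRUE) {
  w <- encoder$w
  asNode <- function(v) adConst(tape, v)
  p <- list(tok = asNode(w$tok), pos = asNode(w$pos),
            lnEg = asNode(matrix(w$lnEg, 1)),
            lnEb = asNode(matrix(w$lnEb, 1)))
  p$layers <- lapply(w$layers, function(lw) {
    lapply(lw, function(v)
      if (is.matrix(v)) asNode(v) else asNode(matrix(v, 1)))
  })
  p$adapters <- lapply(seq_along(w$layers), function(l) {
    if (is.null(encoder$lora)) return(list())
    lapply(encoder$lora$adapters[[l]], function(ad) {
      if (trainLora) list(A = adParam(tape, ad$A), B = adParam(tape, ad$B))
      else list(A = adConst(tape, ad$A), B = adConst(tape, ad$B))
    })
  })
  p
}

#' Encode text into token states and a pooled embedding
#'
#' Deterministic in evaluation; returns the final-layer per-token states
#' and the first-token pooled sentence embedding E_t.
#'
#' @param encoder a \code{\link{buildTextEncoder}} result (optionally
#'   LoRA-adapted).
#' @param text input string (empty string encodes special tokens only).
#' @param vocab tokenizer vocabulary.
#' @return list with \code{tokens} (n x d matrix) and \code{pooled}
#'   (length-d vector).
#' @export
encodeText <- function(encoder, text, vocab = defaultVocab()) {
  ids <- tokenize(text, vocab, encoder$cfg$maxLen)
  tape <- adTape()
  p <- encoder_nodes(tape, encoder, trainLora = FALSE)
  out <- encoder_forward(tape, encoder, ids, p)
  list(tokens = value(out$tokens), pooled = as.numeric(value(out$pooled)))
}

#' Build the 256-d projection head
#'
#' An affine map from the encoder's hidden size to the shared embedding
#' space (196,864 parameters at 768 -> 256).
#'
#' @param d input width (default 768).
#' @param out output width (default 256).
#' @param seed initialization seed.
#' @export
projectionHead <- function(d = 768L, out = 256L, seed = 1L) {
  with_seed(seed, list(W = matrix(rnorm(d * out, 0, sqrt(1 / d)), d, out),
                       b = rep(0, out), d = d, out = out))
}

#' Project a pooled embedding into the shared space
#' @param head a \code{\link{projectionHead}}.
#' @param e length-d numeric vector (or n x d matrix).
#' @export
projectEmbedding <- function(head, e) {
  e <- if (is.matrix(e)) e else matrix(e, 1)
  if (ncol(e) != head$d) stopf("expected length-%d input", head$d)
  out <- sweep(e %*% head$W, 2, head$b, "+")
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Parameter count of the projection head
#' @param head a \code{\link{projectionHead}}.
#' @export
projectionParams <- function(head) head$d * head$out + head$out
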