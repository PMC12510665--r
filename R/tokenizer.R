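SPECIAL_TOKENS <- c(PAD = 0L, EOS = 1L, BOS = 2L, UNK = 3L)

# Internal symbol convention: protein residues keep their uppercase letter;
# RNA bases are lowercased so the two alphabets are disjoint and no BPE merge
# can ever combine a protein symbol with an RNA symbol.
symbolize <- function(seq, kind) {
  s <- if (kind == "rna") tolower(seq) else seq
  strsplit(s, "", fixed = TRUE)[[1L]]
}

desymbolize <- function(token) {
  first <- substr(token, 1L, 1L)
  if (first %in% c("a", "c", "g", "u")) toupper(token) else token
}

merge_pair_in_seq <- function(x, left, right, merged) {
  n <- length(x)
  if (n < 2L) return(x)
  out <- character(n)
  j <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && x[i] == left && x[i + 1L] == right) {
      j <- j + 1L
      out[j] <- merged
      i <- i + 2L
    } else {
      j <- j + 1L
      out[j] <- x[i]
      i <- i + 1L
    }
  }
  out[seq_len(j)]
}

#' Train a byte-pair-encoding tokenizer
#'
#' Standard BPE: starting from single-character symbols, the most frequent
#' adjacent symbol pair is merged iteratively until `vocab_size` non-special
#' tokens exist or no pair occurs at least twice. Ties are broken
#' lexicographically on the (left, right) pair. One shared model is trained
#' on the union of protein and RNA sequences; RNA symbols are held in a
#' disjoint internal alphabet (lowercase), so learned merges never mix the
#' two alphabets.
#'
#' @param records List of [sequence_record()] objects (the training corpus).
#' @param vocab_size Maximum number of non-special tokens (base alphabet
#'   plus merges). The four specials PAD/EOS/BOS/UNK are reserved outside
#'   this budget at ids 0-3.
#' @param min_pair_count Minimum pair frequency required to merge (default 2).
#' @return An object of class `bpe_tokenizer`: `vocab` (named integer map
#'   token string -> 0-based id), `merges` (list of c(left, right)),
#'   `specials`, `base_alphabet`.
#' @export
train_bpe <- function(records, vocab_size = 1000L, min_pair_count = 2L) {
  if (length(records) == 0L) stop("training corpus is empty")
  if (inherits(records[[1L]], "interaction_record"))
    records <- unlist(lapply(records, function(r) list(r$protein, r$rna)),
                      recursive = FALSE)
  corpus <- lapply(records, function(r) symbolize(r$seq, r$kind))
  base <- sort(unique(unlist(corpus)))
  if (vocab_size < length(base))
    stop("vocab_size (", vocab_size, ") is smaller than the base alphabet (",
         length(base), " symbols)")
  merges <- list()
  tokens <- base
  while (length(tokens) < vocab_size) {
    lefts <- unlist(lapply(corpus, function(x)
      if (length(x) >= 2L) x[-length(x)] else character()))
    if (length(lefts) == 0L) break
    rights <- unlist(lapply(corpus, function(x)
      if (length(x) >= 2L) x[-1L] else character()))
    keys <- paste(lefts, rights, sep = "\x1f")
    tab <- table(keys)
    best_count <- max(tab)
    if (best_count < min_pair_count) break
    cand <- sort(names(tab)[tab == best_count])[1L]
    pair <- strsplit(cand, "\x1f", fixed = TRUE)[[1L]]
    merged <- paste0(pair[1L], pair[2L])
    merges[[length(merges) + 1L]] <- pair
    tokens <- c(tokens, merged)
    corpus <- lapply(corpus, merge_pair_in_seq, pair[1L], pair[2L], merged)
  }
  vocab <- setNames(seq_along(tokens) - 1L + length(SPECIAL_TOKENS), tokens)
  structure(list(vocab = c(SPECIAL_TOKENS, vocab),
                 merges = merges,
                 specials = SPECIAL_TOKENS,
                 base_alphabet = base),
            class = "bpe_tokenizer")
}

#' Total vocabulary size of a tokenizer (specials included)
#' @param tok A `bpe_tokenizer`.
#' @return Integer count of token ids.
#' @export
vocab_size <- function(tok) length(tok$vocab)

apply_merges <- function(tok, symbols) {
  for (m in tok$merges)
    symbols <- merge_pair_in_seq(symbols, m[1L], m[2L], paste0(m[1L], m[2L]))
  symbols
}

#' Encode a sequence to fixed-length token ids
#'
#' Greedy application of the learned merges in training order, then
#' right-truncation to `max_len` (keeping the N-terminus / 5' end) or
#' right-padding with PAD; when room remains after the real tokens, EOS is
#' appended before the padding. The attention mask is 1 on real tokens
#' (including EOS) and 0 on padding. Spans give, per kept sequence token,
#' the 1-based inclusive residue offsets it covers in the original sequence.
#'
#' @param tok A `bpe_tokenizer` from [train_bpe()].
#' @param seq Sequence string in a single alphabet.
#' @param kind `"protein"` or `"rna"`.
#' @param max_len Frame length (default 1024).
#' @return List with `ids` (0-based integer vector of length `max_len`),
#'   `mask` (0/1 vector), `spans` (k x 2 matrix of residue offsets),
#'   `tokens` (kept token strings), `n_tokens` (count of kept sequence
#'   tokens, excluding EOS).
#' @export
bpe_encode <- function(tok, seq, kind = c("protein", "rna"),
                       max_len = 1024L) {
  kind <- match.arg(kind)
  stopifnot(inherits(tok, "bpe_tokenizer"))
  symbols <- symbolize(seq, kind)
  unknown <- setdiff(unique(symbols), tok$base_alphabet)
  if (length(unknown))
    stop("sequence contains symbols outside the tokenizer alphabet: ",
         paste(desymbolize(unknown), collapse = ", "))
  pieces <- apply_merges(tok, symbols)
  ids <- unname(tok$vocab[pieces])
  truncated <- length(ids) > max_len
  if (truncated) {
    keep <- max_len
    ids <- ids[seq_len(keep)]
    pieces <- pieces[seq_len(keep)]
    body <- ids
    mask <- rep(1L, max_len)
  } else {
    keep <- length(ids)
    body <- c(ids, tok$specials[["EOS"]])
    if (length(body) > max_len) body <- body[seq_len(max_len)]
    mask <- c(rep(1L, length(body)), rep(0L, max_len - length(body)))
    body <- c(body, rep(tok$specials[["PAD"]], max_len - length(body)))
  }
  widths <- nchar(pieces)
  ends <- cumsum(widths)
  spans <- cbind(start = ends - widths + 1L, end = ends)
  list(ids = as.integer(body), mask = as.integer(mask), spans = spans,
       tokens = pieces, n_tokens = keep, truncated = truncated)
}

#' Decode token ids back to a sequence string
#'
#' Special tokens (PAD/BOS/EOS/UNK) are dropped; RNA tokens are mapped back
#' to uppercase bases. `bpe_decode(bpe_encode(s))` recovers `s` exactly for
#' any in-alphabet sequence that fits the frame.
#'
#' @param tok A `bpe_tokenizer`.
#' @param ids Integer vector of 0-based token ids.
#' @return Decoded sequence string.
#' @export
bpe_decode <- function(tok, ids) {
  ids <- ids[!ids %in% tok$specials]
  if (length(ids) == 0L) return("")
  rev_map <- setNames(names(tok$vocab), tok$vocab)
  toks <- rev_map[as.character(ids)]
  if (anyNA(toks)) stop("unknown token id(s): ",
                        paste(ids[is.na(toks)], collapse = ", "))
  paste(vapply(toks, desymbolize, ""), collapse = "")
}

#' Token-to-residue span map for a sequence
#'
#' Returns, for each token of the encoded (possibly truncated) prefix, the
#' 1-based inclusive residue interval it covers. Span widths equal token
#' string lengths and the spans tile the encoded prefix without overlap.
#'
#' @inheritParams bpe_encode
#' @return k x 2 integer matrix with columns `start`, `end`.
#' @export
token_residue_spans <- function(tok, seq, kind = c("protein", "rna"),
                                max_len = 1024L) {
  bpe_encode(tok, seq, kind = kind, max_len = max_len)$spans
}

#' Ids of tokens drawn from the RNA alphabet (plus EOS)
#'
#' Convenience for restricting a decoder's output distribution to the RNA
#' vocabulary (see [restrict_output_vocab()]).
#'
#' @param tok A `bpe_tokenizer`.
#' @return Integer vector of 0-based token ids.
#' @export
rna_token_ids <- function(tok) {
  toks <- names(tok$vocab)
  is_rna <- !toks %in% names(tok$specials) &
    grepl("^[acgu]+$", toks)
  sort(c(unname(tok$vocab[is_rna]), tok$specials[["EOS"]]))
}

#' Serialize a tokenizer to JSON
#' @param tok A `bpe_tokenizer`.
#' @param path Output path.
#' @export
write_tokenizer <- function(tok, path) {
  jsonlite::write_json(
    list(vocab = as.list(tok$vocab),
         merges = lapply(tok$merges, as.list),
         base_alphabet = tok$base_alphabet),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a tokenizer from JSON
#' @param path Path written by [write_tokenizer()].
#' @return A `bpe_tokenizer`.
#' @export
read_tokenizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vocab <- setNames(as.integer(unlist(obj$vocab)), names(obj$vocab))
  structure(list(vocab = vocab,
                 merges = lapply(obj$merges, function(m)
                   c(m[[1L]], m[[2L]])),
                 specials = SPECIAL_TOKENS,
                 base_alphabet = unlist(obj$base_alphabet)),
            class = "bpe_tokenizer")
}
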