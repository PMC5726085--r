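#' Construct a citation corpus
#'
#' A citation corpus is an ordered collection of bibliographic records, each
#' carrying a unique identifier, a title, an abstract (possibly empty) and an
#' optional binary eligibility label (1 = include/eligible, 0 =
#' exclude/ineligible, `NA` = not yet screened).
#'
#' @param id character vector of unique citation identifiers.
#' @param title character vector of titles.
#' @param abstract character vector of abstracts; `NA` is coerced to `""`.
#' @param label integer vector of gold labels (0, 1 or `NA`).
#' @return A data frame of class `citation_corpus` with columns `id`,
#'   `title`, `abstract`, `label`.
#' @examples
#' citation_corpus(c("a", "b"), c("Trial of X", "Survey of Y"),
#'                 c("some text", ""), c(1L, NA))
#' @export
citation_corpus <- function(id, title, abstract, label = NA_integer_) {
  n <- length(id)
  id <- as.character(id)
  title <- as.character(title)
  abstract <- as.character(abstract)
  abstract[is.na(abstract)] <- ""
  title[is.na(title)] <- ""
  label <- suppressWarnings(as.integer(label))
  label <- rep_len(label, n)
  corpus <- data.frame(id = id, title = rep_len(title, n),
                       abstract = rep_len(abstract, n), label = label,
                       stringsAsFactors = FALSE)
  class(corpus) <- c("citation_corpus", "data.frame")
  validate_corpus(corpus)
  corpus
}

validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  need <- c("id", "title", "abstract", "label")
  miss <- setdiff(need, names(corpus))
  if (length(miss) > 0L) {
    stop("corpus is missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- unique(corpus$id[duplicated(corpus$id)])
  if (length(dup) > 0L) {
    stop("duplicate citation id(s): ", paste(dup, collapse = ", "))
  }
  bad <- !(is.na(corpus$label) | corpus$label %in% c(0L, 1L))
  if (any(bad)) {
    stop("labels must be 0, 1 or NA; offending id(s): ",
         paste(corpus$id[bad], collapse = ", "))
  }
  invisible(corpus)
}

#' Read a citation corpus from a delimited file
#'
#' The file must be UTF-8 with a header row naming at least `id`, `title`
#' and `abstract`; an optional `label` column holds 0/1 screening decisions,
#' with blank or `NA` cells meaning unscreened. Rows are kept in file order.
#'
#' @param path path to a CSV or TSV file.
#' @param format `"auto"` (by file extension, default), `"csv"` or `"tsv"`.
#' @return A [citation_corpus] data frame.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", na.strings = character(),
                           comment.char = "", fileEncoding = "UTF-8",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "title", "abstract")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  lab <- if ("label" %in% names(raw)) parse_label(raw$label) else
    rep(NA_integer_, nrow(raw))
  citation_corpus(raw$id, raw$title, raw$abstract, lab)
}

parse_label <- function(x) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  out[x == "0"] <- 0L
  out[x == "1"] <- 1L
  bad <- !(x %in% c("", "NA", "na", "0", "1"))
  if (any(bad)) {
    stop("unparseable label value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Write a citation corpus to a delimited file
#'
#' @param corpus a [citation_corpus].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  out <- as.data.frame(corpus)[, c("id", "title", "abstract", "label")]
  out$label <- ifelse(is.na(out$label), "", as.character(out$label))
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, col.names = TRUE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Tokenise free text
#'
#' Lowercases the input and splits on any maximal run of non-alphanumeric
#' characters; all resulting tokens of length >= 1 are kept in order. No
#' stemming is applied. An optional stop-word list may be removed.
#'
#' @param text character vector; each element is tokenised independently.
#' @param stopwords character vector of tokens to drop (compared after
#'   lowercasing); empty by default.
#' @return A list of character vectors, one per element of `text`.
#' @examples
#' tokenize_text("Beta-2 agonist, COPD.")
#' @export
tokenize_text <- function(text, stopwords = character()) {
  text <- tolower(as.character(text))
  text[is.na(text)] <- ""
  toks <- strsplit(text, "[^a-z0-9]+")
  lapply(toks, function(tt) {
    tt <- tt[nzchar(tt)]
    if (length(stopwords) > 0L) tt <- tt[!(tt %in% stopwords)]
    tt
  })
}

corpus_tokens <- function(corpus, stopwords = character()) {
  # title and abstract form a single bag per citation
  tokenize_text(paste(corpus$title, corpus$abstract), stopwords = stopwords)
}

#' Build the corpus vocabulary
#'
#' Collects every token occurring in at least one citation (title and
#' abstract concatenated) and records, for each token, its document
#' frequency `f_w`: the fraction of citations that contain it. Document
#' frequency is computed over the full pool — labelled and unlabelled alike —
#' since the whole citation list is on hand when screening starts.
#'
#' @param corpus a [citation_corpus].
#' @param stopwords optional stop-word list passed to [tokenize_text()].
#' @return An object of class `screen_vocabulary`: a list with `tokens`
#'   (ordered character vector), `df` (named numeric, document frequencies in
#'   (0, 1]) and `n_docs`.
#' @export
build_vocabulary <- function(corpus, stopwords = character()) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0L) stop("corpus is empty")
  toks <- corpus_tokens(corpus, stopwords)
  if (sum(lengths(toks)) == 0L) {
    stop("corpus contains no tokens at all")
  }
  per_doc <- lapply(toks, unique)
  tab <- table(unlist(per_doc))
  tokens <- sort(names(tab))
  df <- as.numeric(tab[tokens]) / nrow(corpus)
  names(df) <- tokens
  structure(list(tokens = tokens, df = df, n_docs = nrow(corpus),
                 stopwords = stopwords),
            class = "screen_vocabulary")
}

#' @export
print.screen_vocabulary <- function(x, ...) {
  cat("<screen_vocabulary> ", length(x$tokens), " tokens over ",
      x$n_docs, " citations\n", sep = "")
  invisible(x)
}

#' TF-IDF term matrix
#'
#' Builds the sparse n x m matrix with entries `X[d, w] = c_dw * log(1/f_w)`,
#' where `c_dw` is the count of token `w` in citation `d` and `f_w` its
#' document frequency. The natural logarithm is used; the base only rescales
#' columns and cancels in the cosine and Bhattacharyya similarities used
#' downstream. Tokens present in every citation get `log(1) = 0` and so
#' contribute nothing; every entry is non-negative.
#'
#' @param corpus a [citation_corpus].
#' @param vocab a `screen_vocabulary`; defaults to one built from `corpus`.
#' @return A `dgCMatrix` with citation ids as row names and tokens as column
#'   names.
#' @export
tfidf_matrix <- function(corpus, vocab = build_vocabulary(corpus)) {
  validate_corpus(corpus)
  stopifnot(inherits(vocab, "screen_vocabulary"))
  toks <- corpus_tokens(corpus, vocab$stopwords)
  m <- length(vocab$tokens)
  n <- nrow(corpus)
  idx <- lapply(toks, function(tt) {
    j <- match(tt, vocab$tokens)
    j[!is.na(j)]
  })
  i <- rep.int(seq_len(n), lengths(idx))
  j <- unlist(idx, use.names = FALSE)
  if (length(j) == 0L) {
    X <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, m))
  } else {
    # duplicate (i, j) pairs are summed: term counts
    X <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, m))
  }
  idf <- log(1 / vocab$df)
  X <- X %*% Matrix::Diagonal(m, idf)
  X <- methods::as(Matrix::drop0(X), "CsparseMatrix")
  dimnames(X) <- list(corpus$id, vocab$tokens)
  X
}

#' Export a term matrix as Matrix Market plus a vocabulary table
#'
#' Writes `<prefix>.mtx` (the sparse matrix) and `<prefix>.vocab.tsv` with
#' columns `token`, `index` (0-based) and `df`.
#'
#' @param X a sparse term matrix from [tfidf_matrix()].
#' @param vocab the matching `screen_vocabulary`.
#' @param prefix output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_term_matrix <- function(X, vocab, prefix) {
  stopifnot(inherits(vocab, "screen_vocabulary"), ncol(X) == length(vocab$tokens))
  mtx <- paste0(prefix, ".mtx")
  vtsv <- paste0(prefix, ".vocab.tsv")
  Matrix::writeMM(X, mtx)
  utils::write.table(
    data.frame(token = vocab$tokens,
               index = seq_along(vocab$tokens) - 1L,
               df = vocab$df[vocab$tokens]),
    vtsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(mtx, vtsv))
}
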