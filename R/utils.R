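#' @importFrom rlang %||% abort warn
#' @importFrom stats qnorm rnorm rpois runif rbinom prop.test setNames aggregate
#' @importFrom utils head tail
NULL

#' Parse an ISO-8601-style timestamp as UTC
#'
#' Accepts `"YYYY-mm-ddTHH:MM:SS"` (optionally with a trailing `Z`) or a
#' space separator. Already-parsed `POSIXct` input is passed through after
#' conversion to UTC.
#'
#' @param x Character vector (or `POSIXct`).
#' @return `POSIXct` in UTC; unparseable elements become `NA`.
#' @export
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- sub("Z$", "", sub("T", " ", as.character(x), fixed = TRUE))
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Format a UTC instant as an ISO-8601 string
#'
#' @param t `POSIXct` vector.
#' @return Character vector `"YYYY-mm-ddTHH:MM:SSZ"`; `NA` stays `NA`.
#' @export
fmt_utc <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Lowercase alphanumeric tokenization: split on runs of non-alphanumerics.
tokenize <- function(x) {
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9]+")
  lapply(toks, function(tk) tk[nzchar(tk)])
}

# Does the token sequence `term_toks` occur contiguously within `toks`?
contains_token_seq <- function(toks, term_toks) {
  k <- length(term_toks)
  if (k == 0L || length(toks) < k) return(FALSE)
  if (k == 1L) return(term_toks %in% toks)
  starts <- which(toks == term_toks[[1L]])
  starts <- starts[starts + k - 1L <= length(toks)]
  for (s in starts) {
    if (all(toks[s:(s + k - 1L)] == term_toks)) return(TRUE)
  }
  FALSE
}

# Which of `terms` (character, lowercased) match the single string `text`?
# mode "token": contiguous token-sequence match on word boundaries;
# mode "substring": plain case-insensitive substring containment.
matching_terms <- function(text, terms, mode = c("token", "substring")) {
  mode <- match.arg(mode)
  if (is.na(text) || !nzchar(text) || length(terms) == 0L) return(character(0))
  if (mode == "substring") {
    low <- tolower(text)
    return(terms[vapply(terms, function(tm) grepl(tm, low, fixed = TRUE), logical(1))])
  }
  toks <- tokenize(text)[[1L]]
  term_toks <- strsplit(terms, "[^a-z0-9]+")
  terms[vapply(term_toks, contains_token_seq, logical(1), toks = toks)]
}

# All 5-digit tokens in a string (candidate ZIP codes).
zip_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- tokenize(text)[[1L]]
  toks[grepl("^[0-9]{5}$", toks)]
}

normalize_terms <- function(terms, strip_prefix = NULL) {
  terms <- trimws(tolower(as.character(terms)))
  if (!is.null(strip_prefix)) terms <- sub(paste0("^[", strip_prefix, "]"), "", terms)
  unique(terms[nzchar(terms)])
}
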