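#' Parse a PROSITE-style pattern
#'
#' Parses the dash-separated PROSITE motif syntax used to describe the
#' conserved histidine boxes of fatty acid desaturases, e.g. the tripartite
#' motif `"H-x(3,4)-H-x(3,150)-H-x(2,3)-H-H-x(50,250)-[HQ]-x(2,3)-H-H"`.
#' Supported elements: literal residues (`H`), residue classes (`[HQ]`),
#' negated classes (`{P}`), and the wildcard `x`, each with an optional
#' repeat count `(n)` or range `(n,m)`. Stray whitespace is tolerated.
#'
#' @param text Pattern string.
#' @return Object of class `prosite_pattern`: a data frame with columns
#'   `type` (`literal`/`class`/`negated`/`any`), `chars`, `min`, `max`.
#' @examples
#' parse_prosite("H-x(3,4)-H")
#' @export
parse_prosite <- function(text) {
  text <- gsub("[[:space:]]+", "", text)
  if (!nzchar(text)) stop("empty pattern")
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) stop("empty pattern element (stray dash?)")
  parse_one <- function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-WYZ]|\\[([A-Z]+)\\]|\\{([A-Z]+)\\})(\\((\\d+)(,(\\d+))?\\))?$",
      tok))[[1]]
    if (length(m) == 0) {
      if (grepl("\\($", tok) || grepl("\\([^)]*$", tok)) {
        stop("malformed repeat range in element: ", tok)
      }
      if (grepl("^\\[\\]", tok) || grepl("^\\{\\}", tok)) {
        stop("empty residue class in element: ", tok)
      }
      stop("cannot parse pattern element: ", tok)
    }
    head <- m[2]
    if (startsWith(head, "[")) {
      type <- "class"; chars <- m[3]
    } else if (startsWith(head, "{")) {
      type <- "negated"; chars <- m[4]
    } else if (head == "x") {
      type <- "any"; chars <- ""
    } else {
      type <- "literal"; chars <- head
    }
    lo <- if (nzchar(m[6])) as.integer(m[6]) else 1L
    hi <- if (nzchar(m[8])) as.integer(m[8]) else lo
    if (lo > hi) stop("repeat range has min > max in element: ", tok)
    if (lo < 1 && type != "any") {
      stop("repeat minimum must be >= 1 in element: ", tok)
    }
    data.frame(type = type, chars = chars, min = lo, max = hi,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(tokens, parse_one))
  class(out) <- c("prosite_pattern", class(out))
  out
}

#' The tripartite histidine-box motif of the fatty acid desaturase family
#'
#' The PROSITE pattern used to curate candidate long-spaced desaturase
#' (FAD) sequences: three histidine clusters with family-characteristic
#' spacing, the third cluster admitting glutamine in its first position.
#'
#' @return Pattern string suitable for [parse_prosite()].
#' @export
fad_tripartite_motif <- function() {
  "H-x(3,4)-H-x(3,150)-H-x(2,3)-H-H-x(50,250)-[HQ]-x(2,3)-H-H"
}

# does residue ch satisfy pattern element row e?
element_ok <- function(e, ch) {
  switch(e$type,
         any = TRUE,
         literal = ch == e$chars,
         class = grepl(ch, e$chars, fixed = TRUE),
         negated = !grepl(ch, e$chars, fixed = TRUE))
}

#' Scan a protein for matches to a PROSITE-style pattern
#'
#' Enumerates match start positions left to right; at each start,
#' variable-length elements are explored shortest-first and only the first
#' (shortest-expansion) match is reported, mirroring single-hit ScanProsite
#' reporting. Overlapping matches with distinct starts are all reported.
#'
#' @param pattern A `prosite_pattern` or pattern string.
#' @param protein Protein string, or named character vector of proteins.
#' @return Data frame with columns `id`, `start`, `end` (0-based,
#'   half-open) and `length`.
#' @examples
#' scan_prosite("H-x(3,4)-H", c(p1 = "AHAAAHA"))
#' @export
scan_prosite <- function(pattern, protein) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  if (is.null(names(protein))) {
    names(protein) <- paste0("seq", seq_along(protein))
  }
  res <- lapply(names(protein), function(id) {
    hits <- scan_one(pattern, protein[[id]])
    if (nrow(hits) == 0) return(NULL)
    cbind(data.frame(id = id, stringsAsFactors = FALSE), hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(id = character(), start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# scan one sequence; returns data.frame(start, end, length) 0-based half-open
scan_one <- function(pattern, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_el <- nrow(pattern)
  elems <- lapply(seq_len(n_el), function(i) pattern[i, ])
  # minimal total remaining length from element i (for pruning)
  min_rest <- rev(cumsum(rev(pattern$min)))
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(L)) {
    # fail memo: fail[i, p] TRUE if element i cannot match starting at p
    fail <- matrix(FALSE, n_el, L + 2L)
    match_from <- function(i, pos) {
      # returns end position (1-based, exclusive) or -1
      if (i > n_el) return(pos)
      if (pos + min_rest[i] - 1L > L) return(-1L)
      if (pos <= L + 1L && fail[i, pos]) return(-1L)
      e <- elems[[i]]
      # shortest-first over repeat counts
      k <- 0L
      p <- pos
      while (k < e$min) {  # mandatory repeats
        if (p > L || !element_ok(e, chars[p])) {
          fail[i, pos] <<- TRUE
          return(-1L)
        }
        p <- p + 1L; k <- k + 1L
      }
      repeat {
        r <- match_from(i + 1L, p)
        if (r >= 0L) return(r)
        if (k >= e$max) break
        if (p > L || !element_ok(e, chars[p])) break
        p <- p + 1L; k <- k + 1L
      }
      fail[i, pos] <<- TRUE
      -1L
    }
    e <- match_from(1L, s)
    if (e >= 0L && e > s) {
      starts <- c(starts, s - 1L)  # 0-based
      ends <- c(ends, e - 1L)     # half-open
    }
  }
  data.frame(start = starts, end = ends, length = ends - starts,
             stringsAsFactors = FALSE)
}

#' Partition proteins by motif presence
#'
#' @param proteins Named character vector of protein sequences.
#' @param pattern A `prosite_pattern` or pattern string; defaults to the
#'   FAD tripartite histidine motif.
#' @return List with elements `kept` (proteins with at least one match) and
#'   `discarded`; the two are an exhaustive, disjoint partition of the
#'   input.
#' @export
filter_by_motif <- function(proteins, pattern = fad_tripartite_motif()) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  if (length(proteins) == 0) {
    return(list(kept = proteins, discarded = proteins))
  }
  has <- vapply(proteins, function(p) nrow(scan_one(pattern, p)) > 0,
                logical(1))
  list(kept = proteins[has], discarded = proteins[!has])
}
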