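# Independent brute-force oracles. These re-derive expected values from
# first principles and deliberately share no code with the package
# implementations they check.

# ---- motif scanning ----------------------------------------------------

# PROSITE pattern -> anchored lazy regex; R's PCRE engine is the
# independent matcher. Lazy quantifiers reproduce shortest-first expansion.
oracle_pattern_regex <- function(text) {
  text <- gsub("[[:space:]]+", "", text)
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\((\\d+)(,(\\d+))?\\))?$",
      tok))[[1]]
    head <- m[2]
    base <- if (head == "x") "." else if (startsWith(head, "{")) {
      paste0("[^", substr(head, 2, nchar(head) - 1), "]")
    } else head
    lo <- if (nzchar(m[4])) m[4] else "1"
    hi <- if (nzchar(m[6])) m[6] else lo
    if (lo == "1" && hi == "1") base
    else sprintf("%s{%s,%s}?", base, lo, hi)
  }, character(1))
  paste0(parts, collapse = "")
}

# all matches (0-based half-open, shortest expansion per start) via the
# regex engine, one anchored probe per start position
oracle_scan <- function(pattern_text, seq) {
  rx <- paste0("^(", oracle_pattern_regex(pattern_text), ")")
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(nchar(seq))) {
    m <- regexpr(rx, substring(seq, s), perl = TRUE)
    if (m == 1) {
      starts <- c(starts, s - 1L)
      ends <- c(ends, s - 1L + attr(m, "match.length"))
    }
  }
  data.frame(start = starts, end = ends)
}

# ---- global alignment --------------------------------------------------

# exhaustive enumeration of all global alignments (affine gaps: a gap of
# length L costs open + ext * L); feasible for lengths <= 5
oracle_align_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: i, j consumed; last move (0 start, 1 diag, 2 up/gap-in-b, 3 left)
  rec <- function(i, j, last, sc) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) {
      rec(i + 1, j + 1, 1, sc + mat[ca[i + 1], cb[j + 1]])
    }
    if (i < length(ca)) {
      cost <- ext + if (last == 2) 0 else open
      rec(i + 1, j, 2, sc - cost)
    }
    if (j < length(cb)) {
      cost <- ext + if (last == 3) 0 else open
      rec(i, j + 1, 3, sc - cost)
    }
  }
  rec(0, 0, 0, 0)
  best
}

# ---- Nei-Gojobori ------------------------------------------------------

oracle_codon_neighbours <- function(codon) {
  nt <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(nt, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      out <- c(out, alt)
    }
  }
  out
}

# site fractions by direct enumeration of the 9 single-nt changes
oracle_ng86_sites <- function(codon, aa_map) {
  s <- 0; n <- 0
  for (p in 1:3) {
    alts <- character(0)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      alts <- c(alts, alt)
    }
    keep <- alts[aa_map[alts] != "*"]
    if (length(keep) == 0) next
    fs <- sum(aa_map[keep] == aa_map[codon]) / length(keep)
    s <- s + fs
    n <- n + (1 - fs)
  }
  c(s = s, n = n)
}

# pathway-averaged differences for one codon pair: DFS over orders of the
# differing positions, paths through stops dropped; returns NULL if all
# paths are blocked
oracle_ng86_diffs <- function(a, b, aa_map) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  acc <- list(sd = 0, nd = 0, n = 0)
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      acc$sd <<- acc$sd + sd
      acc$nd <<- acc$nd + nd
      acc$n <<- acc$n + 1
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (aa_map[[nxt]] == "*") next
      syn <- aa_map[[nxt]] == aa_map[[cur]]
      walk(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  walk(a, pos, 0, 0)
  if (acc$n == 0) return(NULL)
  c(sd = acc$sd / acc$n, nd = acc$nd / acc$n)
}

# full pairwise NG86 on codon vectors, computed from the primitives above
oracle_ng86_pair <- function(ca, cb, aa_map) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; skipped <- 0
  for (k in seq_along(ca)) {
    d <- oracle_ng86_diffs(ca[k], cb[k], aa_map)
    if (is.null(d)) { skipped <- skipped + 1; next }
    sa <- oracle_ng86_sites(ca[k], aa_map)
    sb <- oracle_ng86_sites(cb[k], aa_map)
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    Sd <- Sd + d["sd"]
    Nd <- Nd + d["nd"]
  }
  jc <- function(p) {
    if (!is.finite(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       dS = jc(unname(Sd / S)), dN = jc(unname(Nd / N)),
       skipped = skipped)
}

# ---- Fitch parsimony ---------------------------------------------------

# minimum number of state changes over ALL internal labelings drawn from
# the observed states; exact for small trees
oracle_fitch_length <- function(tree, tip_states) {
  states <- sort(unique(tip_states))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  grids <- rep(list(states), n_int)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(tip_states[tree$tip.label], unlist(combos[r, ]))
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# ---- misc helpers ------------------------------------------------------

random_protein <- function(n, alphabet = c("A", "H", "Q", "K", "L")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_cds <- function(codons, code, id = "g") {
  fadevo:::new_coding_sequence(id, codons, code)
}

random_sense_codons <- function(n, code) {
  sample(code$sense, n, replace = TRUE)
}
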