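#' Global pairwise protein alignment with EMBOSS-style statistics
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + gap_extend * L`). Percent identity is the
#' number of identical aligned pairs over the alignment length; percent
#' similarity is the number of aligned residue pairs with a positive
#' substitution score over the alignment length. With the default
#' BLOSUM62 / 10 / 0.5 scoring these are the EMBOSS needle conventions,
#' the community default for reporting identity/similarity between two
#' proteins.
#'
#' @param a,b Protein sequences (strings).
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, `length`,
#'   `identity` and `similarity` (percentages).
#' @examples
#' r <- global_align("MKV", "MRV")
#' c(r$identity, r$similarity)  # 66.67, 100 (K/R scores +2 in BLOSUM62)
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (is.character(matrix)) {
    mat <- get(utils::data(list = matrix, package = "Biostrings",
                           envir = environment()))
  } else {
    mat <- matrix
  }
  for (s in c(a, b)) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    missing <- setdiff(ch, rownames(mat))
    if (length(missing) > 0) {
      stop("residue(s) absent from substitution matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & both)
  pair_scores <- mat[cbind(match(ca[both], rownames(mat)),
                           match(cb[both], colnames(mat)))]
  simil <- sum(pair_scores > 0)
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 score = Biostrings::score(pa), length = len,
                 identity = 100 * ident / len,
                 similarity = 100 * simil / len),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> length %d, score %.1f, identity %.1f%%, similarity %.1f%%\n",
    x$length, x$score, x$identity, x$similarity))
  invisible(x)
}

#' Identity and similarity of the two Des22 paralogs
#'
#' Convenience wrapper: reads a two-record protein FASTA holding the
#' *Tetrahymena thermophila* sterol C-22 desaturase paralogs Des22Ap
#' (UniProt I7M1E1, gene TTHERM_00129290) and Des22Bp (UniProt Q236U7,
#' gene TTHERM_00085010) and reports their EMBOSS-convention global
#' identity and similarity. The sequences are not redistributed with the
#' package; download them from UniProt into a FASTA file first.
#'
#' @param fasta Path to a protein FASTA with exactly two records.
#' @param ... Passed to [global_align()].
#' @return The [global_align()] result.
#' @export
des22_identity <- function(fasta, ...) {
  prot <- read_fasta(fasta, alphabet = "protein")
  if (length(prot) != 2) {
    stop("expected exactly 2 protein records, found ", length(prot))
  }
  global_align(prot[[1]], prot[[2]], ...)
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style greedy clustering used for redundancy removal: sequences
#' are sorted by length descending (ties by id), the first seeds a cluster,
#' and each subsequent sequence joins the first existing seed it matches at
#' `identity >= threshold`, where identity is the number of identical
#' aligned pairs over the length of the shorter sequence (from a global
#' alignment); otherwise it seeds a new cluster. No k-mer prefilter is
#' used; every comparison is an explicit alignment.
#'
#' @param seqs Named character vector of protein sequences.
#' @param threshold Identity fraction in (0, 1]; the redundancy filter of
#'   the FAD curation uses 0.99.
#' @param ... Passed to [global_align()].
#' @return Data frame with columns `cluster_id`, `member_id`,
#'   `representative` (logical; the cluster seed).
#' @export
greedy_cluster <- function(seqs, threshold = 0.99, ...) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0) {
    return(data.frame(cluster_id = integer(), member_id = character(),
                      representative = logical()))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  seeds <- character(0)   # seed ids in creation order
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      al <- global_align(seqs[[seeds[k]]], seqs[[i]], ...)
      ident <- n_identical_pairs(al) /
        min(nchar(seqs[[seeds[k]]]), nchar(seqs[[i]]))
      if (ident >= threshold) {
        assign_to[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, names(seqs)[i])
      assign_to[i] <- length(seeds)
    }
  }
  data.frame(cluster_id = assign_to,
             member_id = names(seqs),
             representative = names(seqs) == seeds[assign_to],
             stringsAsFactors = FALSE)
}

n_identical_pairs <- function(al) {
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-")
}
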