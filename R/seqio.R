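#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA. Record order is preserved, ids are the
#' header token up to the first whitespace, sequences are upper-cased, and
#' `U` is mapped to `T` for nucleotide input. Gap characters (`-`) are
#' accepted so that FASTA-as-alignment files can be read.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "nucleotide") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    legal <- "ACGTN-"
  } else {
    legal <- "ACDEFGHIKLMNPQRSTVWYX*-"
  }
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", gsub("-", "\\-", legal)), seqs[[i]])
    if (bad > 0) {
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   substr(seqs[[i]], bad, bad), bad, ids[[i]]))
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate a raw nucleotide sequence as a coding sequence
#'
#' Checks that the sequence length is divisible by 3, contains no ambiguity
#' characters, and contains no internal stop codon under the bound genetic
#' code. A terminal stop codon is stripped and recorded. Sequences
#' containing `N` are rejected, not repaired: all downstream codon-usage
#' statistics are count-based and imputation would bias them.
#'
#' @param seq Nucleotide string over A, C, G, T (U accepted, mapped to T).
#' @param code A [genetic_code()] object.
#' @param id Sequence identifier carried into reports.
#' @return An object of class `coding_sequence`: list with `id`, `codons`
#'   (character vector of sense codons), `code` (the bound genetic code),
#'   and `had_terminal_stop`.
#' @examples
#' cds <- validate_cds("ATGTTTTAA", genetic_code(1), id = "x")
#' cds$codons            # "ATG" "TTT"
#' cds$had_terminal_stop # TRUE
#' @export
validate_cds <- function(seq, code, id = "seq") {
  stopifnot(is_genetic_code(code))
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] > 0) {
    stop(sprintf("sequence '%s' has non-ACGT character(s) at position(s): %s",
                 id, paste(bad, collapse = ", ")))
  }
  if (nchar(seq) %% 3 != 0) {
    stop(sprintf("sequence '%s' length %d is not divisible by 3",
                 id, nchar(seq)))
  }
  codons <- split_codons(seq)
  if (length(codons) == 0) stop(sprintf("sequence '%s' is empty", id))
  aa <- code$codon_to_aa[codons]
  had_terminal_stop <- aa[length(aa)] == "*"
  if (had_terminal_stop) {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (length(codons) == 0) {
    stop(sprintf("sequence '%s' has no codons after stripping terminal stop",
                 id))
  }
  internal <- which(aa == "*")
  if (length(internal) > 0) {
    stop(sprintf(
      "sequence '%s' has internal stop codon %s at codon index %d (0-based) under table %s",
      id, codons[internal[1]], internal[1] - 1L, code$table_id))
  }
  new_coding_sequence(id, codons, code, had_terminal_stop)
}

# Internal constructor; codons assumed sense under `code`.
new_coding_sequence <- function(id, codons, code, had_terminal_stop = FALSE) {
  structure(list(id = id, codons = codons, code = code,
                 had_terminal_stop = had_terminal_stop),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence '%s'> %d codons, table %s%s\n", x$id,
              length(x$codons), x$code$table_id,
              if (x$had_terminal_stop) ", terminal stop stripped" else ""))
  invisible(x)
}

#' Translate a coding sequence
#'
#' One residue per codon under the sequence's bound genetic code.
#'
#' @param cds A `coding_sequence` from [validate_cds()].
#' @return Protein string.
#' @examples
#' translate_cds(validate_cds("ATGTTT", genetic_code(1)))  # "MF"
#' translate_cds(validate_cds("TAA", genetic_code(6)))     # "Q"
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  paste(cds$code$codon_to_aa[cds$codons], collapse = "")
}

#' Read a Newick tree
#'
#' Reads one Newick tree. Internal nodes without labels get stable generated
#' labels (`"N1"`, `"N2"`, ... in preorder); missing branch lengths default
#' to 0 with a warning. Duplicate leaf labels and negative branch lengths
#' are errors.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An [ape::read.tree()] `phylo` object, rooted layout preserved,
#'   with `node.label` filled in.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) {
    stop("expected one tree in ", path, ", found ", length(phy))
  }
  if (is.null(phy)) stop("could not parse Newick in ", path)
  label_phylo(phy)
}

# Fill missing internal-node labels (N1.. in preorder), default missing
# branch lengths to 0 with a warning, check invariants. Shared by
# read_newick and the simulators.
label_phylo <- function(phy) {
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup) > 0) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  } else if (anyNA(phy$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  if (is.null(phy$node.label)) phy$node.label <- rep("", n_node)
  phy$node.label[is.na(phy$node.label)] <- ""
  # preorder over internal nodes
  pre <- ape::reorder.phylo(phy, "cladewise")
  internal_pre <- unique(pre$edge[, 1])
  needs <- !nzchar(phy$node.label)
  k <- 0L
  for (nd in internal_pre) {
    idx <- nd - n_tip
    if (needs[idx]) {
      k <- k + 1L
      phy$node.label[idx] <- paste0("N", k)
    }
  }
  # guard against collisions with tip labels
  clash <- intersect(phy$node.label, phy$tip.label)
  if (length(clash) > 0) {
    stop("internal node label(s) clash with tip labels: ",
         paste(clash, collapse = ", "))
  }
  phy
}

#' Write a Newick tree
#'
#' Branch lengths are written with 10 significant digits so that a
#' write/read round trip preserves them.
#'
#' @param phy A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 10)
  invisible(path)
}

# node label lookup: label for node number (tips then internals)
node_labels <- function(phy) c(phy$tip.label, phy$node.label)
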